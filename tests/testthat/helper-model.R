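# Shared fixtures: the packaged base case, a zero-mortality life table, and
# small generators for property-style tests.

basecase <- load_model()

zero_life_table <- as_life_table(data.frame(
  age = rep(55:70, 2),
  sex = rep(c("male", "female"), each = 16),
  annual_mortality = 0
))

# random contiguous schedule over 1..horizon
random_schedule <- function(horizon = 60, max_prob = 0.5) {
  k <- sample(1:4, 1)
  cuts <- sort(sample(seq_len(horizon - 1), k - 1))
  first <- c(1, cuts + 1)
  last <- c(cuts, horizon)
  transition_schedule(first, last, stats::runif(k, 0.01, max_prob))
}

# minimal treatment arm around a schedule
toy_arm <- function(schedule, p_cancer_death = 0.02, p_g12 = 0.05,
                    p_g34 = 0.03, p_disc = 0.01, p_aed = 0.002,
                    drug_cost = 1000, admin_cost = 100, window = 6) {
  structure(list(
    id = "toy", label = "toy", drug_cost = drug_cost, admin_cost = admin_cost,
    p_cancer_death_pf = p_cancer_death, progression = schedule,
    ae = list(p_grade12 = p_g12, p_grade34 = p_g34,
              p_discontinuation = p_disc, p_death = p_aed,
              cost_grade34 = 10000, disutility_grade12 = 0.07,
              disutility_grade34 = 0.18, window = window),
    pf_cost_from_bsc = FALSE), class = "gc_arm")
}

# brute-force frontier oracle: strict pairwise dominance plus extended
# dominance by two-point blends (independent of the ICER-chain construction)
oracle_frontier <- function(df) {
  n <- nrow(df)
  strictly <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qalys >= df$qalys[i] &
          (df$cost < df$cost[i] | df$qalys > df$qalys[i]))
  }, logical(1))
  extended <- logical(n)
  for (i in seq_len(n)) {
    if (strictly[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (j == i || k == i || j == k) next
        qj <- df$qalys[j]; qk <- df$qalys[k]
        if (qj >= qk) next
        if (df$qalys[i] < qj || df$qalys[i] > qk) next
        lam <- (df$qalys[i] - qj) / (qk - qj)
        blend_cost <- (1 - lam) * df$cost[j] + lam * df$cost[k]
        if (blend_cost < df$cost[i] - 1e-9) extended[i] <- TRUE
      }
    }
  }
  ifelse(strictly, "dominated",
         ifelse(extended, "weakly dominated", "frontier"))
}
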