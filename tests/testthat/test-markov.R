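test_that("a cycle with zero probabilities leaves the cohort untouched", {
  arm <- toy_arm(resolve_schedule(transition_schedule(1, Inf, 0), 60),
                 p_cancer_death = 0, p_g12 = 0, p_g34 = 0, p_disc = 0,
                 p_aed = 0)
  state <- list(pf = 0.6, pd = 0.3, dead_cancer = 0.05, dead_ae = 0,
                dead_other = 0.05)
  econ0 <- basecase$econ
  econ0$p_cancer_death_pd <- 0
  res <- markov_step(state, arm, econ0, p_allcause = 0, cycle = 1)
  expect_equal(res$state, state)
  expect_equal(unlist(res$events), c(ae_g12 = 0, ae_g34 = 0, discontinued = 0,
                                     ae_deaths = 0, hospitalized = 0))
})

test_that("within-cycle event ordering: deaths first, then progression", {
  # pf=1, p_cancer=0.05, p_allcause=0.001, progression 0.2:
  # deaths 1 - 0.95*0.999 = 0.05095; pd inflow 0.94905*0.2; pf 0.94905*0.8
  arm <- toy_arm(resolve_schedule(transition_schedule(1, Inf, 0.2), 60),
                 p_cancer_death = 0.05, p_disc = 0, p_aed = 0)
  state <- list(pf = 1, pd = 0, dead_cancer = 0, dead_ae = 0, dead_other = 0)
  res <- markov_step(state, arm, basecase$econ, p_allcause = 0.001, cycle = 1)
  expect_equal(res$state$pd, 0.18981, tolerance = 1e-10)
  expect_equal(res$state$pf, 0.75924, tolerance = 1e-10)
  expect_equal(res$state$dead_cancer + res$state$dead_other, 0.05095,
               tolerance = 1e-10)
})

test_that("toxicity fractions vanish outside the six-month window", {
  arm <- basecase$arms$ram_pac
  tr <- run_cohort(arm, basecase$econ, basecase$life_table, basecase$cohort)
  expect_true(all(tr$ae_g12[tr$cycle %in% 1:6] > 0))
  expect_true(all(tr$ae_g34[tr$cycle %in% 1:6] > 0))
  after <- tr$cycle > 6
  expect_equal(tr$ae_g12[after], rep(0, sum(after)))
  expect_equal(tr$ae_g34[after], rep(0, sum(after)))
  expect_equal(tr$discontinued[after], rep(0, sum(after)))
  expect_equal(tr$hospitalized[after], rep(0, sum(after)))
})

test_that("mass is conserved at every cycle for every base-case arm", {
  for (arm in basecase$arms) {
    tr <- run_cohort(arm, basecase$econ, basecase$life_table, basecase$cohort)
    total <- tr$pf + tr$pd + tr$dead_cancer + tr$dead_ae + tr$dead_other
    expect_true(all(abs(total - 1) < 1e-12))
    expect_true(all(tr[, c("pf", "pd")] >= 0))
  }
})

test_that("certain first-cycle progression empties the treated state", {
  arm <- toy_arm(resolve_schedule(transition_schedule(1, Inf, 1), 60),
                 p_cancer_death = 0, p_disc = 0, p_aed = 0)
  tr <- run_cohort(arm, basecase$econ, zero_life_table, basecase$cohort)
  expect_equal(tr$pf[tr$cycle >= 1], rep(0, 60))
  expect_equal(tr$pd[tr$cycle == 1], 1)
})

test_that("constant probabilities give the analytic geometric occupancy", {
  p_prog <- 0.15; p_cd <- 0.03
  arm <- toy_arm(resolve_schedule(transition_schedule(1, Inf, p_prog), 60),
                 p_cancer_death = p_cd, p_g12 = 0, p_g34 = 0, p_disc = 0,
                 p_aed = 0)
  tr <- run_cohort(arm, basecase$econ, zero_life_table, basecase$cohort)
  expected <- ((1 - p_cd) * (1 - p_prog))^(1:60)
  expect_equal(tr$pf[tr$cycle >= 1], expected, tolerance = 1e-12)
})

test_that("supportive-care occupancy matches an independent product oracle", {
  arm <- basecase$arms$bsc
  tr <- run_cohort(arm, basecase$econ, zero_life_table, basecase$cohort)
  p <- monthly_prob_at(arm$progression, 1:60)
  oracle_pf <- cumprod((1 - arm$p_cancer_death_pf) * (1 - p))
  expect_equal(tr$pf[tr$cycle >= 1], oracle_pf, tolerance = 1e-12)
  # progressed-state recursion oracle
  pd <- numeric(60)
  pf_prev <- 1
  for (c in 1:60) {
    inflow <- pf_prev * (1 - arm$p_cancer_death_pf) * p[c]
    pd[c] <- (if (c > 1) pd[c - 1] else 0) *
      (1 - basecase$econ$p_cancer_death_pd) + inflow
    pf_prev <- oracle_pf[c]
  }
  expect_equal(tr$pd[tr$cycle >= 1], pd, tolerance = 1e-12)
})

test_that("life years are person-time alive in the trace", {
  tr <- data.frame(cycle = 0:60, pf = c(1, rep(1, 60)), pd = 0,
                   dead_cancer = 0, dead_ae = 0, dead_other = 0,
                   ae_g12 = 0, ae_g34 = 0, discontinued = 0, ae_deaths = 0,
                   hospitalized = 0)
  class(tr) <- c("gc_trace", "data.frame")
  expect_equal(life_years(tr), 5)
  tr$pf <- c(1, rep(0.5, 12), rep(0, 48))
  expect_equal(life_years(tr), 0.5)
})

test_that("raising any hazard never increases life years", {
  set.seed(31)
  for (rep in 1:15) {
    sched <- resolve_schedule(random_schedule(60, max_prob = 0.3), 60)
    arm <- toy_arm(sched, p_cancer_death = runif(1, 0, 0.1),
                   p_disc = runif(1, 0, 0.03), p_aed = runif(1, 0, 0.01))
    base_ly <- life_years(run_cohort(arm, basecase$econ, basecase$life_table,
                                     basecase$cohort))
    bump <- arm
    what <- sample(c("prog", "cd", "aed"), 1)
    if (what == "prog") {
      bump$progression$prob <- pmin(1, bump$progression$prob + runif(1, 0, 0.2))
    } else if (what == "cd") {
      bump$p_cancer_death_pf <- min(1, bump$p_cancer_death_pf + runif(1, 0, 0.2))
    } else {
      bump$ae$p_death <- min(1, bump$ae$p_death + runif(1, 0, 0.05))
    }
    bumped_ly <- life_years(run_cohort(bump, basecase$econ,
                                       basecase$life_table, basecase$cohort))
    expect_lte(bumped_ly, base_ly + 1e-12)
  }
})

test_that("a pointwise-lower event schedule keeps more patients stable", {
  set.seed(32)
  for (rep in 1:10) {
    sched_hi <- resolve_schedule(random_schedule(60, max_prob = 0.4), 60)
    sched_lo <- sched_hi
    sched_lo$prob <- sched_lo$prob * runif(1, 0.3, 0.9)
    hi <- run_cohort(toy_arm(sched_hi), basecase$econ, basecase$life_table,
                     basecase$cohort)
    lo <- run_cohort(toy_arm(sched_lo), basecase$econ, basecase$life_table,
                     basecase$cohort)
    expect_true(all(lo$pf >= hi$pf - 1e-12))
  }
})
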