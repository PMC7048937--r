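#' Base value of a sensitivity parameter
#'
#' Multiplier-type parameters have base value 1; absolute parameters return
#' the current model value (e.g. the total monthly progression-free cost of
#' an arm for the drug-cost entries).
#'
#' @param model A `gc_model`.
#' @param id Sensitivity parameter id (see `model$sensitivity`).
#' @return Numeric base value.
#' @export
get_parameter <- function(model, id) {
  econ <- model$econ
  arm_total <- function(arm_id) {
    a <- model$arms[[arm_id]]
    a$drug_cost + a$admin_cost + econ$followup_cost_pf
  }
  switch(id,
    msi_h_prevalence = model$cohort$msi_h_prevalence,
    prog_pem_msi = 1, prog_other = 1,
    prog_bsc = 1, prog_pac = 1, prog_ram_pac = 1,
    prog_pem_agnostic = 1, prog_pem_pdl1 = 1,
    p_cancer_death_pd = 1,
    cost_pem = arm_total("pem_agnostic"),
    cost_pac = arm_total("pac"),
    cost_ram_pac = arm_total("ram_pac"),
    cost_bsc = econ$bsc_cost_pd,
    cost_ae_pem = model$arms$pem_agnostic$ae$cost_grade34,
    cost_ae_pac = model$arms$pac$ae$cost_grade34,
    cost_ae_ram_pac = model$arms$ram_pac$ae$cost_grade34,
    utility_pf = econ$utility_pf,
    utility_pd = econ$utility_pd,
    du12_pem = model$arms$pem_agnostic$ae$disutility_grade12,
    du34_pem = model$arms$pem_agnostic$ae$disutility_grade34,
    du12_pac = model$arms$pac$ae$disutility_grade12,
    du34_pac = model$arms$pac$ae$disutility_grade34,
    du12_ram_pac = model$arms$ram_pac$ae$disutility_grade12,
    du34_ram_pac = model$arms$ram_pac$ae$disutility_grade34,
    stop(sprintf("unknown sensitivity parameter '%s'", id), call. = FALSE)
  )
}

pem_arm_ids <- c("pem_agnostic", "pem_pdl1", "pem_msi")

# set an arm's total monthly PF cost by rescaling drug + administration
set_arm_total_cost <- function(model, arm_ids, total) {
  treat <- max(total - model$econ$followup_cost_pf, 0)
  for (id in arm_ids) {
    a <- model$arms[[id]]
    base_treat <- a$drug_cost + a$admin_cost
    f <- if (base_treat > 0) treat / base_treat else 0
    model$arms[[id]]$drug_cost <- a$drug_cost * f
    model$arms[[id]]$admin_cost <- a$admin_cost * f
  }
  model
}

#' Set a sensitivity parameter on a model
#'
#' Applies one parameter value (absolute value, or multiplier for the
#' `prog_*` / `p_cancer_death_pd` entries) to a fresh copy of the model.
#' Multipliers on probabilities are capped at 1. Drug-cost entries set the
#' arm's total monthly progression-free cost (drug + administration +
#' follow-up) by rescaling the treatment component; the pembrolizumab cost is
#' shared across its three biomarker schedules.
#'
#' @param model A `gc_model`.
#' @param id Parameter id.
#' @param value New value (or multiplier).
#' @return The modified model.
#' @export
set_parameter <- function(model, id, value) {
  sched_mult <- function(model, arm_ids, m) {
    for (a in arm_ids) {
      model$arms[[a]]$progression <- scale_schedule(model$arms[[a]]$progression, m)
    }
    model
  }
  prog_targets <- list(
    prog_pem_msi = "pem_msi", prog_bsc = "bsc", prog_pac = "pac",
    prog_ram_pac = "ram_pac", prog_pem_agnostic = "pem_agnostic",
    prog_pem_pdl1 = "pem_pdl1",
    prog_other = c("bsc", "pac", "ram_pac", "pem_agnostic", "pem_pdl1"))
  if (id %in% names(prog_targets)) {
    return(sched_mult(model, prog_targets[[id]], value))
  }
  switch(id,
    msi_h_prevalence = {
      check_prob(value, "msi_h_prevalence")
      model$cohort$msi_h_prevalence <- value
      model
    },
    p_cancer_death_pd = {
      model$econ$p_cancer_death_pd <- min(1, model$econ$p_cancer_death_pd * value)
      model
    },
    cost_pem = set_arm_total_cost(model, pem_arm_ids, value),
    cost_pac = set_arm_total_cost(model, "pac", value),
    cost_ram_pac = set_arm_total_cost(model, "ram_pac", value),
    cost_bsc = { model$econ$bsc_cost_pd <- max(value, 0); model },
    cost_ae_pem = {
      for (a in pem_arm_ids) model$arms[[a]]$ae$cost_grade34 <- max(value, 0)
      model
    },
    cost_ae_pac = { model$arms$pac$ae$cost_grade34 <- max(value, 0); model },
    cost_ae_ram_pac = { model$arms$ram_pac$ae$cost_grade34 <- max(value, 0); model },
    utility_pf = { model$econ$utility_pf <- value; model },
    utility_pd = { model$econ$utility_pd <- value; model },
    du12_pem = {
      for (a in pem_arm_ids) model$arms[[a]]$ae$disutility_grade12 <- value
      model
    },
    du34_pem = {
      for (a in pem_arm_ids) model$arms[[a]]$ae$disutility_grade34 <- value
      model
    },
    du12_pac = { model$arms$pac$ae$disutility_grade12 <- value; model },
    du34_pac = { model$arms$pac$ae$disutility_grade34 <- value; model },
    du12_ram_pac = { model$arms$ram_pac$ae$disutility_grade12 <- value; model },
    du34_ram_pac = { model$arms$ram_pac$ae$disutility_grade34 <- value; model },
    stop(sprintf("unknown sensitivity parameter '%s'", id), call. = FALSE)
  )
}

pairwise_icer <- function(model, comparison) {
  res <- evaluate_strategies(model, comparison)
  icer(as.list(res[res$id == comparison[2], ]),
       as.list(res[res$id == comparison[1], ]))
}

#' One-way sensitivity of an ICER to a single parameter
#'
#' Re-evaluates the stated pairwise comparison with the parameter at its low
#' and high bound, everything else at base values.
#'
#' @param model A `gc_model`.
#' @param id Sensitivity parameter id.
#' @param low,high Bounds; default from the model's sensitivity table.
#' @param comparison Character pair `c(strategy, comparator)`; default the
#'   MSI-guided pembrolizumab strategy versus paclitaxel for all.
#' @return List with `icer_base`, `icer_low`, `icer_high`.
#' @export
one_way <- function(model, id, low = NULL, high = NULL,
                    comparison = c("msi_pem_pac", "pac_all")) {
  entry <- model$sensitivity[[id]]
  if (is.null(low)) low <- entry$low
  if (is.null(high)) high <- entry$high
  if (is.null(low) || is.null(high) || low > high) {
    stop(sprintf("invalid bounds for parameter '%s'", id), call. = FALSE)
  }
  list(
    id = id,
    icer_base = pairwise_icer(model, comparison),
    icer_low = pairwise_icer(set_parameter(model, id, low), comparison),
    icer_high = pairwise_icer(set_parameter(model, id, high), comparison)
  )
}

#' Tornado table over every sensitivity parameter
#'
#' One row per entry of the model's sensitivity table (Table-2 shape), giving
#' the ICER of the comparison at the low and high bound and the bar width.
#'
#' @inheritParams one_way
#' @return A tibble sorted by decreasing bar width.
#' @export
tornado <- function(model, comparison = c("msi_pem_pac", "pac_all")) {
  base <- pairwise_icer(model, comparison)
  rows <- lapply(model$sensitivity, function(e) {
    ow <- one_way(model, e$id, comparison = comparison)
    tibble::tibble(id = e$id, label = e$label, low = e$low, high = e$high,
                   icer_low = ow$icer_low, icer_high = ow$icer_high,
                   width = abs(ow$icer_high - ow$icer_low))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  attr(out, "icer_base") <- base
  out
}

draw_parameter <- function(entry, base, n) {
  lo <- entry$low; hi <- entry$high
  x <- switch(entry$distribution,
    uniform = stats::runif(n, lo, hi),
    beta = {
      m <- base; v <- entry$sd^2
      k <- m * (1 - m) / v - 1
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    gamma = {
      shape <- (base / entry$sd)^2
      stats::rgamma(n, shape = shape, rate = base / entry$sd^2)
    },
    normal = {
      # printed range read as a 95% interval around the base value
      sdev <- if (!is.na(entry$sd)) entry$sd else (hi - lo) / (2 * stats::qnorm(0.975))
      mu <- if (entry$type == "multiplier") 1 else base
      pmax(stats::rnorm(n, mu, sdev), 0)
    })
  x
}

#' Probabilistic sensitivity analysis
#'
#' Draws all sensitivity parameters jointly from their distributions
#' (truncating normals at 0 and probabilities at 1), re-evaluates the two
#' compared strategies per draw, and classifies each draw by the sign of the
#' incremental net monetary benefit at the willingness-to-pay threshold.
#' Entries flagged `psa_independent` (the progression multipliers for the
#' non-MSI schedules) receive an independent draw per schedule.
#'
#' @param model A `gc_model`.
#' @param comparison Character pair `c(strategy, comparator)`.
#' @param n Number of Monte Carlo samples.
#' @param seed Optional integer seed for reproducibility.
#' @param wtp Willingness to pay; defaults to the model's.
#' @return A `gc_psa` list: `samples` tibble (`dcost`, `dqaly`, `nmb`, `ce`),
#'   `fraction_ce`, `n`, `comparison`, `wtp`.
#' @export
psa <- function(model, comparison = c("pac_all", "bsc_all"), n = 10000,
                seed = NULL, wtp = model$econ$wtp) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model$sensitivity)) {
    stop("model has no sensitivity specification", call. = FALSE)
  }

  draws <- list()
  for (e in model$sensitivity) {
    if (e$psa_independent && !is.null(e$applies)) {
      for (t in e$applies) {
        draws[[paste0("prog_", t)]] <- draw_parameter(e, 1, n)
      }
    } else {
      draws[[e$id]] <- draw_parameter(e, get_parameter(model, e$id), n)
    }
  }
  # prevalence must stay a probability
  if (!is.null(draws$msi_h_prevalence)) {
    draws$msi_h_prevalence <- pmin(pmax(draws$msi_h_prevalence, 0), 1)
  }

  p_ac <- all_cause_vector(model$life_table, model$cohort)
  dcost <- numeric(n); dqaly <- numeric(n)
  for (i in seq_len(n)) {
    m_i <- model
    for (id in names(draws)) m_i <- set_parameter(m_i, id, draws[[id]][i])
    res <- evaluate_strategies(m_i, comparison, p_allcause = p_ac)
    a <- res[res$id == comparison[1], ]
    b <- res[res$id == comparison[2], ]
    dcost[i] <- a$cost - b$cost
    dqaly[i] <- a$qalys - b$qalys
  }
  nmb <- dqaly * wtp - dcost
  samples <- tibble::tibble(draw = seq_len(n), dcost = dcost, dqaly = dqaly,
                            nmb = nmb, ce = nmb > 0)
  structure(list(samples = samples, fraction_ce = mean(samples$ce),
                 n = n, comparison = comparison, wtp = wtp),
            class = "gc_psa")
}

#' @export
print.gc_psa <- function(x, ...) {
  cat(sprintf("PSA: %s vs %s, %d draws, WTP $%s/QALY\n",
              x$comparison[1], x$comparison[2], x$n,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  cost-effective in %.1f%% of draws\n", 100 * x$fraction_ce))
  invisible(x)
}

#' Break-even monthly price of a drug component
#'
#' Bisects the monthly drug-acquisition cost of the priced arm until the ICER
#' of `strategy` versus `comparator` equals the willingness-to-pay threshold
#' (to $1). Monotonicity of the ICER in the price is verified at the bracket
#' ends.
#'
#' @param model A `gc_model`.
#' @param strategy,comparator Strategy ids.
#' @param arm_ids Arms whose `drug_cost` is re-priced (default: the three
#'   pembrolizumab schedules, which share one acquisition price).
#' @param wtp Willingness to pay.
#' @param tol Price tolerance in USD.
#' @return List with `price` (USD/month), `icer_at_price`, and `converged`;
#'   if the ICER never crosses `wtp` on `[0, base price]`, `converged` is
#'   FALSE and `price` reports the bracket end closer to the target.
#' @export
threshold_price <- function(model, strategy = "msi_pem_pac",
                            comparator = "pac_all", arm_ids = pem_arm_ids,
                            wtp = model$econ$wtp, tol = 1) {
  base_price <- model$arms[[arm_ids[1]]]$drug_cost
  at_price <- function(p) {
    m <- model
    for (a in arm_ids) m$arms[[a]]$drug_cost <- p
    pairwise_icer(m, c(strategy, comparator))
  }
  f_lo <- at_price(0); f_hi <- at_price(base_price)
  if (f_lo >= f_hi) stop("ICER is not increasing in the component price",
                         call. = FALSE)
  if (wtp <= f_lo || wtp >= f_hi) {
    nearer <- if (abs(wtp - f_lo) < abs(wtp - f_hi)) 0 else base_price
    return(list(price = nearer, icer_at_price = at_price(nearer),
                converged = FALSE))
  }
  lo <- 0; hi <- base_price
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (at_price(mid) < wtp) lo <- mid else hi <- mid
  }
  price <- (lo + hi) / 2
  list(price = price, icer_at_price = at_price(price), converged = TRUE)
}

#' Outcomes of a biomarker strategy across a prevalence grid
#'
#' @param model A `gc_model`.
#' @param prevalences Grid of biomarker-positive prevalences.
#' @param strategy Biomarker-split strategy id.
#' @param comparator Strategy id the ICER is taken against.
#' @return A tibble with `prevalence`, `cost`, `life_years`, `qalys`, `icer`.
#' @export
prevalence_sweep <- function(model, prevalences = seq(0.02, 0.22, by = 0.02),
                             strategy = "msi_pem_pac", comparator = "pac_all") {
  stopifnot(all(prevalences >= 0 & prevalences <= 1))
  st <- model$strategies[[strategy]]
  if (is.null(st) || st$kind != "biomarker_split") {
    stop("prevalence sweep needs a biomarker-split strategy", call. = FALSE)
  }
  rows <- lapply(prevalences, function(p) {
    m <- model
    if (st$biomarker == "msi") m$cohort$msi_h_prevalence <- p
    else m$cohort$pdl1_pos_prevalence <- p
    res <- evaluate_strategies(m, c(strategy, comparator))
    a <- as.list(res[res$id == strategy, ])
    b <- as.list(res[res$id == comparator, ])
    tibble::tibble(prevalence = p, cost = a$cost, life_years = a$life_years,
                   qalys = a$qalys, icer = icer(b, a))
  })
  do.call(rbind, rows)
}
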