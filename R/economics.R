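#' Discount multiplier for a monthly cycle
#'
#' Continuous-by-cycle form of annual discounting: `(1 + rate)^(-cycle/12)`,
#' applied at cycle start.
#'
#' @param cycle Cycle index (0-based; vectorised).
#' @param annual_rate Annual discount rate in \[0, 1).
#' @return Discount multiplier(s).
#' @examples
#' discount_factor(12, 0.03)  # one year out: 1/1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  (1 + annual_rate)^(-cycle / 12)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle `c` with discount `d(c)`:
#' cost accrues `pf * (drug + administration + follow-up)` (for the
#' supportive-care arm the home-care cost replaces drug + administration),
#' `pd * bsc_cost`, and `hospitalized * cost_grade34`; utility accrues
#' `(pf * u_pf + pd * u_pd - toxicity disutilities) / 12`, floored at zero
#' with a warning should disutilities exceed the state utilities. The one-time
#' biomarker test cost is charged at cycle 0, undiscounted. Life years are
#' undiscounted; costs and QALYs are discounted.
#'
#' @param trace A `gc_trace` from [run_cohort()].
#' @param arm The `gc_arm` that generated the trace.
#' @param econ Economics settings.
#' @param test_cost One-time biomarker test cost (0 for uniform strategies).
#' @param name Strategy or arm label to carry on the outcome.
#' @return A `gc_outcome` list: `strategy`, `cost` (discounted USD),
#'   `life_years` (undiscounted), `qalys` (discounted).
#' @export
accrue <- function(trace, arm, econ, test_cost = 0, name = arm$label) {
  keep <- trace$cycle >= 1
  cyc <- trace$cycle[keep]
  d <- discount_factor(cyc, econ$annual_discount)

  pf_cost <- if (arm$pf_cost_from_bsc) {
    econ$bsc_cost_pd + econ$followup_cost_pf
  } else {
    arm$drug_cost + arm$admin_cost + econ$followup_cost_pf
  }
  cost_cycle <- trace$pf[keep] * pf_cost +
    trace$pd[keep] * econ$bsc_cost_pd +
    trace$hospitalized[keep] * arm$ae$cost_grade34
  total_cost <- test_cost + sum(d * cost_cycle)

  util_cycle <- trace$pf[keep] * econ$utility_pf +
    trace$pd[keep] * econ$utility_pd -
    (trace$ae_g12[keep] * arm$ae$disutility_grade12 +
       trace$ae_g34[keep] * arm$ae$disutility_grade34)
  if (any(util_cycle < 0)) {
    warning("negative per-cycle utility floored at 0")
    util_cycle <- pmax(util_cycle, 0)
  }
  qalys <- sum(d * util_cycle) / 12

  structure(list(strategy = name, cost = total_cost,
                 life_years = life_years(trace), qalys = qalys),
            class = "gc_outcome")
}

#' @export
print.gc_outcome <- function(x, ...) {
  cat(sprintf("%s: cost $%.0f, %.3f life years, %.3f QALYs\n",
              x$strategy, x$cost, x$life_years, x$qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_b - cost_a) / (qalys_b - qalys_a)`; `b` must deliver strictly more
#' QALYs than `a` (dominance is the frontier's business, not the ratio's).
#'
#' @param a,b `gc_outcome` objects (or lists with `cost` and `qalys`).
#' @return USD per QALY gained.
#' @export
icer <- function(a, b) {
  dq <- b$qalys - a$qalys
  if (dq <= 0) {
    stop("ICER undefined: comparator must gain QALYs (dominance context)",
         call. = FALSE)
  }
  (b$cost - a$cost) / dq
}

#' Net monetary benefit
#'
#' @param outcome A `gc_outcome`.
#' @param wtp Willingness to pay, USD per QALY.
#' @return `qalys * wtp - cost` in USD.
#' @export
net_monetary_benefit <- function(outcome, wtp) {
  stopifnot(wtp >= 0)
  outcome$qalys * wtp - outcome$cost
}
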