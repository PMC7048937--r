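#' Advance the cohort one monthly cycle
#'
#' Within a cycle, events are ordered as follows. (1) Progression-free (PF)
#' patients die from the three competing causes, combined multiplicatively:
#' `1 - (1 - p_cancer)(1 - p_allcause)(1 - p_ae_death)`, the adverse-event
#' death cause active only during the toxicity window (first six months of
#' treatment). (2) Surviving PF patients move to progressive disease with the
#' schedule probability for that cycle plus the treatment-discontinuation
#' probability (window only), capped at 1; patients who discontinue enter the
#' progressed state and receive third-line best supportive care. (3) Patients
#' already progressed at cycle start die from cancer-specific (3L BSC) or
#' all-cause mortality, again combined multiplicatively; new arrivals join the
#' progressed state at cycle end. Deaths are attributed to causes in
#' proportion to the single-cause probabilities.
#'
#' Toxicity event fractions (grade 1/2, grade 3/4, discontinuation) are
#' recorded against the fraction still on treatment (end-of-cycle PF) during
#' the toxicity window and are zero afterwards.
#'
#' @param state Named list/vector with `pf`, `pd`, `dead_cancer`, `dead_ae`,
#'   `dead_other` fractions summing to 1.
#' @param arm A `gc_arm`.
#' @param econ Economics settings from a `gc_model`.
#' @param p_allcause Monthly all-cause death probability for this cycle.
#' @param cycle Cycle index (1-based).
#' @return List with the new `state` and the cycle's `events` (fractions:
#'   `ae_g12`, `ae_g34`, `discontinued`, `ae_deaths`, `hospitalized`).
#' @export
markov_step <- function(state, arm, econ, p_allcause, cycle) {
  in_window <- cycle <= arm$ae$window
  p_aed <- if (in_window) arm$ae$p_death else 0
  p_cd <- arm$p_cancer_death_pf

  p_death_pf <- 1 - (1 - p_cd) * (1 - p_allcause) * (1 - p_aed)
  tot <- p_cd + p_allcause + p_aed
  share <- if (tot > 0) c(p_cd, p_aed, p_allcause) / tot else c(0, 0, 0)
  pf_deaths <- state$pf * p_death_pf

  surv <- state$pf - pf_deaths
  p_prog <- monthly_prob_at(arm$progression, cycle)
  p_disc <- if (in_window) arm$ae$p_discontinuation else 0
  p_move <- min(1, p_prog + p_disc)
  new_pd <- surv * p_move
  pf_new <- surv - new_pd

  p_death_pd <- 1 - (1 - econ$p_cancer_death_pd) * (1 - p_allcause)
  pd_deaths <- state$pd * p_death_pd
  tot_pd <- econ$p_cancer_death_pd + p_allcause
  share_pd <- if (tot_pd > 0) c(econ$p_cancer_death_pd, p_allcause) / tot_pd else c(0, 0)
  pd_new <- state$pd - pd_deaths + new_pd

  new_state <- list(
    pf = pf_new,
    pd = pd_new,
    dead_cancer = state$dead_cancer + pf_deaths * share[1] + pd_deaths * share_pd[1],
    dead_ae = state$dead_ae + pf_deaths * share[2],
    dead_other = state$dead_other + pf_deaths * share[3] + pd_deaths * share_pd[2]
  )
  if (any(unlist(new_state) < -1e-12)) {
    stop("internal consistency error: negative state fraction", call. = FALSE)
  }
  total <- sum(unlist(new_state))
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("internal consistency error: mass not conserved (%.3e)",
                 total - 1), call. = FALSE)
  }

  has_treatment <- arm$ae$p_grade12 > 0 || arm$ae$p_grade34 > 0
  g34 <- if (in_window) pf_new * arm$ae$p_grade34 else 0
  events <- list(
    ae_g12 = if (in_window) pf_new * arm$ae$p_grade12 else 0,
    ae_g34 = g34,
    discontinued = if (in_window) surv * p_disc else 0,
    ae_deaths = pf_deaths * share[2],
    hospitalized = if (!in_window || !has_treatment) 0
      else if (econ$hospitalization_mode == "grade34") g34
      else pf_new * econ$p_hospitalization
  )
  list(state = new_state, events = events)
}

#' Propagate a cohort through all cycles for one treatment arm
#'
#' Starts the whole cohort progression-free at cycle 0 and applies
#' [markov_step()] for cycles 1..horizon, advancing attained age by 1/12 year
#' per cycle for the all-cause mortality lookup.
#'
#' @param arm A `gc_arm`.
#' @param econ Economics settings.
#' @param life_table A `gc_life_table`.
#' @param cohort Cohort settings (start age, male fraction, horizon).
#' @param p_allcause Optional precomputed vector of monthly all-cause death
#'   probabilities for cycles 1..horizon (a small speed-up for repeated runs).
#' @return A `gc_trace` data frame with one row per cycle 0..horizon: state
#'   occupancy (`pf`, `pd`, `dead_cancer`, `dead_ae`, `dead_other`), attained
#'   `age`, and per-cycle event fractions.
#' @examples
#' model <- load_model()
#' tr <- run_cohort(model$arms$bsc, model$econ, model$life_table, model$cohort)
#' life_years(tr)
#' @export
run_cohort <- function(arm, econ, life_table, cohort, p_allcause = NULL) {
  H <- cohort$horizon
  if (is.null(p_allcause)) p_allcause <- all_cause_vector(life_table, cohort)
  stopifnot(length(p_allcause) == H)

  cols <- c("pf", "pd", "dead_cancer", "dead_ae", "dead_other",
            "ae_g12", "ae_g34", "discontinued", "ae_deaths", "hospitalized")
  m <- matrix(0, nrow = H + 1, ncol = length(cols),
              dimnames = list(NULL, cols))
  m[1, "pf"] <- 1
  state <- list(pf = 1, pd = 0, dead_cancer = 0, dead_ae = 0, dead_other = 0)
  for (cycle in seq_len(H)) {
    res <- markov_step(state, arm, econ, p_allcause[cycle], cycle)
    state <- res$state
    m[cycle + 1, ] <- c(unlist(state), unlist(res$events))
  }
  tr <- data.frame(cycle = 0:H,
                   age = cohort$start_age + (0:H) / 12,
                   m, check.names = FALSE)
  attr(tr, "arm") <- arm$id
  class(tr) <- c("gc_trace", "data.frame")
  tr
}

#' Undiscounted life years from a cohort trace
#'
#' Sums person-time alive (progression-free plus progressed occupancy) over
#' cycles 1..horizon at 1/12 year per cycle; cycle-0 occupancy accrues
#' nothing (rewards follow post-transition membership, with no half-cycle
#' correction).
#'
#' @param trace A `gc_trace`.
#' @return Life years (undiscounted).
#' @export
life_years <- function(trace) {
  keep <- trace$cycle >= 1
  sum(trace$pf[keep] + trace$pd[keep]) / 12
}
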