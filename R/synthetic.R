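#' Simulate a Kaplan-Meier curve from a known transition schedule
#'
#' Draws one discrete event time per patient from the per-cycle hazards of
#' the schedule (matching the model's monthly-probability semantics), applies
#' independent geometric right-censoring, and returns the product-limit
#' estimate evaluated at whole months — the synthetic counterpart of a
#' digitized trial survival curve, used to stress-test the calibration stage.
#'
#' @param schedule A `gc_schedule` (finite, or closed at `horizon`).
#' @param n_patients Number of simulated patients.
#' @param censor_prob Per-cycle probability of censoring (applied at cycle
#'   end, so an event in the same cycle wins).
#' @param seed Optional integer seed; identical seeds give identical curves.
#' @param horizon Last cycle simulated; defaults to the schedule's end.
#' @return A `gc_km_curve` at months 0..horizon, with attributes `n_events`
#'   and `n_censored`.
#' @examples
#' sched <- transition_schedule(1, Inf, 0.1)
#' curve <- simulate_km(resolve_schedule(sched, 24), 500, seed = 1)
#' @export
simulate_km <- function(schedule, n_patients, censor_prob = 0, seed = NULL,
                        horizon = NULL) {
  stopifnot(n_patients >= 1, censor_prob >= 0, censor_prob < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(horizon)) horizon <- max(schedule$last)
  if (is.infinite(horizon)) stop("horizon must be finite", call. = FALSE)

  p <- monthly_prob_at(schedule, seq_len(horizon))
  u <- matrix(stats::runif(n_patients * horizon), nrow = n_patients)
  hit <- sweep(u, 2, p, `<`)
  event_time <- apply(hit, 1, function(r) {
    w <- which(r); if (length(w)) w[1] else Inf
  })
  censor_time <- if (censor_prob > 0) {
    stats::rgeom(n_patients, censor_prob) + 1
  } else {
    rep(Inf, n_patients)
  }
  time <- pmin(event_time, censor_time, horizon)
  status <- as.integer(event_time <= censor_time & event_time <= horizon)
  if (sum(status) == 0) {
    stop("degenerate curve: no events observed", call. = FALSE)
  }

  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  s <- summary(sf, times = 0:horizon, extend = TRUE)$surv
  curve <- km_curve(0:horizon, s)
  attr(curve, "n_events") <- sum(status)
  attr(curve, "n_censored") <- n_patients - sum(status)
  curve
}

#' Construct a Gompertz-like synthetic life table
#'
#' Annual all-cause mortality grows geometrically with age,
#' `q(age) = q_ref * factor^(age - ref_age)`, separately for men and women —
#' a plausible stand-in for national vital statistics over a narrow adult age
#' band.
#'
#' @param q_ref_male,q_ref_female Annual death probability at `ref_age`.
#' @param annual_factor Yearly multiplicative increase (>= 1).
#' @param ages Integer age range covered.
#' @param ref_age Reference age (default 60).
#' @return A `gc_life_table`.
#' @examples
#' lt <- make_life_table(0.0112, 0.0066, 1.085, ages = 55:70)
#' all_cause_monthly_prob(lt, 60, 0.7)
#' @export
make_life_table <- function(q_ref_male, q_ref_female, annual_factor,
                            ages = 55:70, ref_age = 60) {
  stopifnot(q_ref_male > 0, q_ref_male < 1, q_ref_female > 0, q_ref_female < 1,
            annual_factor >= 1)
  qm <- q_ref_male * annual_factor^(ages - ref_age)
  qf <- q_ref_female * annual_factor^(ages - ref_age)
  if (any(qm >= 1) || any(qf >= 1)) {
    stop("annual mortality exceeds 1 within the requested age range",
         call. = FALSE)
  }
  as_life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("male", "female"), each = length(ages)),
    annual_mortality = c(qm, qf)
  ))
}

#' Write a life table to delimited text
#'
#' @param life_table A `gc_life_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
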