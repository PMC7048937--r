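#' Kaplan-Meier curve container
#'
#' @param time Event/evaluation times in months, strictly increasing,
#'   starting at 0.
#' @param survival Survival fraction at each time; non-increasing with
#'   `survival[time == 0] == 1`. A missing time-0 point is prepended.
#' @return A `gc_km_curve` data frame with columns `time`, `survival`.
#' @export
km_curve <- function(time, survival) {
  ord <- order(time)
  time <- as.numeric(time[ord]); survival <- as.numeric(survival[ord])
  if (length(time) == 0) stop("empty curve", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (time[1] > 0) { time <- c(0, time); survival <- c(1, survival) }
  if (abs(survival[1] - 1) > 1e-12) {
    stop("survival at time 0 must be 1", call. = FALSE)
  }
  if (any(diff(survival) > 1e-12)) {
    stop("survival must be non-increasing", call. = FALSE)
  }
  if (any(survival < 0) || any(survival > 1)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(time = time, survival = survival),
            class = c("gc_km_curve", "data.frame"))
}

#' Read a KM curve from delimited text
#'
#' Expects a header `time_months,survival` (an optional `n_at_risk` column is
#' carried along untouched).
#'
#' @param path CSV path.
#' @return A `gc_km_curve`.
#' @export
read_km_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_months", "survival") %in% names(df))) {
    stop("KM file needs columns time_months, survival", call. = FALSE)
  }
  km_curve(df$time_months, df$survival)
}

#' Reconstruct a survival curve from a transition schedule
#'
#' `S(t) = prod_{c <= t} (1 - p_c)` evaluated at whole months 0..horizon; the
#' inverse of [fit_piecewise_probs()] on noiseless input.
#'
#' @param schedule A `gc_schedule`.
#' @param horizon Last month; defaults to the schedule's final segment end.
#' @return A `gc_km_curve`.
#' @export
schedule_to_survival <- function(schedule, horizon = NULL) {
  if (is.null(horizon)) horizon <- max(schedule$last)
  if (is.infinite(horizon)) stop("horizon must be finite", call. = FALSE)
  p <- monthly_prob_at(schedule, seq_len(horizon))
  km_curve(0:horizon, c(1, cumprod(1 - p)))
}

#' Fit piecewise-constant monthly probabilities to a survival curve
#'
#' Within each segment defined by the breakpoints, a single monthly event
#' probability is estimated by least squares on log-survival (survival decay
#' is linear in log space under a constant per-cycle probability), weighting
#' observations by the survival fraction as a proxy for the number still at
#' risk: the fitted slope `b` of `log S(t)` against `t` over the segment's
#' observation window gives `p = 1 - exp(b)`. With only the segment's
#' start/end observations this reduces to the geometric ratio
#' `p = 1 - (S_end/S_start)^(1/duration)`. Segments entered by few patients
#' carry irreducible sampling noise: the attainable precision is bounded by
#' the binomial error of the at-risk set, whatever the estimator.
#'
#' @param curve A `gc_km_curve` covering at least the last breakpoint.
#' @param breakpoints Strictly increasing cycle indices ending each segment
#'   except the last (e.g. `c(3, 10)` for segments 1-3, 4-10, 11-horizon).
#' @param horizon Final cycle of the last segment; defaults to the last whole
#'   month the curve covers.
#' @return A `gc_schedule`.
#' @examples
#' sched <- transition_schedule(c(1, 4, 11), c(3, 10, Inf), c(0.414, 0.347, 0.251))
#' curve <- schedule_to_survival(resolve_schedule(sched, 24))
#' fit_piecewise_probs(curve, breakpoints = c(3, 10))
#' @export
fit_piecewise_probs <- function(curve, breakpoints, horizon = NULL) {
  if (is.null(horizon)) horizon <- floor(max(curve$time))
  breakpoints <- sort(unique(as.numeric(breakpoints)))
  if (length(breakpoints) > 0 &&
      (any(breakpoints < 1) || any(breakpoints >= horizon))) {
    stop("breakpoints must lie strictly inside [1, horizon)", call. = FALSE)
  }
  if (max(curve$time) < max(c(breakpoints, 1))) {
    stop("curve does not cover the last breakpoint", call. = FALSE)
  }
  first <- c(1, breakpoints + 1)
  last <- c(breakpoints, horizon)

  log_s_at <- function(t) {
    # log-linear interpolation; exact at observed times
    pos <- curve$survival > 0
    stats::approx(curve$time[pos], log(curve$survival[pos]), xout = t,
                  rule = 2)$y
  }
  probs <- vapply(seq_along(first), function(i) {
    f <- first[i]; l <- last[i]
    win <- curve$time >= f - 1 & curve$time <= l
    t <- curve$time[win]; s <- curve$survival[win]
    keep <- s > 0
    if (sum(keep) < 2) {
      if (all(s == 0)) {
        stop("survival reaches zero before segment end (degenerate segment)",
             call. = FALSE)
      }
      t <- c(f - 1, l); ls <- log_s_at(t); w <- c(1, 1)
    } else {
      t <- t[keep]; ls <- log(s[keep])
      # weight by survival, a proxy for the number still at risk: late KM
      # steps are estimated from few patients and would otherwise dominate
      w <- s[keep]
    }
    mt <- sum(w * t) / sum(w)
    mls <- sum(w * ls) / sum(w)
    slope <- sum(w * (t - mt) * (ls - mls)) / sum(w * (t - mt)^2)
    min(max(1 - exp(slope), 0), 1)
  }, numeric(1))

  transition_schedule(first, last, probs)
}
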