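#' Piecewise-constant monthly transition schedule
#'
#' A transition schedule holds the probability of an event (disease
#' progression, in this model) per monthly cycle, constant within contiguous
#' cycle ranges. This mirrors the way trial survival curves are summarised:
#' one monthly probability per follow-up segment, the last segment held
#' constant out to the model horizon.
#'
#' @param first Integer vector of first cycles of each segment (cycle 1 is the
#'   first month on treatment).
#' @param last Integer vector of last cycles (inclusive); the final entry may
#'   be `Inf` meaning "to the horizon".
#' @param prob Monthly event probability per segment, each in \[0, 1\].
#' @return A `gc_schedule` data frame with columns `first`, `last`, `prob`.
#' @examples
#' sched <- transition_schedule(c(1, 4, 11), c(3, 10, Inf), c(0.414, 0.347, 0.251))
#' monthly_prob_at(sched, 7)
#' @export
transition_schedule <- function(first, last, prob) {
  if (length(first) != length(last) || length(first) != length(prob)) {
    stop("first, last and prob must have equal length", call. = FALSE)
  }
  s <- data.frame(first = as.numeric(first), last = as.numeric(last),
                  prob = as.numeric(prob))
  s <- s[order(s$first), , drop = FALSE]
  rownames(s) <- NULL
  if (any(!is.finite(s$prob)) || any(s$prob < 0) || any(s$prob > 1)) {
    stop("schedule probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(s$last < s$first)) {
    stop("segment end before segment start", call. = FALSE)
  }
  if (nrow(s) > 1 && any(s$first[-1] != s$last[-nrow(s)] + 1)) {
    stop("schedule segments must be contiguous and non-overlapping", call. = FALSE)
  }
  class(s) <- c("gc_schedule", "data.frame")
  s
}

#' Resolve a schedule against a model horizon
#'
#' Closes an open-ended (`Inf`) final segment at `horizon` and checks that the
#' segments partition cycles `1..horizon` exactly.
#'
#' @param schedule A `gc_schedule`.
#' @param horizon Number of monthly cycles.
#' @return The schedule with a finite final segment.
#' @export
resolve_schedule <- function(schedule, horizon) {
  n <- nrow(schedule)
  if (is.infinite(schedule$last[n])) schedule$last[n] <- horizon
  if (schedule$first[1] != 1 || schedule$last[n] != horizon) {
    stop(sprintf("schedule must cover cycles 1..%d (covers %d..%d)",
                 horizon, schedule$first[1], schedule$last[n]), call. = FALSE)
  }
  schedule
}

#' Monthly event probability at a given cycle
#'
#' @param schedule A `gc_schedule`.
#' @param cycle Cycle index (vectorised).
#' @return Probability per cycle of the segment containing `cycle`.
#' @export
monthly_prob_at <- function(schedule, cycle) {
  idx <- findInterval(cycle, schedule$first)
  if (any(idx == 0) || any(cycle > schedule$last[pmax(idx, 1)])) {
    stop("cycle outside schedule coverage", call. = FALSE)
  }
  schedule$prob[idx]
}

#' @export
print.gc_schedule <- function(x, ...) {
  cat("Monthly transition schedule:\n")
  for (i in seq_len(nrow(x))) {
    end <- if (is.infinite(x$last[i])) "+" else paste0("-", x$last[i])
    cat(sprintf("  cycles %d%s: p = %.6g\n", x$first[i], end, x$prob[i]))
  }
  invisible(x)
}

# scale all segment probabilities, capping at 1 (used by sensitivity analyses)
scale_schedule <- function(schedule, mult) {
  schedule$prob <- pmin(1, pmax(0, schedule$prob * mult))
  schedule
}
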