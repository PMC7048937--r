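#' Evaluate one treatment strategy
#'
#' Uniform strategies run a single cohort on the strategy's arm. Biomarker
#' strategies run the biomarker-positive and biomarker-negative sub-cohorts
#' independently (each on its own transition schedules) and combine their
#' outcomes as a prevalence-weighted mixture, adding the one-time test cost
#' for the whole cohort. Cohort models are linear in the initial distribution,
#' so the split simulation is exact.
#'
#' @param strategy A strategy entry from a `gc_model` (or its id).
#' @param model A `gc_model`.
#' @param arm_cache Optional environment memoising per-arm outcomes (used
#'   internally when evaluating many strategies against one parameter set).
#' @return A `gc_outcome`.
#' @examples
#' model <- load_model()
#' evaluate_strategy("pac_all", model)
#' @export
evaluate_strategy <- function(strategy, model, arm_cache = NULL) {
  if (is.character(strategy)) {
    strategy <- model$strategies[[strategy]] %||%
      stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
  }
  arm_outcome <- function(arm_id) {
    if (!is.null(arm_cache) && !is.null(arm_cache[[arm_id]])) {
      return(arm_cache[[arm_id]])
    }
    arm <- model$arms[[arm_id]]
    if (is.null(arm)) {
      stop(sprintf("strategy '%s': missing arm/schedule '%s'",
                   strategy$id, arm_id), call. = FALSE)
    }
    pac_vec <- if (!is.null(arm_cache) && !is.null(arm_cache$.p_allcause)) {
      arm_cache$.p_allcause
    } else {
      all_cause_vector(model$life_table, model$cohort)
    }
    tr <- run_cohort(arm, model$econ, model$life_table, model$cohort,
                     p_allcause = pac_vec)
    out <- accrue(tr, arm, model$econ, test_cost = 0)
    if (!is.null(arm_cache)) arm_cache[[arm_id]] <- out
    out
  }

  if (strategy$kind == "uniform") {
    out <- arm_outcome(strategy$arm)
    out$strategy <- strategy$name
    return(out)
  }
  prev <- switch(strategy$biomarker,
                 msi = model$cohort$msi_h_prevalence,
                 pdl1 = model$cohort$pdl1_pos_prevalence)
  pos <- arm_outcome(strategy$positive_arm)
  neg <- arm_outcome(strategy$negative_arm)
  structure(list(
    strategy = strategy$name,
    cost = strategy$test_cost + prev * pos$cost + (1 - prev) * neg$cost,
    life_years = prev * pos$life_years + (1 - prev) * neg$life_years,
    qalys = prev * pos$qalys + (1 - prev) * neg$qalys
  ), class = "gc_outcome")
}

#' Evaluate several strategies against one parameter set
#'
#' Memoises per-arm cohort runs so arms shared between strategies are
#' simulated once.
#'
#' @param model A `gc_model`.
#' @param ids Strategy ids (default: all).
#' @param p_allcause Optional precomputed all-cause mortality vector (see
#'   [run_cohort()]).
#' @return A tibble with one row per strategy: `id`, `strategy`, `cost`,
#'   `life_years`, `qalys`.
#' @export
evaluate_strategies <- function(model, ids = names(model$strategies),
                                p_allcause = NULL) {
  cache <- new.env(parent = emptyenv())
  cache$.p_allcause <- p_allcause %||%
    all_cause_vector(model$life_table, model$cohort)
  rows <- lapply(ids, function(id) {
    out <- evaluate_strategy(id, model, arm_cache = cache)
    tibble::tibble(id = id, strategy = out$strategy, cost = out$cost,
                   life_years = out$life_years, qalys = out$qalys)
  })
  do.call(rbind, rows)
}

#' Evaluate all strategies of a model
#'
#' @param model A `gc_model`.
#' @return A tibble of outcomes, one row per strategy.
#' @export
evaluate_all <- function(model) evaluate_strategies(model)

#' Efficiency frontier with strict and extended dominance
#'
#' Sorts strategies by cost and labels each `frontier`, `dominated` (some
#' strategy costs no more and yields at least as many QALYs, one strictly), or
#' `weakly dominated` (removed to restore a strictly increasing ICER sequence
#' along the frontier — the standard extended-dominance convex-hull
#' construction). Frontier members carry the ICER against the previous
#' frontier point.
#'
#' @param outcomes A data frame/tibble with columns `strategy`, `cost`,
#'   `qalys` (and optionally `life_years`), e.g. from [evaluate_all()].
#' @return The input sorted by cost with `status` and `icer` columns.
#' @export
efficiency_frontier <- function(outcomes) {
  df <- as.data.frame(outcomes)
  if (nrow(df) < 1) stop("need at least one outcome", call. = FALSE)
  # deterministic order: cost asc, then qalys desc, then name
  df <- df[order(df$cost, -df$qalys, df$strategy), , drop = FALSE]
  n <- nrow(df)

  dominated <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qalys >= df$qalys[i] &
          (df$cost < df$cost[i] | df$qalys > df$qalys[i]))
  }, logical(1))

  # exact ties in both cost and qalys: keep the first in sort order (name
  # tie-break), treat the rest as dominated
  nd <- which(!dominated)
  if (length(nd) > 1) {
    key <- paste(df$cost[nd], df$qalys[nd])
    dup <- nd[duplicated(key)]
    if (length(dup) > 0) {
      message("tie in cost and QALYs broken by strategy name")
      dominated[dup] <- TRUE
    }
  }

  cand <- which(!dominated)  # already in increasing cost AND increasing qaly
  weakly <- logical(n)
  repeat {
    if (length(cand) < 3) break
    ic <- diff(df$cost[cand]) / diff(df$qalys[cand])
    bad <- which(diff(ic) <= 0)  # ICER not strictly increasing
    if (length(bad) == 0) break
    drop <- cand[bad[1] + 1]     # interior point breaking monotonicity
    weakly[drop] <- TRUE
    cand <- setdiff(cand, drop)
  }

  status <- ifelse(dominated, "dominated",
                   ifelse(weakly, "weakly dominated", "frontier"))
  icer_col <- rep(NA_real_, n)
  if (length(cand) > 1) {
    icer_col[cand[-1]] <- diff(df$cost[cand]) / diff(df$qalys[cand])
  }
  df$status <- status
  df$icer <- icer_col
  tibble::as_tibble(df)
}
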