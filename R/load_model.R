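#' Path to the packaged base-case configuration
#'
#' @return Path to the YAML file holding the full base-case parameter set.
#' @export
gc_example_config <- function() {
  system.file("extdata", "basecase.yaml", package = "gc2lcea", mustWork = TRUE)
}

#' Path to the packaged synthetic life table
#'
#' A Gompertz-like adult life table (ages 55-70, male and female) constructed
#' with [make_life_table()] to emulate US all-cause mortality around age 60
#' (roughly 1%/year). It is a synthetic stand-in, not published vital
#' statistics; its values are a small, documented tolerance source.
#'
#' @return Path to the CSV life table.
#' @export
gc_example_life_table <- function() {
  system.file("extdata", "lifetable_synthetic_2014us.csv",
              package = "gc2lcea", mustWork = TRUE)
}

# Month labels count from 0 at treatment start, so month m is simulated by
# cycle m + 1: "0-3" -> cycles 1..4, "2-9" -> 3..10, "11+" -> 12..Inf.
parse_month_range <- function(label) {
  label <- trimws(label)
  if (grepl("^\\d+\\+$", label)) {
    a <- as.integer(sub("\\+$", "", label))
    c(a + 1L, Inf)
  } else if (grepl("^\\d+-\\d+$", label)) {
    ab <- as.integer(strsplit(label, "-")[[1]])
    c(ab[1] + 1L, ab[2] + 1L)
  } else {
    stop(sprintf("cannot parse month range '%s'", label), call. = FALSE)
  }
}

parse_progression <- function(rows, horizon) {
  rng <- lapply(rows, function(r) parse_month_range(r$months))
  sched <- transition_schedule(
    first = vapply(rng, `[`, numeric(1), 1),
    last  = vapply(rng, `[`, numeric(1), 2),
    prob  = vapply(rows, function(r) as.numeric(r$p), numeric(1))
  )
  resolve_schedule(sched, horizon)
}

zero_ae_profile <- function(window) {
  list(p_grade12 = 0, p_grade34 = 0, p_discontinuation = 0, p_death = 0,
       cost_grade34 = 0, disutility_grade12 = 0, disutility_grade34 = 0,
       window = window)
}

parse_ae_profile <- function(ae, window) {
  if (is.null(ae)) return(zero_ae_profile(window))
  prof <- list(
    p_grade12 = as.numeric(ae$p_grade12),
    p_grade34 = as.numeric(ae$p_grade34),
    p_discontinuation = as.numeric(ae$p_discontinuation),
    p_death = as.numeric(ae$p_death),
    cost_grade34 = as.numeric(ae$cost_grade34),
    disutility_grade12 = as.numeric(ae$disutility_grade12),
    disutility_grade34 = as.numeric(ae$disutility_grade34),
    window = window
  )
  for (f in c("p_grade12", "p_grade34", "p_discontinuation", "p_death")) {
    check_prob(prof[[f]], paste0("adverse_events.", f))
  }
  if (prof$cost_grade34 < 0) stop("adverse event cost must be >= 0", call. = FALSE)
  if (prof$disutility_grade12 < 0 || prof$disutility_grade34 < 0) {
    stop("disutilities are stored as magnitudes and must be >= 0", call. = FALSE)
  }
  prof
}

check_prob <- function(x, what) {
  if (is.null(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1] (got %s)",
                 what, format(x)), call. = FALSE)
  }
  invisible(x)
}

make_arm <- function(id, label, drug_cost, admin_cost, p_cancer_death,
                     progression, ae, pf_cost_from_bsc = FALSE) {
  check_prob(p_cancer_death, paste0("arms.", id, ".p_cancer_death"))
  if (drug_cost < 0 || admin_cost < 0) {
    stop(sprintf("costs for arm '%s' must be >= 0", id), call. = FALSE)
  }
  structure(list(id = id, label = label, drug_cost = drug_cost,
                 admin_cost = admin_cost, p_cancer_death_pf = p_cancer_death,
                 progression = progression, ae = ae,
                 pf_cost_from_bsc = isTRUE(pf_cost_from_bsc)),
            class = "gc_arm")
}

#' Load and validate a complete model specification
#'
#' Reads the YAML configuration (cohort, economics, treatment arms, the eight
#' strategies, and the sensitivity-analysis table), checks every structural
#' invariant (probabilities in \[0, 1\], schedules partitioning the horizon,
#' biomarker strategies referencing a known prevalence and test cost), and
#' attaches the life table.
#'
#' @param config_path YAML configuration; defaults to the packaged base case.
#' @param life_table_path CSV life table; defaults to the packaged synthetic
#'   table.
#' @return A `gc_model` list with elements `cohort`, `econ`, `arms`,
#'   `strategies`, `sensitivity`, `life_table`.
#' @examples
#' model <- load_model()
#' names(model$arms)
#' @export
load_model <- function(config_path = gc_example_config(),
                       life_table_path = gc_example_life_table()) {
  if (!file.exists(config_path)) {
    stop(sprintf("config file '%s' not found", config_path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(config_path)
  for (key in c("cohort", "economics", "biomarker_tests", "arms", "strategies")) {
    if (is.null(cfg[[key]])) stop(sprintf("config is missing '%s'", key), call. = FALSE)
  }

  co <- cfg$cohort
  cohort <- list(
    start_age = as.numeric(co$start_age),
    male_fraction = as.numeric(co$male_fraction),
    msi_h_prevalence = as.numeric(co$msi_h_prevalence),
    pdl1_pos_prevalence = as.numeric(co$pdl1_pos_prevalence),
    horizon = as.integer(co$horizon),
    cycle_length_months = as.numeric(co$cycle_length_months)
  )
  check_prob(cohort$male_fraction, "cohort.male_fraction")
  check_prob(cohort$msi_h_prevalence, "cohort.msi_h_prevalence")
  check_prob(cohort$pdl1_pos_prevalence, "cohort.pdl1_pos_prevalence")
  if (cohort$horizon <= 0) stop("cohort.horizon must be > 0", call. = FALSE)

  ec <- cfg$economics
  # follow-up bundle: either itemised (gp/oncology/radiology) or pre-summed
  fu_pf <- if (!is.null(ec$followup_cost_pf)) {
    as.numeric(ec$followup_cost_pf)
  } else {
    fu <- ec$followup_cost
    as.numeric(fu$gp) + as.numeric(fu$oncology) + as.numeric(fu$radiology)
  }
  econ <- list(
    annual_discount = as.numeric(ec$annual_discount),
    wtp = as.numeric(ec$wtp),
    followup_cost_pf = fu_pf,
    bsc_cost_pd = as.numeric(ec$bsc_cost_pd),
    utility_pf = as.numeric(ec$utility_pf),
    utility_pd = as.numeric(ec$utility_pd),
    p_cancer_death_pd = as.numeric(ec$p_cancer_death_pd),
    p_hospitalization = as.numeric(ec$p_hospitalization),
    hospitalization_mode = match.arg(ec$hospitalization_mode,
                                     c("grade34", "claims")),
    ae_window = as.integer(ec$ae_window)
  )
  if (econ$annual_discount < 0 || econ$annual_discount >= 1) {
    stop("economics.annual_discount must lie in [0, 1)", call. = FALSE)
  }
  check_prob(econ$utility_pf, "economics.utility_pf")
  check_prob(econ$utility_pd, "economics.utility_pd")
  check_prob(econ$p_cancer_death_pd, "economics.p_cancer_death_pd")
  check_prob(econ$p_hospitalization, "economics.p_hospitalization")
  if (econ$ae_window > cohort$horizon) {
    stop("economics.ae_window exceeds the horizon", call. = FALSE)
  }

  H <- cohort$horizon
  win <- econ$ae_window
  ac <- cfg$arms
  arms <- list()
  arms$bsc <- make_arm("bsc", ac$best_supportive_care$label %||% "BSC",
                       as.numeric(ac$best_supportive_care$drug_cost %||% 0),
                       as.numeric(ac$best_supportive_care$admin_cost %||% 0),
                       as.numeric(ac$best_supportive_care$p_cancer_death),
                       parse_progression(ac$best_supportive_care$progression, H),
                       parse_ae_profile(ac$best_supportive_care$adverse_events, win),
                       pf_cost_from_bsc = isTRUE(ac$best_supportive_care$pf_cost_from_bsc))
  arms$pac <- make_arm("pac", ac$paclitaxel$label %||% "PAC",
                       as.numeric(ac$paclitaxel$drug_cost),
                       as.numeric(ac$paclitaxel$admin_cost),
                       as.numeric(ac$paclitaxel$p_cancer_death),
                       parse_progression(ac$paclitaxel$progression, H),
                       parse_ae_profile(ac$paclitaxel$adverse_events, win))
  arms$ram_pac <- make_arm("ram_pac", ac$ramucirumab_paclitaxel$label %||% "RAM/PAC",
                           as.numeric(ac$ramucirumab_paclitaxel$drug_cost),
                           as.numeric(ac$ramucirumab_paclitaxel$admin_cost),
                           as.numeric(ac$ramucirumab_paclitaxel$p_cancer_death),
                           parse_progression(ac$ramucirumab_paclitaxel$progression, H),
                           parse_ae_profile(ac$ramucirumab_paclitaxel$adverse_events, win))
  pem <- ac$pembrolizumab
  pem_ae <- parse_ae_profile(pem$adverse_events, win)
  sub_ids <- c(biomarker_agnostic = "pem_agnostic",
               pdl1_positive = "pem_pdl1", msi_high = "pem_msi")
  for (sub in names(sub_ids)) {
    blk <- pem$subgroups[[sub]]
    if (is.null(blk)) stop(sprintf("missing pembrolizumab subgroup '%s'", sub),
                           call. = FALSE)
    arms[[sub_ids[[sub]]]] <- make_arm(
      sub_ids[[sub]],
      paste0(pem$label %||% "PEM", " (", gsub("_", " ", sub), ")"),
      as.numeric(pem$drug_cost), as.numeric(pem$admin_cost),
      as.numeric(blk$p_cancer_death),
      parse_progression(blk$progression, H), pem_ae)
  }

  test_costs <- list(msi = as.numeric(cfg$biomarker_tests$msi),
                     pdl1 = as.numeric(cfg$biomarker_tests$pdl1))
  strategies <- lapply(cfg$strategies, function(s) {
    st <- list(id = s$id, name = s$name, kind = s$kind)
    if (identical(s$kind, "uniform")) {
      if (is.null(arms[[s$arm]])) {
        stop(sprintf("strategy '%s' references unknown arm '%s'", s$id, s$arm),
             call. = FALSE)
      }
      st$arm <- s$arm
      st$test_cost <- 0
    } else if (identical(s$kind, "biomarker_split")) {
      if (!s$biomarker %in% c("msi", "pdl1")) {
        stop(sprintf("strategy '%s': unknown biomarker '%s'", s$id, s$biomarker),
             call. = FALSE)
      }
      if (is.null(arms[[s$positive_arm]]) || is.null(arms[[s$negative_arm]])) {
        stop(sprintf("strategy '%s' references an unknown arm", s$id), call. = FALSE)
      }
      st$biomarker <- s$biomarker
      st$positive_arm <- s$positive_arm
      st$negative_arm <- s$negative_arm
      st$test_cost <- test_costs[[s$biomarker]]
    } else {
      stop(sprintf("strategy '%s': kind must be uniform or biomarker_split", s$id),
           call. = FALSE)
    }
    st
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "id")

  life_table <- read_life_table(life_table_path)
  max_age <- cohort$start_age + cohort$horizon / 12
  for (s in c("male", "female")) {
    ages <- life_table$age[life_table$sex == s]
    if (min(ages) > cohort$start_age || max(ages) < floor(max_age)) {
      stop("life table does not cover the cohort age range", call. = FALSE)
    }
  }

  model <- structure(list(cohort = cohort, econ = econ, arms = arms,
                          strategies = strategies,
                          sensitivity = parse_sensitivity(cfg$sensitivity),
                          test_costs = test_costs,
                          life_table = life_table,
                          config_path = normalizePath(config_path)),
                     class = "gc_model")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_sensitivity <- function(rows) {
  if (is.null(rows)) return(NULL)
  ent <- lapply(rows, function(r) {
    type <- match.arg(r$type, c("absolute", "multiplier"))
    low <- if (type == "multiplier") 1 - r$pct / 100 else as.numeric(r$low)
    high <- if (type == "multiplier") 1 + r$pct / 100 else as.numeric(r$high)
    if (low > high) stop(sprintf("sensitivity '%s': low > high", r$id), call. = FALSE)
    list(id = r$id, label = r$label, type = type, low = low, high = high,
         sd = if (is.null(r$sd)) NA_real_ else as.numeric(r$sd),
         distribution = match.arg(r$distribution,
                                  c("beta", "normal", "uniform", "gamma")),
         applies = r$applies,
         psa_independent = isTRUE(r$psa_independent))
  })
  names(ent) <- vapply(ent, `[[`, character(1), "id")
  ent
}

#' @export
print.gc_model <- function(x, ...) {
  cat("Markov cohort cost-effectiveness model\n")
  cat(sprintf("  cohort: age %g, %.0f%% male, horizon %d monthly cycles\n",
              x$cohort$start_age, 100 * x$cohort$male_fraction, x$cohort$horizon))
  cat(sprintf("  biomarker prevalence: MSI-H %.0f%%, PD-L1+ %.0f%%\n",
              100 * x$cohort$msi_h_prevalence, 100 * x$cohort$pdl1_pos_prevalence))
  cat(sprintf("  arms: %s\n", paste(names(x$arms), collapse = ", ")))
  cat(sprintf("  strategies: %d (%s)\n", length(x$strategies),
              paste(vapply(x$strategies, `[[`, character(1), "name"),
                    collapse = "; ")))
  cat(sprintf("  discount %.1f%%/yr, WTP $%s/QALY\n",
              100 * x$econ$annual_discount,
              format(x$econ$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Serialise a model back to its configuration list
#'
#' Returns the normalized configuration (the same shape [load_model()] reads)
#' so that a loaded model can be round-tripped through YAML.
#'
#' @param model A `gc_model`.
#' @return A list serialisable with `yaml::write_yaml()`.
#' @export
model_to_config <- function(model) {
  sched_out <- function(sched, horizon) {
    # inverse of parse_month_range: cycle c simulates month c - 1
    lapply(seq_len(nrow(sched)), function(i) {
      f <- sched$first[i]; l <- sched$last[i]
      lab <- if (l >= horizon) paste0(f - 1, "+") else paste0(f - 1, "-", l - 1)
      list(months = lab, p = sched$prob[i])
    })
  }
  ae_out <- function(ae) {
    if (ae$p_grade12 == 0 && ae$p_grade34 == 0 && ae$p_discontinuation == 0 &&
        ae$p_death == 0) return(NULL)
    ae[c("p_grade12", "p_grade34", "p_discontinuation", "p_death",
         "cost_grade34", "disutility_grade12", "disutility_grade34")]
  }
  H <- model$cohort$horizon
  arm_out <- function(a) {
    out <- list(label = a$label, drug_cost = a$drug_cost,
                admin_cost = a$admin_cost, p_cancer_death = a$p_cancer_death_pf,
                progression = sched_out(a$progression, H),
                adverse_events = ae_out(a$ae))
    if (a$pf_cost_from_bsc) out$pf_cost_from_bsc <- TRUE
    out
  }
  pem_subs <- list(
    biomarker_agnostic = model$arms$pem_agnostic,
    pdl1_positive = model$arms$pem_pdl1,
    msi_high = model$arms$pem_msi)
  fu <- model$econ$followup_cost_pf
  list(
    cohort = model$cohort,
    economics = c(model$econ[c("annual_discount", "wtp")],
                  list(followup_cost_pf = fu),
                  model$econ[c("bsc_cost_pd", "utility_pf", "utility_pd",
                               "p_cancer_death_pd", "p_hospitalization",
                               "hospitalization_mode", "ae_window")]),
    biomarker_tests = model$test_costs,
    arms = list(
      best_supportive_care = arm_out(model$arms$bsc),
      paclitaxel = arm_out(model$arms$pac),
      ramucirumab_paclitaxel = arm_out(model$arms$ram_pac),
      pembrolizumab = list(
        label = "PEM",
        drug_cost = model$arms$pem_agnostic$drug_cost,
        admin_cost = model$arms$pem_agnostic$admin_cost,
        adverse_events = ae_out(model$arms$pem_agnostic$ae),
        subgroups = lapply(pem_subs, function(a) {
          list(p_cancer_death = a$p_cancer_death_pf,
               progression = sched_out(a$progression, H))
        }))),
    strategies = unname(lapply(model$strategies, function(s) {
      s[setdiff(names(s), "test_cost")]
    }))
  )
}
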