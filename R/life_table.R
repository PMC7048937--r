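#' Read a life table from delimited text
#'
#' The file must have a header `age,sex,annual_mortality` with one row per
#' age/sex combination; `sex` is `male` or `female` and `annual_mortality` is
#' the annual probability of death from any cause.
#'
#' @param path Path to a CSV life table.
#' @return A `gc_life_table` data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_life_table(lt)
}

#' Validate a life-table data frame
#'
#' @param lt Data frame with columns `age`, `sex`, `annual_mortality`.
#' @return The validated `gc_life_table`.
#' @export
as_life_table <- function(lt) {
  need <- c("age", "sex", "annual_mortality")
  if (!all(need %in% names(lt))) {
    stop("life table needs columns age, sex, annual_mortality", call. = FALSE)
  }
  if (!all(lt$sex %in% c("male", "female"))) {
    stop("life table sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(lt$annual_mortality < 0) || any(lt$annual_mortality > 1)) {
    stop("annual mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (s in c("male", "female")) {
    ages <- sort(lt$age[lt$sex == s])
    if (length(ages) == 0 || any(diff(ages) != 1)) {
      stop(sprintf("life table ages for %s must be contiguous", s), call. = FALSE)
    }
  }
  class(lt) <- c("gc_life_table", "data.frame")
  lt
}

#' Sex-weighted monthly all-cause mortality
#'
#' Weights the annual male and female all-cause death probabilities at the
#' (floored) attained age and converts the blended annual probability `q` to a
#' monthly probability with the compound form `1 - (1 - q)^(1/12)`.
#'
#' @param life_table A `gc_life_table`.
#' @param age Attained age in years (may be fractional; floored for lookup).
#' @param male_fraction Proportion of the cohort that is male.
#' @return Monthly probability of all-cause death.
#' @export
all_cause_monthly_prob <- function(life_table, age, male_fraction) {
  a <- floor(age)
  qm <- life_table$annual_mortality[life_table$sex == "male" & life_table$age == a]
  qf <- life_table$annual_mortality[life_table$sex == "female" & life_table$age == a]
  if (length(qm) != 1 || length(qf) != 1) {
    stop(sprintf("age %s outside life-table range", a), call. = FALSE)
  }
  q <- male_fraction * qm + (1 - male_fraction) * qf
  1 - (1 - q)^(1 / 12)
}

# vector of monthly all-cause probabilities for cycles 1..horizon
all_cause_vector <- function(life_table, cohort) {
  ages <- cohort$start_age + (seq_len(cohort$horizon) - 1) / 12
  vapply(ages, function(a) {
    all_cause_monthly_prob(life_table, a, cohort$male_fraction)
  }, numeric(1))
}
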