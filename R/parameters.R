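#' Per-type distribution parameters for the three orbital morphotypes
#'
#' Returns the distributional parameters that define the three orbital
#' morphotypes: Tall & Broad (A), Deep & Broad (B) and Compact (C). For every
#' type and every linear dimension (depth, height, width, in millimetres) the
#' table holds the mean, standard deviation and observed minimum/maximum of
#' the published reference cohort, together with the type prevalences
#' (33.5/30.2/36.2%, renormalized to sum to one). These parameters drive both
#' the synthetic cohort generator ([simulate_cohort()]) and the analytic
#' mixture decompositions ([mixture_eta2()]).
#'
#' Each dimension is modelled as a normal distribution truncated to the
#' observed \[min, max\] range; the mean/sd columns are the parameters of the
#' parent (untruncated) normal. Use [truncnorm_moments()] for the moments of
#' the truncated law actually sampled.
#'
#' @param prevalence Named numeric vector of type prevalences (names "A",
#'   "B", "C"). Renormalized to sum to 1. Default is the published
#'   distribution.
#' @return A tibble with one row per (type, dimension) pair and columns
#'   `type`, `prevalence`, `dimension`, `mean`, `sd`, `min`, `max`.
#' @examples
#' morphotype_parameters()
#' @export
morphotype_parameters <- function(prevalence = c(A = 0.335, B = 0.302, C = 0.362)) {
  stopifnot(is.numeric(prevalence), length(prevalence) == 3L)
  if (is.null(names(prevalence))) names(prevalence) <- ORBIT_TYPES
  if (!setequal(names(prevalence), ORBIT_TYPES)) {
    abort("`prevalence` must be named with types A, B, C.")
  }
  if (any(prevalence <= 0)) abort("prevalences must be positive")
  prevalence <- prevalence[ORBIT_TYPES] / sum(prevalence)

  tbl <- tibble::tribble(
    ~type, ~dimension,  ~mean,  ~sd,  ~min,  ~max,
    "A",   "depth_mm",  40.10, 2.20,  35.3,  45.4,
    "A",   "height_mm", 35.97, 1.45,  32.8,  39.9,
    "A",   "width_mm",  37.11, 1.71,  32.7,  44.5,
    "B",   "depth_mm",  43.52, 2.12,  38.5,  50.9,
    "B",   "height_mm", 32.79, 1.52,  27.1,  37.1,
    "B",   "width_mm",  36.76, 1.43,  33.7,  39.7,
    "C",   "depth_mm",  38.56, 2.15,  32.8,  45.5,
    "C",   "height_mm", 32.48, 1.66,  23.0,  35.8,
    "C",   "width_mm",  34.22, 1.64,  26.5,  37.2
  )
  tbl <- dplyr::mutate(tbl, prevalence = unname(prevalence[.data$type]),
                       .after = "type")
  validate_morphotype_parameters(tbl)
  tbl
}

#' Validate a morphotype parameter table
#'
#' Checks the invariants a parameter table must satisfy before it can drive
#' simulation: prevalences sum to one, all standard deviations are positive,
#' and every truncation interval strictly contains its mean (otherwise
#' rejection sampling would not terminate).
#'
#' @param params A tibble as returned by [morphotype_parameters()].
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_morphotype_parameters <- function(params) {
  needed <- c("type", "prevalence", "dimension", "mean", "sd", "min", "max")
  missing <- setdiff(needed, names(params))
  if (length(missing)) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  prev <- dplyr::distinct(params, .data$type, .data$prevalence)
  if (abs(sum(prev$prevalence) - 1) > 1e-9) {
    abort("prevalences must sum to 1 (within 1e-9)")
  }
  if (any(params$sd <= 0)) abort("all sd values must be > 0")
  bad <- params$min >= params$mean | params$mean >= params$max
  if (any(bad)) {
    abort(paste0("truncation bounds must satisfy min < mean < max; violated for ",
                 paste(paste(params$type[bad], params$dimension[bad]),
                       collapse = ", ")))
  }
  invisible(params)
}

#' Covariate model for synthetic cohorts
#'
#' Describes the demographic structure attached to simulated orbits: the
#' male fraction, a truncated-normal age distribution, a target Spearman
#' correlation between age and orbital width (coupled through a Gaussian
#' copula on ranks), and optional additive sex effects on depth and width.
#' Defaults reproduce the reference cohort demographics (63.3% male, age
#' 44.6 +/- 18.1 years on 8-88, age-width rho of -0.11); the sex shifts
#' default to 0 because no per-sex dimension means are published.
#'
#' Setting `age_width_spearman`, `sex_depth_shift` and `sex_width_shift` all
#' to 0 makes the dimensions independent of the covariates.
#'
#' @param sex_male_fraction Probability that an orbit comes from a male
#'   patient.
#' @param age_mean,age_sd Mean and sd (years) of the parent normal for age.
#' @param age_min,age_max Truncation bounds for age (years).
#' @param age_width_spearman Target Spearman correlation between age and
#'   width (dimensionless, in (-1, 1)).
#' @param sex_depth_shift,sex_width_shift Millimetres added to male depth /
#'   width.
#' @return A list of class `covariate_model`.
#' @examples
#' covariate_model()
#' covariate_model(sex_depth_shift = 1.2, sex_width_shift = 0.8)
#' @export
covariate_model <- function(sex_male_fraction = 0.633,
                            age_mean = 44.6, age_sd = 18.1,
                            age_min = 8, age_max = 88,
                            age_width_spearman = -0.11,
                            sex_depth_shift = 0,
                            sex_width_shift = 0) {
  stopifnot(sex_male_fraction >= 0, sex_male_fraction <= 1,
            age_sd > 0, age_min < age_mean, age_mean < age_max,
            abs(age_width_spearman) < 1)
  structure(
    list(sex_male_fraction = sex_male_fraction,
         age_mean = age_mean, age_sd = age_sd,
         age_min = age_min, age_max = age_max,
         age_width_spearman = age_width_spearman,
         sex_depth_shift = sex_depth_shift,
         sex_width_shift = sex_width_shift),
    class = "covariate_model")
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and variance of a normal(mean, sd) distribution
#' truncated to \[min, max\], via the standard Mills-ratio expressions. Used
#' for the analytic expectations of the simulated dimensions: the truncated
#' mean differs from the parent mean whenever the bounds are asymmetric
#' around it.
#'
#' @param mean,sd Parent normal parameters (`sd > 0`).
#' @param min,max Truncation bounds (`min < max`).
#' @return A list with elements `mean` and `var` of the truncated law.
#' @examples
#' truncnorm_moments(0, 1, -1, 1)   # symmetric: mean 0, var < 1
#' truncnorm_moments(34.22, 1.64, 26.5, 37.2)
#' @export
truncnorm_moments <- function(mean, sd, min, max) {
  stopifnot(sd > 0, min < max)
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) abort("truncation interval has no probability mass")
  dr <- (dnorm(a) - dnorm(b)) / z
  m <- mean + sd * dr
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - dr^2)
  list(mean = m, var = v)
}
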