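#' Run the full morphotype analysis pipeline
#'
#' End-to-end, seeded run wiring the whole package together: simulate a
#' cohort (or read one from CSV), summarize the type distribution and
#' per-type descriptives, re-derive the morphotypes (k-means + cluster
#' naming + stratified cross-validated LDA), extract the decision-rule
#' cut-offs, classify with the full and depth-only rules, score both
#' against the generating (or supplied) labels, and run the group
#' statistics. Returns one report object and optionally writes it as JSON.
#'
#' Runs with `n < 30` complete but carry a small-sample warning: the
#' derivation steps (k-means, 5-fold LDA, bootstrap) are unstable at such
#' sizes.
#'
#' @param n Cohort size when simulating. Default 499.
#' @param seed Integer seed driving every stochastic stage.
#' @param input Optional CSV path; when given, the cohort is read with
#'   [read_measurements()] instead of simulated, and truth labels are taken
#'   from its `true_type` column.
#' @param params,covariates Generator settings (see [simulate_cohort()]).
#' @param cutoffs An [orbit_cutoffs()] set for the fixed-rule classifiers.
#' @param folds Cross-validation folds for the LDA step.
#' @param bootstrap_B Bootstrap resamples for the depth-cut CIs.
#' @param output Optional path; when given the report is written there as
#'   JSON (schema shipped in `inst/extdata/report-schema.json`).
#' @return A list of class `orbit_report` with elements `meta`,
#'   `type_distribution`, `descriptives`, `group_tests`, `derivation`,
#'   `full_rule`, `depth_rule` and `derived_cutoffs`.
#' @examples
#' rep <- run_full_pipeline(n = 200, seed = 42, bootstrap_B = 50)
#' rep$full_rule$accuracy
#' @export
run_full_pipeline <- function(n = 499, seed = 1, input = NULL,
                              params = morphotype_parameters(),
                              covariates = covariate_model(),
                              cutoffs = orbit_cutoffs(),
                              folds = 5, bootstrap_B = 1000,
                              output = NULL) {
  if (!is.null(output) && !dir.exists(dirname(output))) {
    abort(paste0("output directory does not exist: ", dirname(output)))
  }
  cohort <- if (is.null(input)) {
    simulate_cohort(n = n, params = params, covariates = covariates,
                    seed = seed)
  } else {
    read_measurements(input)
  }
  n <- nrow(cohort)
  if (n < 30) warn("small cohort (n < 30): derivation results will be unstable")
  if (all(is.na(cohort$true_type))) {
    abort("cohort carries no `true_type` labels to score against")
  }

  # descriptives
  summ <- summarize_cohort(cohort)
  type_dist <- summ |>
    dplyr::distinct(.data$type, .data$n, .data$prevalence)

  # group statistics between types; degenerate groups fail soft with a warning
  try_stage <- function(expr, stage, fallback) {
    tryCatch(expr, error = function(e) {
      warn(paste0("stage `", stage, "` skipped for this cohort: ",
                  conditionMessage(e)))
      fallback
    })
  }
  group_tests <- purrr::map_dfr(DIM_COLS, function(dm) {
    a <- try_stage(anova_eta2(cohort, dm, "true_type"), paste0("anova/", dm),
                   tibble::tibble(statistic = NA_real_, df_between = NA_real_,
                                  df_within = NA_real_, p_value = NA_real_,
                                  effect_size = NA_real_))
    k <- try_stage(kruskal_wallis(cohort, dm, "true_type"),
                   paste0("kruskal/", dm),
                   tibble::tibble(statistic = NA_real_, p_value = NA_real_))
    tibble::tibble(dimension = dm,
                   anova_f = a$statistic, anova_df1 = a$df_between,
                   anova_df2 = a$df_within, anova_p = a$p_value,
                   eta_squared = a$effect_size,
                   kw_h = k$statistic, kw_p = k$p_value)
  })

  # derivation: k-means -> naming -> CV LDA -> cut-off extraction
  km <- orbit_kmeans(cohort, seed = seed)
  map <- name_clusters(km)
  km_labels <- unname(map[as.character(km$cluster)])
  cv <- try_stage(
    cv_lda(cohort[, DIM_COLS], km$cluster, folds = folds, seed = seed),
    "cv_lda",
    tibble::tibble(mean_accuracy = NA_real_, sd_accuracy = NA_real_))
  stump <- try_stage(derive_rule_cutoffs(cohort, km_labels), "stump",
                     tibble::tibble(h_cut = NA_real_, d_cut = NA_real_,
                                    accuracy = NA_real_))
  dc <- try_stage(
    optimize_depth_cutoffs(cohort$depth_mm, km_labels,
                           bootstrap_B = bootstrap_B, seed = seed),
    "depth_cutoffs",
    list(d1 = NA_real_, d2 = NA_real_, accuracy = NA_real_,
         ci_d1 = c(NA_real_, NA_real_), ci_d2 = c(NA_real_, NA_real_)))

  # fixed published rules scored against the generating labels
  full <- classify_orbits(cohort, cutoffs, mode = "full")
  full_m <- evaluate_classification(full)
  depth <- classify_orbits(cohort, cutoffs, mode = "depth")
  depth_m <- evaluate_classification(depth, ci = TRUE, B = bootstrap_B,
                                     seed = seed)

  report <- structure(list(
    meta = list(package = "orbitype",
                version = as.character(utils::packageVersion("orbitype")),
                seed = seed, n = n, folds = folds, bootstrap_B = bootstrap_B,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    type_distribution = type_dist,
    descriptives = summ,
    group_tests = group_tests,
    derivation = list(
      standardization = list(center = as.list(km$center),
                             scale = as.list(km$scale)),
      centroids_raw = km$centers_raw,
      cluster_map = as.list(map),
      cluster_sizes = km$sizes,
      cv_accuracy_mean = cv$mean_accuracy,
      cv_accuracy_sd = cv$sd_accuracy
    ),
    derived_cutoffs = list(
      h_cut = stump$h_cut, d_cut = stump$d_cut,
      stump_training_accuracy = stump$accuracy,
      d1 = dc$d1, d2 = dc$d2,
      d1_ci = dc$ci_d1, d2_ci = dc$ci_d2,
      depth_training_accuracy = dc$accuracy
    ),
    full_rule = list(accuracy = full_m$accuracy,
                     confusion = unclass(full_m$confusion),
                     precision = as.list(full_m$precision),
                     recall = as.list(full_m$recall)),
    depth_rule = list(accuracy = depth_m$accuracy,
                      ci = depth_m$ci,
                      confusion = unclass(depth_m$confusion),
                      precision = as.list(depth_m$precision),
                      recall = as.list(depth_m$recall))
  ), class = "orbit_report")

  if (!is.null(output)) {
    jsonlite::write_json(report_to_json(report), output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

# flatten tibbles/matrices into plain lists for JSON serialization
report_to_json <- function(report) {
  flatten <- function(x) {
    if (inherits(x, "tbl_df") || is.data.frame(x)) return(as.list(as.data.frame(x)))
    if (is.matrix(x)) {
      return(apply(x, 1L, as.list, simplify = FALSE))
    }
    if (is.list(x)) return(lapply(x, flatten))
    x
  }
  flatten(unclass(report))
}

#' @export
print.orbit_report <- function(x, ...) {
  cat(sprintf("Orbit morphotype pipeline report (n = %s, seed = %s)\n",
              x$meta$n, x$meta$seed))
  cat("\nType distribution:\n"); print(x$type_distribution)
  cat(sprintf("\nDerivation: 5-fold LDA CV accuracy %.3f +/- %.3f\n",
              x$derivation$cv_accuracy_mean, x$derivation$cv_accuracy_sd))
  cat(sprintf("Derived cut-offs: H %.2f, D %.2f; depth-only %.2f / %.2f\n",
              x$derived_cutoffs$h_cut, x$derived_cutoffs$d_cut,
              x$derived_cutoffs$d1, x$derived_cutoffs$d2))
  cat(sprintf("Full rule accuracy: %.3f; depth-only rule accuracy: %.3f\n",
              x$full_rule$accuracy, x$depth_rule$accuracy))
  invisible(x)
}

#' Validate a pipeline report against the shipped schema
#'
#' Light structural check of a report (or a JSON file written by
#' [run_full_pipeline()]) against the schema in
#' `inst/extdata/report-schema.json`: required keys present with the
#' expected JSON types.
#'
#' @param report An `orbit_report` object or a path to a report JSON file.
#' @return `TRUE` invisibly on success; otherwise an error listing the
#'   violations.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  if (inherits(report, "orbit_report")) report <- report_to_json(report)
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "orbitype"))
  problems <- character(0)
  check <- function(obj, spec, path) {
    for (key in names(spec$required)) {
      if (!key %in% names(obj)) {
        problems <<- c(problems, paste0("missing key: ", path, key))
        next
      }
      sub <- spec$required[[key]]
      if (is.list(sub) && !is.null(sub$required)) {
        check(obj[[key]], sub, paste0(path, key, "."))
      } else if (identical(sub, "number")) {
        val <- unlist(obj[[key]])
        if (!is.numeric(val)) {
          problems <<- c(problems, paste0("not numeric: ", path, key))
        }
      }
    }
  }
  check(report, schema, "")
  if (length(problems)) {
    abort(paste0("report fails schema: ", paste(problems, collapse = "; ")))
  }
  invisible(TRUE)
}
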