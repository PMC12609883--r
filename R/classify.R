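#' Published classification cut-offs
#'
#' Container for the threshold set used by the decision rules. Defaults are
#' the published values: the full rule classifies on height then depth
#' (`h_cut`, `d_cut`), width thresholds annotate borderline cases
#' (`w_support_b`, `w_support_c`), and the depth-only fallback uses the two
#' cut points `d1 < d2`.
#'
#' @param h_cut Height threshold (mm): `H > h_cut` is type A.
#' @param d_cut Depth threshold (mm): among `H <= h_cut`, `D > d_cut` is B.
#' @param w_support_b,w_support_c Width support thresholds (mm) for
#'   borderline annotation.
#' @param d1,d2 Depth-only cut points (mm), `d1 < d2`.
#' @return A list of class `orbit_cutoffs`.
#' @examples
#' orbit_cutoffs()
#' orbit_cutoffs(h_cut = 34.0)
#' @export
orbit_cutoffs <- function(h_cut = 34.35, d_cut = 41.65,
                          w_support_b = 34.45, w_support_c = 36.25,
                          d1 = 40.75, d2 = 41.95) {
  vals <- c(h_cut = h_cut, d_cut = d_cut, w_support_b = w_support_b,
            w_support_c = w_support_c, d1 = d1, d2 = d2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all cut-offs must be positive finite numbers")
  }
  if (d1 >= d2) abort("`d1` must be strictly less than `d2`")
  structure(as.list(vals), class = "orbit_cutoffs")
}

#' @export
print.orbit_cutoffs <- function(x, ...) {
  cat("Orbit classification cut-offs (mm):\n")
  cat(sprintf("  full rule: H > %.2f -> A; else D > %.2f -> B; else C\n",
              x$h_cut, x$d_cut))
  cat(sprintf("  width support (borderline): W > %.2f leans B; W <= %.2f leans C\n",
              x$w_support_c, x$w_support_b))
  cat(sprintf("  depth-only: D <= %.2f -> C; <= %.2f -> A; else B\n", x$d1, x$d2))
  invisible(x)
}

#' Classify orbits into morphotypes
#'
#' Applies the threshold decision rules to every record and appends the
#' predicted type. Two modes are available:
#'
#' * `"full"` — the three-dimension algorithm: `H > h_cut` gives type A;
#'   otherwise `D > d_cut` gives type B; otherwise type C. Boundary values
#'   use `<=`, so a record exactly on a threshold falls to the lower branch
#'   (ultimately type C). Records within `margin` of either threshold are
#'   flagged `borderline`, and for those the width support is reported as a
#'   non-overriding annotation in `width_lean`: `W > w_support_c` leans B,
#'   `W <= w_support_b` leans C, in between no lean. The lean never changes
#'   the primary label.
#' * `"depth"` — the depth-only fallback for trauma cases: `D <= d1` gives
#'   C, `d1 < D <= d2` gives A, `D > d2` gives B. The interval-to-type
#'   mapping follows ascending type-mean depth (C 38.56 < A 40.1 < B
#'   43.52 mm).
#'
#' @param data Data frame with positive `depth_mm`, `height_mm`, `width_mm`
#'   (only `depth_mm` is required in depth mode).
#' @param cutoffs An [orbit_cutoffs()] object.
#' @param mode `"full"` or `"depth"`.
#' @param margin Borderline margin (mm) around `h_cut`/`d_cut` in full mode.
#' @return `data` with `pred_type` appended (plus `borderline` and
#'   `width_lean` in full mode), as a tibble.
#' @examples
#' x <- tibble::tibble(depth_mm = c(40.1, 43.52, 38.56),
#'                     height_mm = c(35.97, 32.79, 32.48),
#'                     width_mm = c(37.11, 36.76, 34.22))
#' classify_orbits(x)$pred_type            # "A" "B" "C"
#' classify_orbits(x, mode = "depth")$pred_type
#' @export
classify_orbits <- function(data, cutoffs = orbit_cutoffs(),
                            mode = c("full", "depth"), margin = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(cutoffs, "orbit_cutoffs"))
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  data <- tibble::as_tibble(data)

  if (mode == "depth") {
    if (!"depth_mm" %in% names(data)) abort("missing required column(s): depth_mm")
    d <- data$depth_mm
    if (any(!is.finite(d) | d <= 0)) abort("depth_mm must be positive and finite")
    pred <- ifelse(d <= cutoffs$d1, "C", ifelse(d <= cutoffs$d2, "A", "B"))
    return(dplyr::mutate(data, pred_type = pred))
  }

  check_dimension_cols(data)
  d <- data$depth_mm; h <- data$height_mm; w <- data$width_mm
  if (any(!is.finite(d) | !is.finite(h) | !is.finite(w)) ||
      any(d <= 0 | h <= 0 | w <= 0)) {
    abort("all dimensions must be positive and finite")
  }
  pred <- ifelse(h > cutoffs$h_cut, "A", ifelse(d > cutoffs$d_cut, "B", "C"))
  borderline <- abs(h - cutoffs$h_cut) < margin | abs(d - cutoffs$d_cut) < margin
  lean <- dplyr::case_when(
    !borderline ~ NA_character_,
    w > cutoffs$w_support_c ~ "B",
    w <= cutoffs$w_support_b ~ "C",
    .default = NA_character_
  )
  dplyr::mutate(data, pred_type = pred, borderline = borderline,
                width_lean = lean)
}

#' Score predictions against true morphotypes
#'
#' Builds the 3x3 confusion matrix (rows = truth, columns = prediction) and
#' derives overall accuracy and per-class precision and recall. Precision of
#' an empty prediction column is reported as 0 and flagged. Optionally a
#' seeded percentile bootstrap over record indices gives a confidence
#' interval for accuracy.
#'
#' @param data Data frame holding truth and prediction columns (e.g. the
#'   output of [classify_orbits()] on a simulated cohort).
#' @param truth,pred Column names of the true and predicted labels.
#' @param levels Label universe; defaults to A/B/C.
#' @param ci Bootstrap an accuracy CI? Default `FALSE`.
#' @param B Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `orbit_metrics` with elements `confusion`,
#'   `accuracy`, `precision`, `recall`, `n` and optionally `ci`. Use
#'   [tidy()] for a per-class tibble and [glance()] for a one-row summary.
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 3) |> classify_orbits()
#' m <- evaluate_classification(cohort)
#' glance(m)
#' tidy(m)
#' @export
evaluate_classification <- function(data, truth = "true_type",
                                    pred = "pred_type",
                                    levels = ORBIT_TYPES,
                                    ci = FALSE, B = 1000, conf = 0.95,
                                    seed = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  for (col in c(truth, pred)) {
    if (!col %in% names(data)) abort(paste0("column `", col, "` not found"))
  }
  tr <- as.character(data[[truth]])
  pr <- as.character(data[[pred]])
  n <- length(tr)
  if (n < 1L) abort("need at least one (truth, prediction) pair")
  unknown <- setdiff(unique(c(tr, pr)), levels)
  if (length(unknown)) {
    abort(paste0("unknown label(s): ", paste(unknown, collapse = ", ")))
  }

  cm <- table(factor(tr, levels = levels), factor(pr, levels = levels))
  dimnames(cm) <- list(truth = levels, prediction = levels)
  acc <- sum(diag(cm)) / n
  colsum <- colSums(cm); rowsum <- rowSums(cm)
  precision <- ifelse(colsum > 0, diag(cm) / colsum, 0)
  recall <- ifelse(rowsum > 0, diag(cm) / rowsum, 0)
  empty_pred <- levels[colsum == 0]

  out <- structure(
    list(confusion = cm, accuracy = acc,
         precision = setNames(as.numeric(precision), levels),
         recall = setNames(as.numeric(recall), levels),
         n = n, empty_prediction_classes = empty_pred, ci = NULL),
    class = "orbit_metrics")

  if (ci) {
    stopifnot(B >= 1)
    boot <- function() {
      vapply(seq_len(B), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        mean(tr[i] == pr[i])
      }, numeric(1))
    }
    accs <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
    alpha <- (1 - conf) / 2
    out$ci <- unname(quantile(accs, c(alpha, 1 - alpha), type = 7))
    out$conf <- conf
  }
  out
}

#' @export
print.orbit_metrics <- function(x, ...) {
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy: %.3f", x$accuracy))
  if (!is.null(x$ci)) {
    cat(sprintf("  (%.0f%% bootstrap CI %.3f-%.3f)", 100 * x$conf,
                x$ci[1], x$ci[2]))
  }
  cat("\n")
  for (k in names(x$precision)) {
    cat(sprintf("  %s: precision %.2f, recall %.2f\n",
                k, x$precision[k], x$recall[k]))
  }
  invisible(x)
}

#' @rdname evaluate_classification
#' @param x An `orbit_metrics` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.orbit_metrics <- function(x, ...) {
  tibble::tibble(
    class = names(x$precision),
    n_true = as.numeric(rowSums(x$confusion)),
    n_pred = as.numeric(colSums(x$confusion)),
    precision = unname(x$precision),
    recall = unname(x$recall)
  )
}

#' @rdname evaluate_classification
#' @exportS3Method generics::glance
glance.orbit_metrics <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, n = x$n,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci[1],
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci[2]
  )
}
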