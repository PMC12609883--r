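#' Z-standardize the dimension columns
#'
#' Centers and scales each of `depth_mm`, `height_mm`, `width_mm` to mean 0
#' and sd 1 (denominator n - 1), keeping the constants for the inverse
#' transform. Clustering operates in this standardized space so no single
#' dimension dominates the Euclidean distance.
#'
#' @param data Data frame with the three dimension columns (n >= 2).
#' @return A list with `scaled` (n x 3 matrix), `center` and `scale`
#'   (named length-3 vectors).
#' @examples
#' s <- standardize_dims(simulate_cohort(n = 50, seed = 1))
#' colMeans(s$scaled)   # ~0
#' @export
standardize_dims <- function(data) {
  check_dimension_cols(data)
  X <- as.matrix(data[, DIM_COLS])
  if (nrow(X) < 2L) abort("need at least 2 records to standardize")
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  if (any(scale <= 0)) {
    abort(paste0("constant column(s): ",
                 paste(DIM_COLS[scale <= 0], collapse = ", ")))
  }
  list(scaled = sweep(sweep(X, 2L, center), 2L, scale, `/`),
       center = center, scale = scale)
}

#' Invert a standardization
#'
#' @param scaled Matrix produced by [standardize_dims()].
#' @param center,scale The stored constants.
#' @return Matrix on the original millimetre scale.
#' @export
unstandardize_dims <- function(scaled, center, scale) {
  sweep(sweep(scaled, 2L, scale, `*`), 2L, center, `+`)
}

#' K-means clustering of standardized orbit dimensions
#'
#' Lloyd's algorithm with k-means++-style seeded initialization, run
#' `restarts` times and keeping the solution with the smallest total
#' within-cluster sum of squares. The within-cluster objective is checked to
#' be non-increasing at every iteration; an iteration that empties a cluster
#' re-seeds its centroid at the point farthest from its assigned centroid.
#' Deterministic for a fixed seed.
#'
#' @param data Cohort data frame (dimensions are standardized internally).
#' @param k Number of clusters (default 3, the morphotype count).
#' @param restarts Independent initializations (default 10).
#' @param max_iter Iteration cap per run (default 300).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param include_indices Also cluster on the proportional indices `di`,
#'   `wi`, `hi` (standardized alongside the dimensions)? Default `FALSE`:
#'   the morphotypes are defined on the raw dimensions.
#' @return An object of class `orbit_kmeans`: `cluster` (assignments),
#'   `centers_std` and `centers_raw` (k x p), `withinss`, `tot_withinss`,
#'   `iterations`, `center`/`scale` standardization constants and `sizes`.
#' @examples
#' km <- orbit_kmeans(simulate_cohort(n = 300, seed = 4), seed = 4)
#' glance(km)
#' @export
orbit_kmeans <- function(data, k = 3, restarts = 10, max_iter = 300,
                         seed = NULL, include_indices = FALSE) {
  std <- standardize_dims(data)
  X <- std$scaled
  if (include_indices) {
    idx <- as.matrix(add_indices(data)[, c("di", "wi", "hi")])
    ic <- colMeans(idx); is_ <- apply(idx, 2L, sd)
    if (any(is_ <= 0)) abort("constant index column")
    X <- cbind(X, sweep(sweep(idx, 2L, ic), 2L, is_, `/`))
  }
  n <- nrow(X)
  if (n < k) abort("need at least k records")

  run_all <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(X, k, max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
    best
  }
  best <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  centers_raw <- unstandardize_dims(best$centers[, seq_len(3L), drop = FALSE],
                                    std$center, std$scale)
  structure(
    list(cluster = best$cluster, centers_std = best$centers,
         centers_raw = centers_raw, withinss = best$withinss,
         tot_withinss = best$tot_withinss, iterations = best$iterations,
         sizes = tabulate(best$cluster, k), k = k,
         center = std$center, scale = std$scale),
    class = "orbit_kmeans")
}

# Squared Euclidean distances from every row of X to every row of C (n x k).
row_mins <- function(M) do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))

dist2 <- function(X, C) {
  D2 <- outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
  pmax(D2, 0)   # guard against small negative values from cancellation
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- row_mins(dist2(X, centers))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, X[sample.int(n, 1L, prob = p), ])
  }
  centers
}

lloyd_once <- function(X, k, max_iter) {
  centers <- kmeanspp_init(X, k)
  assign <- rep(0L, nrow(X))
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    D2 <- dist2(X, centers)
    new_assign <- max.col(-D2, ties.method = "first")
    obj <- sum(D2[cbind(seq_len(nrow(X)), new_assign)])
    # Lloyd guarantees a non-increasing objective; a violation indicates a bug
    stopifnot(obj <= obj_prev + 1e-8)
    obj_prev <- obj
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # empty cluster: re-seed at the point farthest from its centroid
        far <- which.max(row_mins(D2))
        centers[j, ] <- X[far, ]
        assign[far] <- j
      } else {
        centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
    }
  }
  D2 <- dist2(X, centers)
  withinss <- vapply(seq_len(k), function(j) {
    sum(D2[cbind(which(assign == j), rep(j, sum(assign == j)))])
  }, numeric(1))
  list(cluster = assign, centers = centers, withinss = withinss,
       tot_withinss = sum(withinss), iterations = it)
}

#' @export
print.orbit_kmeans <- function(x, ...) {
  cat(sprintf("K-means (k = %d) on standardized orbit dimensions\n", x$k))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("total within-cluster SS: %.3f (%d iterations)\n",
              x$tot_withinss, x$iterations))
  cat("raw-scale centroids (mm):\n")
  print(round(x$centers_raw, 2))
  invisible(x)
}

#' @rdname orbit_kmeans
#' @param x An `orbit_kmeans` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.orbit_kmeans <- function(x, ...) {
  tibble::as_tibble(x$centers_raw) |>
    dplyr::mutate(cluster = seq_len(x$k), size = x$sizes,
                  withinss = x$withinss, .before = 1L)
}

#' @rdname orbit_kmeans
#' @exportS3Method generics::glance
glance.orbit_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, tot_withinss = x$tot_withinss,
                 iterations = x$iterations, n = length(x$cluster))
}

#' Name clusters as morphotypes A/B/C
#'
#' Maps cluster indices to morphotype labels by the defining anatomy: the
#' cluster with the greatest mean raw height is Tall & Broad (A); of the two
#' remaining, the one with greater mean raw depth is Deep & Broad (B); the
#' last is Compact (C). Exact ties are broken by cluster index with a
#' warning.
#'
#' @param km An [orbit_kmeans()] fit with `k = 3`.
#' @return Named character vector mapping cluster index (`"1"`, `"2"`,
#'   `"3"`) to type label.
#' @examples
#' cohort <- simulate_cohort(n = 499, seed = 5)
#' km <- orbit_kmeans(cohort, seed = 5)
#' map <- name_clusters(km)
#' table(map[km$cluster], cohort$true_type)
#' @export
name_clusters <- function(km) {
  stopifnot(inherits(km, "orbit_kmeans"))
  if (km$k != 3L) abort("cluster naming requires k = 3")
  H <- km$centers_raw[, "height_mm"]
  D <- km$centers_raw[, "depth_mm"]
  if (anyDuplicated(H) || anyDuplicated(D)) {
    warn("tied cluster means; breaking ties by cluster index")
  }
  a <- which.max(H)                       # which.max takes the first on ties
  rest <- setdiff(1:3, a)
  b <- rest[which.max(D[rest])]
  cc <- setdiff(rest, b)
  map <- character(3)
  map[c(a, b, cc)] <- c("A", "B", "C")
  setNames(map, as.character(1:3))
}

#' Linear discriminant analysis of orbit dimensions
#'
#' Fits Gaussian LDA from class means, a pooled within-class covariance and
#' class priors (proportional to class sizes). Prediction uses the linear
#' discriminant scores
#' \deqn{\delta_k(x) = x^\top \Sigma^{-1}\mu_k - \tfrac12 \mu_k^\top
#'   \Sigma^{-1}\mu_k + \log \pi_k,}
#' assigning each point to the class with the largest score — equivalent to
#' the maximum posterior under equal-covariance Gaussians.
#'
#' @param x Numeric matrix or data frame of predictors (rows = records).
#' @param grouping Class labels, one per row (>= 2 classes, each with >= 2
#'   records).
#' @return An object of class `orbit_lda`: `means` (classes x predictors),
#'   `pooled_cov`, `priors`, `levels`.
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 6)
#' fit <- orbit_lda(cohort[, c("depth_mm", "height_mm", "width_mm")],
#'                  cohort$true_type)
#' mean(predict(fit, cohort[, c("depth_mm", "height_mm", "width_mm")])
#'      == cohort$true_type)
#' @export
orbit_lda <- function(x, grouping) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  g <- factor(grouping)
  if (nrow(X) != length(g)) abort("`x` and `grouping` lengths differ")
  sizes <- table(g)
  if (nlevels(g) < 2L) abort("need at least 2 classes")
  if (any(sizes < 2L)) abort("every class needs at least 2 records")

  p <- ncol(X)
  means <- vapply(levels(g), function(l) colMeans(X[g == l, , drop = FALSE]),
                  numeric(p))
  means <- if (p == 1L) matrix(means, ncol = 1L) else t(means)
  rownames(means) <- levels(g)
  # pooled within-class covariance, denominator n - k
  Sw <- matrix(0, p, p)
  for (l in levels(g)) {
    Xl <- X[g == l, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xl, 2L, colMeans(Xl)))
  }
  pooled <- Sw / (nrow(X) - nlevels(g))
  pooled <- (pooled + t(pooled)) / 2
  cn <- kappa(pooled, exact = TRUE)
  if (!is.finite(cn) || cn > 1e12) {
    abort(sprintf("pooled covariance is (near-)singular: condition number %.3g", cn))
  }
  structure(
    list(means = means, pooled_cov = pooled,
         priors = as.numeric(sizes) / length(g), levels = levels(g),
         pooled_cov_inv = solve(pooled)),
    class = "orbit_lda")
}

#' @rdname orbit_lda
#' @param object An `orbit_lda` fit.
#' @param newdata Matrix or data frame with the training predictors.
#' @param type `"class"` for labels (default) or `"posterior"` for class
#'   probabilities.
#' @param ... Unused.
#' @export
predict.orbit_lda <- function(object, newdata, type = c("class", "posterior"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Sinv <- object$pooled_cov_inv
  M <- object$means
  # delta_k(x) = x' Sinv mu_k - 0.5 mu_k' Sinv mu_k + log pi_k
  scores <- X %*% Sinv %*% t(M)
  scores <- sweep(scores, 2L, 0.5 * rowSums((M %*% Sinv) * M), `-`)
  scores <- sweep(scores, 2L, log(object$priors), `+`)
  if (type == "class") {
    return(object$levels[max.col(scores, ties.method = "first")])
  }
  post <- exp(scores - apply(scores, 1L, max))
  post <- post / rowSums(post)
  colnames(post) <- object$levels
  post
}

#' @rdname orbit_lda
#' @exportS3Method generics::tidy
tidy.orbit_lda <- function(x, ...) {
  tibble::as_tibble(x$means) |>
    dplyr::mutate(class = x$levels, prior = x$priors, .before = 1L)
}

#' @rdname orbit_lda
#' @exportS3Method generics::glance
glance.orbit_lda <- function(x, ...) {
  tibble::tibble(n_classes = length(x$levels), n_predictors = ncol(x$means),
                 cov_condition = kappa(x$pooled_cov, exact = TRUE))
}

#' Stratified k-fold cross-validated LDA accuracy
#'
#' Splits records into `folds` stratified folds (each class spread evenly),
#' fits [orbit_lda()] on the training part and scores the held-out part;
#' reports the mean and sd of the per-fold accuracies. Seeded for
#' reproducibility.
#'
#' @inheritParams orbit_lda
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return A tibble with `mean_accuracy`, `sd_accuracy`, `folds` and a
#'   list-column `fold_accuracy`.
#' @examples
#' cohort <- simulate_cohort(n = 499, seed = 7)
#' km <- orbit_kmeans(cohort, seed = 7)
#' cv_lda(cohort[, c("depth_mm", "height_mm", "width_mm")], km$cluster,
#'        seed = 7)
#' @export
cv_lda <- function(x, grouping, folds = 5, seed = NULL) {
  X <- as.matrix(x)
  g <- factor(grouping)
  stopifnot(folds >= 2, nrow(X) == length(g))

  assign_folds <- function() {
    f <- integer(length(g))
    for (l in levels(g)) {
      idx <- which(g == l)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  }
  f <- if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())

  acc <- vapply(seq_len(folds), function(k) {
    train <- f != k
    fit <- orbit_lda(X[train, , drop = FALSE], g[train])
    mean(predict(fit, X[!train, , drop = FALSE]) == g[!train])
  }, numeric(1))
  tibble::tibble(mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 folds = folds, fold_accuracy = list(acc))
}

#' Derive the height/depth decision-rule cut-offs
#'
#' Recovers the two-threshold decision stump from labelled data, constrained
#' to the published structure: a root threshold on height separating A from
#' B and C, and a child threshold on depth separating B from C among the
#' low-height records. Both thresholds are found by exhaustive search over
#' midpoints of consecutive sorted unique values, maximizing overall
#' training accuracy; ties break toward the smaller threshold.
#'
#' @param data Data frame with `height_mm` and `depth_mm`.
#' @param labels Morphotype labels (A/B/C), one per row; all three classes
#'   must be present.
#' @return A tibble with `h_cut`, `d_cut` and `accuracy` (training).
#' @examples
#' cohort <- simulate_cohort(n = 499, seed = 8)
#' derive_rule_cutoffs(cohort, cohort$true_type)
#' @export
derive_rule_cutoffs <- function(data, labels) {
  check_columns(data, c("height_mm", "depth_mm"))
  lab <- as.character(labels)
  if (!all(ORBIT_TYPES %in% lab)) abort("all three classes must be present")
  H <- data$height_mm; D <- data$depth_mm
  n <- length(lab)

  h_cands <- midpoints(H)
  best <- list(acc = -1, h = NA_real_, d = NA_real_)
  for (h in h_cands) {
    upper <- H > h
    acc_a <- sum(upper & lab == "A")
    low <- !upper
    dl <- D[low]; ll <- lab[low]
    if (!length(dl)) next
    d_cands <- midpoints(dl)
    # for each depth split: correct = (#B with D > d) + (#C with D <= d)
    ord <- order(dl)
    ds <- dl[ord]; ls <- ll[ord]
    cumB <- cumsum(ls == "B"); cumC <- cumsum(ls == "C")
    nB <- sum(ls == "B")
    pos <- findInterval(d_cands, ds)            # records with D <= d; >= 1
    correct <- (nB - cumB[pos]) + cumC[pos]
    j <- which.max(correct)                     # first max: smaller threshold
    acc <- (acc_a + correct[j]) / n
    if (acc > best$acc) best <- list(acc = acc, h = h, d = d_cands[j])
  }
  tibble::tibble(h_cut = best$h, d_cut = best$d, accuracy = best$acc)
}

midpoints <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2L) return(u)
  (u[-1] + u[-length(u)]) / 2
}

check_columns <- function(data, cols) {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Optimize the depth-only cut points
#'
#' Finds the pair of depth cut points `d1 < d2` maximizing the accuracy of
#' the interval classifier `D <= d1 -> C`, `d1 < D <= d2 -> A`, `D > d2 ->
#' B` by exhaustive search over ordered midpoint pairs, then attaches
#' percentile bootstrap confidence intervals from seeded record resamples.
#' The search is O(n log n) per dataset: with depths sorted, the best lower
#' cut for every upper cut is a running prefix maximum.
#'
#' @param depth Numeric vector of orbital depths (mm).
#' @param labels Morphotype labels (A/B/C), one per value; all three classes
#'   must be present and at least 3 distinct depths are required.
#' @param bootstrap_B Bootstrap resamples for the CIs (default 1000; 0
#'   skips the bootstrap).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param objective `"accuracy"` (default) or `"balanced"` (mean per-class
#'   recall).
#' @return An object of class `depth_cutoffs`: `d1`, `d2`, `accuracy`,
#'   CI bounds and `bootstrap_B`. [tidy()] gives one row per cut point.
#' @examples
#' cohort <- simulate_cohort(n = 499, seed = 9)
#' optimize_depth_cutoffs(cohort$depth_mm, cohort$true_type,
#'                        bootstrap_B = 100, seed = 9)
#' @export
optimize_depth_cutoffs <- function(depth, labels, bootstrap_B = 1000,
                                   conf = 0.95, seed = NULL,
                                   objective = c("accuracy", "balanced")) {
  objective <- match.arg(objective)
  lab <- as.character(labels)
  stopifnot(length(depth) == length(lab))
  if (!all(ORBIT_TYPES %in% lab)) abort("all three classes must be present")
  if (length(unique(depth)) < 3L) abort("fewer than 3 distinct depth values")
  stopifnot(bootstrap_B >= 0)

  point <- best_depth_pair(depth, lab, objective)

  ci_d1 <- ci_d2 <- c(NA_real_, NA_real_)
  if (bootstrap_B >= 1) {
    n <- length(depth)
    boot <- function() {
      t(vapply(seq_len(bootstrap_B), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        if (length(unique(lab[i])) < 3L || length(unique(depth[i])) < 3L) {
          return(c(point$d1, point$d2))   # degenerate resample: keep point est.
        }
        fit <- best_depth_pair(depth[i], lab[i], objective)
        c(fit$d1, fit$d2)
      }, numeric(2)))
    }
    reps <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
    alpha <- (1 - conf) / 2
    ci_d1 <- unname(quantile(reps[, 1], c(alpha, 1 - alpha)))
    ci_d2 <- unname(quantile(reps[, 2], c(alpha, 1 - alpha)))
  }

  structure(
    list(d1 = point$d1, d2 = point$d2, accuracy = point$acc,
         ci_d1 = ci_d1, ci_d2 = ci_d2, conf = conf,
         bootstrap_B = bootstrap_B, objective = objective,
         depth = depth, labels = lab),
    class = "depth_cutoffs")
}

# Exhaustive ordered-pair search via prefix sums. For cut indices i < j over
# sorted candidate midpoints, correct(i, j) = #C[<=i] + #A[(i, j]] + #B[> j];
# maximizing over i for each j reduces to a running prefix maximum of
# (#C[<=i] - #A[<=i]). Ties break toward smaller thresholds (first maximum).
best_depth_pair <- function(depth, lab, objective = "accuracy") {
  ord <- order(depth)
  d <- depth[ord]; l <- lab[ord]
  cands <- midpoints(d)                         # >= 2 since >= 3 distinct depths
  pos <- findInterval(cands, d)                 # count of records <= cand
  cumA <- cumsum(l == "A"); cumB <- cumsum(l == "B"); cumC <- cumsum(l == "C")
  nA <- sum(l == "A"); nB <- sum(l == "B"); nC <- sum(l == "C")

  if (objective == "accuracy") {
    g1 <- cumC[pos] - cumA[pos]                 # gain from the lower cut at i
    upper <- cumA[pos] + (nB - cumB[pos])       # gain from the upper cut at j
    denom <- length(d)
  } else {
    g1 <- cumC[pos] / nC - cumA[pos] / nA
    upper <- cumA[pos] / nA + (nB - cumB[pos]) / nB
    denom <- 3
  }
  g1cm <- cummax(g1)
  m <- length(cands)
  jidx <- 2:m
  total <- g1cm[jidx - 1L] + upper[jidx]
  j <- jidx[which.max(total)]
  i <- match(g1cm[j - 1L], g1[seq_len(j - 1L)])
  list(d1 = cands[i], d2 = cands[j], acc = max(total) / denom)
}

#' @export
print.depth_cutoffs <- function(x, ...) {
  cat("Depth-only cut points (mm):\n")
  cat(sprintf("  d1 = %.3f", x$d1))
  if (!is.na(x$ci_d1[1])) {
    cat(sprintf("  (%.0f%% CI %.3f-%.3f)", 100 * x$conf, x$ci_d1[1], x$ci_d1[2]))
  }
  cat(sprintf("\n  d2 = %.3f", x$d2))
  if (!is.na(x$ci_d2[1])) {
    cat(sprintf("  (%.0f%% CI %.3f-%.3f)", 100 * x$conf, x$ci_d2[1], x$ci_d2[2]))
  }
  cat(sprintf("\n  training %s: %.3f\n", x$objective, x$accuracy))
  invisible(x)
}

#' @rdname optimize_depth_cutoffs
#' @param x A `depth_cutoffs` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.depth_cutoffs <- function(x, ...) {
  tibble::tibble(
    cutoff = c("d1", "d2"),
    estimate = c(x$d1, x$d2),
    ci_lower = c(x$ci_d1[1], x$ci_d2[1]),
    ci_upper = c(x$ci_d1[2], x$ci_d2[2])
  )
}

#' @rdname optimize_depth_cutoffs
#' @exportS3Method generics::glance
glance.depth_cutoffs <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, objective = x$objective,
                 bootstrap_B = x$bootstrap_B, n = length(x$depth))
}
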