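test_that("standardization has exact closed-form behaviour and round trips", {
  x <- tibble::tibble(depth_mm = c(1, 2, 3), height_mm = c(4, 6, 8),
                      width_mm = c(10, 20, 30))
  s <- standardize_dims(x)
  expect_equal(unname(s$scaled[, "depth_mm"]), c(-1, 0, 1))
  back <- unstandardize_dims(s$scaled, s$center, s$scale)
  expect_equal(unname(back), unname(as.matrix(x)), tolerance = 1e-9)
  expect_equal(unname(colMeans(s$scaled)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(s$scaled, 2, sd)), c(1, 1, 1), tolerance = 1e-9)

  const <- dplyr::mutate(x, width_mm = 5)
  expect_error(standardize_dims(const), "constant column")
})

test_that("standardization constants on a large cohort match the mixture moments", {
  co <- simulate_cohort(n = 50000, seed = 101)
  s <- standardize_dims(co)
  params <- morphotype_parameters()
  for (dm in c("depth_mm", "height_mm", "width_mm")) {
    p <- params[params$dimension == dm, ]
    mo <- Map(truncnorm_moments_quad, p$mean, p$sd, p$min, p$max)
    m_k <- vapply(mo, `[[`, numeric(1), "mean")
    v_k <- vapply(mo, `[[`, numeric(1), "var")
    mix_mean <- sum(p$prevalence * m_k)
    mix_var <- sum(p$prevalence * (v_k + m_k^2)) - mix_mean^2
    expect_equal(unname(s$center[dm]), mix_mean, tolerance = 0.01)
    expect_equal(unname(s$scale[dm]), sqrt(mix_var), tolerance = 0.01)
  }
})

test_that("k-means solves trivial geometries exactly", {
  # three far-apart points: each its own cluster, objective zero
  x <- tibble::tibble(depth_mm = c(0, 100, 200) + 40,
                      height_mm = c(0, 100, 200) + 30,
                      width_mm = c(0, 100, 200) + 30)
  km <- orbit_kmeans(x, k = 3, seed = 1, restarts = 3)
  expect_equal(km$tot_withinss, 0, tolerance = 1e-12)
  expect_equal(sort(km$sizes), c(1, 1, 1))

  # two tight separated blobs: partition equals blob membership for any seed
  withr::with_seed(7, {
    blob <- rbind(matrix(rnorm(150, 0, 0.01), ncol = 3) + 10,
                  matrix(rnorm(150, 0, 0.01), ncol = 3) - 10)
  })
  df <- tibble::as_tibble(as.data.frame(blob)) |>
    rlang::set_names(c("depth_mm", "height_mm", "width_mm")) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), ~ .x + 30))
  for (sd_ in c(2, 3, 4)) {
    km2 <- orbit_kmeans(df, k = 2, seed = sd_, restarts = 2)
    expect_equal(length(unique(km2$cluster[1:50])), 1L)
    expect_equal(length(unique(km2$cluster[51:100])), 1L)
    expect_false(km2$cluster[1] == km2$cluster[51])
  }
})

test_that("k-means is deterministic under a seed and invariant to row duplication", {
  co <- simulate_cohort(n = 300, seed = 111)
  a <- orbit_kmeans(co, seed = 5)
  b <- orbit_kmeans(co, seed = 5)
  expect_identical(a$centers_std, b$centers_std)
  expect_identical(a$cluster, b$cluster)

  dup <- dplyr::bind_rows(co, co)
  kd <- orbit_kmeans(dup, seed = 5)
  # same optimum up to cluster relabeling: compare sorted raw centroids
  expect_equal(a$centers_raw[order(a$centers_raw[, 1]), ],
               kd$centers_raw[order(kd$centers_raw[, 1]), ],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(orbit_kmeans(co[1:2, ], k = 3), "at least k")
})

test_that("k-means matches the stats::kmeans objective on a reference cohort", {
  co <- simulate_cohort(n = 499, seed = 121)
  km <- orbit_kmeans(co, seed = 9)
  ref <- withr::with_seed(9, stats::kmeans(standardize_dims(co)$scaled, 3,
                                           nstart = 10, iter.max = 300))
  # independent implementation should find (essentially) the same optimum
  expect_equal(km$tot_withinss, ref$tot.withinss, tolerance = 1e-4)
})

test_that("cluster naming follows height-then-depth anatomy and ignores labels", {
  co <- simulate_cohort(n = 499, seed = 131)
  km <- orbit_kmeans(co, seed = 13)
  map <- name_clusters(km)
  expect_setequal(unname(map), c("A", "B", "C"))
  a_idx <- as.integer(names(map)[map == "A"])
  b_idx <- as.integer(names(map)[map == "B"])
  expect_equal(a_idx, which.max(km$centers_raw[, "height_mm"]))
  expect_gt(km$centers_raw[b_idx, "depth_mm"],
            km$centers_raw[setdiff(1:3, c(a_idx, b_idx)), "depth_mm"])

  # permuting cluster indices permutes the map, not the type assignment
  perm <- c(2L, 3L, 1L)
  km2 <- km
  km2$centers_raw <- km$centers_raw[perm, ]
  km2$centers_std <- km$centers_std[perm, ]
  km2$cluster <- match(km$cluster, perm)
  map2 <- name_clusters(km2)
  expect_equal(unname(map2[as.character(km2$cluster)]),
               unname(map[as.character(km$cluster)]))

  # degenerate all-equal centroids: deterministic tie-break with a warning
  km3 <- km
  km3$centers_raw <- matrix(30, 3, 3,
                            dimnames = list(NULL, colnames(km$centers_raw)))
  expect_warning(map3 <- name_clusters(km3), "tie")
  expect_equal(unname(map3), c("A", "B", "C"))
})

test_that("k-means recovers the generating type centroids at large n", {
  co <- simulate_cohort(n = 100000, seed = 141)
  km <- orbit_kmeans(co, seed = 14)
  map <- name_clusters(km)
  cen <- km$centers_raw
  a <- which(map == "A"); b <- which(map == "B")
  # dominant axes: height of A and depth of B near the published type means
  expect_lt(abs(cen[a, "height_mm"] - 35.97), 0.3)
  expect_lt(abs(cen[b, "depth_mm"] - 43.52), 0.3)
})

test_that("LDA separates well-separated classes perfectly", {
  withr::with_seed(23, {
    X <- rbind(matrix(rnorm(300, 0, 0.1), ncol = 3) + c(5, 0, 0),
               matrix(rnorm(300, 0, 0.1), ncol = 3) - c(5, 0, 0))
  })
  g <- rep(c("a", "b"), each = 100)
  cv <- cv_lda(X, g, folds = 5, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$sd_accuracy, 0)
})

test_that("two-class equal-prior LDA boundary sits at the midpoint of the means", {
  withr::with_seed(29, {
    x <- matrix(c(rnorm(200, 0, 1), rnorm(200, 4, 1)), ncol = 1)
  })
  g <- rep(c("lo", "hi"), each = 200)
  fit <- orbit_lda(x, g)
  mid <- mean(fit$means)
  eps <- 1e-6
  expect_equal(predict(fit, matrix(mid - 1e-3)), "lo")
  expect_equal(predict(fit, matrix(mid + 1e-3)), "hi")
  # with empirical equal priors the flip occurs within 1e-6 of the midpoint
  expect_equal(predict(fit, matrix(mid - eps)), "lo")
  expect_equal(predict(fit, matrix(mid + eps)), "hi")
})

test_that("LDA predictions equal the brute-force Gaussian posterior oracle", {
  co <- simulate_cohort(n = 1500, seed = 151)
  X <- as.matrix(co[, c("depth_mm", "height_mm", "width_mm")])
  fit <- orbit_lda(X, co$true_type)
  withr::with_seed(31, {
    grid <- cbind(runif(1000, 30, 50), runif(1000, 25, 40), runif(1000, 25, 45))
  })
  expect_equal(predict(fit, grid), gaussian_posterior_oracle(fit, grid))
})

test_that("LDA agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  co <- simulate_cohort(n = 800, seed = 161)
  X <- as.matrix(co[, c("depth_mm", "height_mm", "width_mm")])
  fit <- orbit_lda(X, co$true_type)
  ref <- MASS::lda(X, grouping = co$true_type)
  expect_equal(predict(fit, X),
               as.character(predict(ref, X)$class))
})

test_that("LDA rejects degenerate inputs", {
  expect_error(orbit_lda(matrix(1:4, ncol = 1), c("a", "a", "a", "a")),
               "2 classes")
  X <- cbind(1:6, 1:6)   # perfectly collinear: singular pooled covariance
  expect_error(orbit_lda(X, rep(c("a", "b"), 3)), "singular")
})

test_that("stratified CV is seeded and balanced", {
  co <- simulate_cohort(n = 400, seed = 171)
  X <- co[, c("depth_mm", "height_mm", "width_mm")]
  a <- cv_lda(X, co$true_type, seed = 7)
  b <- cv_lda(X, co$true_type, seed = 7)
  expect_identical(a, b)
  expect_equal(length(a$fold_accuracy[[1]]), 5)
})

test_that("rule cut-off derivation recovers separated thresholds exactly", {
  withr::with_seed(37, {
    toy <- tibble::tibble(
      height_mm = c(rnorm(30, 40, 0.1), rnorm(30, 30, 0.1), rnorm(30, 30, 0.1)),
      depth_mm = c(rnorm(30, 40, 0.1), rnorm(30, 45, 0.1), rnorm(30, 35, 0.1))
    )
  })
  lab <- rep(c("A", "B", "C"), each = 30)
  got <- derive_rule_cutoffs(toy, lab)
  expect_equal(got$accuracy, 1)
  expect_gt(got$h_cut, 30.1); expect_lt(got$h_cut, 39.9)
  expect_gt(got$d_cut, 35.1); expect_lt(got$d_cut, 44.9)
})

test_that("rule derivation is self-consistent with the fixed classifier", {
  co <- simulate_cohort(n = 600, seed = 181)
  labels <- classify_orbits(co)$pred_type
  got <- derive_rule_cutoffs(co, labels)
  expect_equal(got$accuracy, 1)
  # re-applying the derived thresholds reproduces the labels
  re <- classify_orbits(co, orbit_cutoffs(h_cut = got$h_cut,
                                          d_cut = got$d_cut))
  expect_equal(re$pred_type, labels)
})

test_that("three single points per class put thresholds at midpoints", {
  toy <- tibble::tibble(height_mm = c(40, 30, 32), depth_mm = c(40, 45, 35))
  got <- derive_rule_cutoffs(toy, c("A", "B", "C"))
  expect_equal(got$h_cut, 36)        # midpoint of 32 and 40
  expect_equal(got$d_cut, 40)        # midpoint of 35 and 45
  expect_equal(got$accuracy, 1)
  expect_error(derive_rule_cutoffs(toy, c("A", "B", "B")), "three classes")
})

test_that("depth cut-point search matches the exhaustive pair oracle", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      n <- 60
      lab <- sample(c("A", "B", "C"), n, replace = TRUE)
      mu <- c(A = 40.1, B = 43.5, C = 38.6)
      depth <- rnorm(n, mu[lab], 2)
      got <- optimize_depth_cutoffs(depth, lab, bootstrap_B = 0)
      want <- depth_pair_bruteforce(depth, lab)
      expect_equal(got$accuracy, want$acc)
      expect_equal(got$d1, want$d1)
      expect_equal(got$d2, want$d2)
    }
  })
})

test_that("disjoint depth bands are separated with accuracy 1", {
  depth <- c(runif(20, 30, 34), runif(20, 40, 41), runif(20, 45, 50))
  lab <- rep(c("C", "A", "B"), each = 20)
  got <- optimize_depth_cutoffs(depth, lab, bootstrap_B = 0)
  expect_equal(got$accuracy, 1)
  expect_gt(got$d1, 34); expect_lt(got$d1, 40)
  expect_gt(got$d2, 41); expect_lt(got$d2, 45)
  expect_lt(got$d1, got$d2)
})

test_that("depth optimization validates input and seeds its bootstrap", {
  expect_error(optimize_depth_cutoffs(rep(40, 10),
                                      rep(c("A", "B", "C"), length.out = 10)),
               "fewer than 3 distinct depth values")
  co <- simulate_cohort(n = 250, seed = 191)
  a <- optimize_depth_cutoffs(co$depth_mm, co$true_type, bootstrap_B = 50,
                              seed = 2)
  b <- optimize_depth_cutoffs(co$depth_mm, co$true_type, bootstrap_B = 50,
                              seed = 2)
  expect_identical(a$ci_d1, b$ci_d1)
  expect_lte(a$ci_d1[1], a$d1); expect_gte(a$ci_d1[2], a$d1)
  expect_lte(a$ci_d2[1], a$d2); expect_gte(a$ci_d2[2], a$d2)
})
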