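# Shared fixtures and independent oracles, built in code at test time.

# Tiny hand-written cohort: one record per type at the type mean dimensions.
tiny_cohort <- function() {
  tibble::tibble(
    orbit_id = c("a1", "b1", "c1"),
    side = "left", sex = "unknown", age_years = NA_real_,
    depth_mm = c(40.10, 43.52, 38.56),
    height_mm = c(35.97, 32.79, 32.48),
    width_mm = c(37.11, 36.76, 34.22),
    modality = "synthetic",
    true_type = c("A", "B", "C")
  )
}

# Quadrature oracle for truncated-normal moments: numerical integration of
# the truncated density, independent of the closed-form Mills-ratio route.
truncnorm_moments_quad <- function(mean, sd, min, max) {
  z <- stats::integrate(function(x) dnorm(x, mean, sd), min, max,
                        rel.tol = 1e-10)$value
  m <- stats::integrate(function(x) x * dnorm(x, mean, sd), min, max,
                        rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * dnorm(x, mean, sd), min, max,
                         rel.tol = 1e-10)$value / z
  list(mean = m, var = m2 - m^2)
}

# Brute-force Gaussian posterior oracle for LDA predictions: full density
# evaluation per class, no linear-score shortcut.
gaussian_posterior_oracle <- function(fit, X) {
  k <- length(fit$levels)
  Sinv <- solve(fit$pooled_cov)
  logdet <- determinant(fit$pooled_cov, logarithm = TRUE)$modulus
  loglik <- vapply(seq_len(k), function(j) {
    d <- sweep(X, 2L, fit$means[j, ])
    -0.5 * rowSums((d %*% Sinv) * d) - 0.5 * logdet + log(fit$priors[j])
  }, numeric(nrow(X)))
  fit$levels[max.col(loglik, ties.method = "first")]
}

# Exhaustive O(n^2) search over ordered midpoint pairs for the depth-only
# rule, used as the oracle for the prefix-sum implementation.
depth_pair_bruteforce <- function(depth, lab) {
  u <- sort(unique(depth))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- list(acc = -1)
  for (i in seq_along(cands)) {
    for (j in seq_along(cands)) {
      if (i >= j) next
      pred <- ifelse(depth <= cands[i], "C",
                     ifelse(depth <= cands[j], "A", "B"))
      acc <- mean(pred == lab)
      if (acc > best$acc) best <- list(acc = acc, d1 = cands[i], d2 = cands[j])
    }
  }
  best
}
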