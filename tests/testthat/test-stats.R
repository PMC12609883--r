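test_that("ANOVA matches the hand sum-of-squares decomposition", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5, 6),
                       g = rep(c("a", "b"), each = 3))
  got <- anova_eta2(df, "x", "g")
  # SSB = 13.5, SSW = 4, df (1, 4): F = 13.5 / 1 = 13.5
  expect_equal(got$statistic, 13.5)
  expect_equal(got$df_between, 1)
  expect_equal(got$df_within, 4)
  expect_equal(got$effect_size, 13.5 / 17.5)
  expect_equal(got$p_value, pf(13.5, 1, 4, lower.tail = FALSE))

  same <- tibble::tibble(x = c(1, 2, 3, 1, 2, 3), g = df$g)
  got0 <- anova_eta2(same, "x", "g")
  expect_equal(got0$statistic, 0)
  expect_equal(got0$effect_size, 0)
})

test_that("ANOVA rejects degenerate groups", {
  expect_error(anova_eta2(tibble::tibble(x = c(1, 2, 3), g = c("a", "a", "b")),
                          "x", "g"), "at least 2")
  expect_error(anova_eta2(tibble::tibble(x = rep(1, 6),
                                         g = rep(c("a", "b"), 3)),
                          "x", "g"), "zero total variance")
})

test_that("Kruskal-Wallis equals the hand rank formula and is order-invariant", {
  df <- tibble::tibble(x = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  got <- kruskal_wallis(df, "x", "g")
  # ranks 1..4; R_a = 3, R_b = 7; H = 12/(4*5) * (9/2 + 49/2) - 3*5 = 2.4
  expect_equal(got$statistic, 2.4)
  expect_equal(got$df, 1)

  co <- simulate_cohort(n = 300, seed = 201)
  a <- kruskal_wallis(co, "width_mm", "true_type")
  withr::with_seed(3, perm <- sample.int(nrow(co)))
  b <- kruskal_wallis(co[perm, ], "width_mm", "true_type")
  expect_equal(a$statistic, b$statistic)

  twin <- tibble::tibble(x = c(1, 2, 3, 1, 2, 3),
                         g = rep(c("a", "b"), each = 3))
  expect_lt(kruskal_wallis(twin, "x", "g")$statistic, 0.2)
  expect_error(kruskal_wallis(tibble::tibble(x = rep(2, 6),
                                             g = rep(c("a", "b"), 3)),
                              "x", "g"), "identical")
})

test_that("Mann-Whitney U and rank-biserial match the exhaustive pair count", {
  df <- tibble::tibble(x = c(3, 4, 5, 0, 1, 2),
                       g = rep(c("g1", "g2"), each = 3))
  got <- mann_whitney_rb(df, "x", "g")
  expect_equal(got$statistic, 9)       # all 9 pairs favour the first group
  expect_equal(got$effect_size, 1)

  tie <- tibble::tibble(x = c(1, 2, 3, 1, 2, 3), g = df$g)
  got0 <- mann_whitney_rb(tie, "x", "g")
  expect_equal(got0$effect_size, 0)
})

test_that("exact Mann-Whitney p equals the brute-force permutation oracle", {
  withr::with_seed(43, {
    for (rep in 1:4) {
      x <- round(rnorm(4, 0, 5), 3)   # no ties (continuous draws)
      y <- round(rnorm(4, 1, 5), 3)
      df <- tibble::tibble(x = c(x, y), g = rep(c("a", "b"), each = 4))
      got <- mann_whitney_rb(df, "x", "g")
      # enumerate all choose(8,4) assignments of ranks to the first group
      pooled <- c(x, y)
      u_obs <- sum(outer(x, y, `>`))
      combs <- utils::combn(8, 4)
      us <- apply(combs, 2, function(i) {
        sum(outer(pooled[i], pooled[-i], `>`))
      })
      p_perm <- mean(abs(us - 8) >= abs(u_obs - 8))   # two-sided around E[U]=8
      expect_equal(got$p_value, p_perm, tolerance = 1e-12)
    }
  })
})

test_that("Spearman correlation handles the exact and degenerate cases", {
  df <- tibble::tibble(a = 1:10, b = 1:10, c = 10:1)
  expect_equal(spearman_rho(df, "a", "b")$statistic, 1)
  expect_equal(spearman_rho(df, "a", "c")$statistic, -1)
  expect_error(spearman_rho(tibble::tibble(a = 1:5, b = rep(2, 5)), "a", "b"),
               "constant")
})

test_that("pairwise post hoc reports every pair with Bonferroni adjustment", {
  withr::with_seed(47, base <- rnorm(30))
  # a and b share the same noise with a negligible shift: never significant;
  # c is far separated: always significant
  df <- tibble::tibble(
    x = c(base, base + 0.01, base + 5),
    g = rep(c("a", "b", "c"), each = 30)
  )
  got <- pairwise_posthoc(df, "x", "g")
  expect_equal(nrow(got), 3)
  expect_true(all(got$p_adjusted >= got$p_value))
  expect_true(all(got$p_adjusted <= 1))
  # far-separated pairs significant, overlapping pair not
  ac <- got[got$group1 == "a" & got$group2 == "c", ]
  bc <- got[got$group1 == "b" & got$group2 == "c", ]
  ab <- got[got$group1 == "a" & got$group2 == "b", ]
  expect_lt(ac$p_adjusted, 0.001)
  expect_lt(bc$p_adjusted, 0.001)
  expect_gt(ab$p_adjusted, 0.05)

  raw <- pairwise_posthoc(df, "x", "g", method = "none")
  expect_equal(raw$p_adjusted, raw$p_value)
})

test_that("analytic mixture eta-squared matches large-n simulation (truncated route)", {
  analytic <- mixture_eta2(moments = "truncated")
  co <- simulate_cohort(n = 100000, seed = 211)
  for (dm in c("depth_mm", "height_mm", "width_mm")) {
    sim <- anova_eta2(co, dm, "true_type")$effect_size
    want <- analytic$eta_squared[analytic$dimension == dm]
    expect_lt(abs(sim - want), 0.005)
  }
})

test_that("statistics are invariant to within-group reordering", {
  co <- simulate_cohort(n = 200, seed = 221)
  withr::with_seed(7, perm <- sample.int(nrow(co)))
  for (f in list(anova_eta2, kruskal_wallis)) {
    expect_equal(f(co, "depth_mm", "true_type"),
                 f(co[perm, ], "depth_mm", "true_type"))
  }
})
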