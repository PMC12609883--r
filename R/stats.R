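#' One-way ANOVA with eta-squared effect size
#'
#' Classical fixed-effects one-way ANOVA through [stats::aov()], augmented
#' with the eta-squared effect size computed from the sum-of-squares
#' decomposition: `eta^2 = SSB / (SSB + SSW)`, the fraction of total
#' variance explained by group membership.
#'
#' @param data Data frame in long format.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column (>= 2 groups, each with >= 2
#'   values).
#' @return One-row tibble: `method`, `statistic` (F), `df_between`,
#'   `df_within`, `p_value`, `effect_size` (eta-squared), `effect_type`,
#'   `n_groups`, `n`.
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 10)
#' anova_eta2(cohort, "depth_mm", "true_type")
#' @export
anova_eta2 <- function(data, value, group) {
  v <- check_group_data(data, value, group, min_per_group = 2L)
  if (var(v$x) == 0) abort("zero total variance: ANOVA undefined")
  fit <- aov(x ~ g, data = v)
  ss <- summary(fit)[[1]]
  ssb <- ss[["Sum Sq"]][1]; ssw <- ss[["Sum Sq"]][2]
  tibble::tibble(
    method = "one-way ANOVA",
    statistic = ss[["F value"]][1],
    df_between = ss[["Df"]][1], df_within = ss[["Df"]][2],
    p_value = ss[["Pr(>F)"]][1],
    effect_size = ssb / (ssb + ssw), effect_type = "eta_squared",
    n_groups = nlevels(v$g), n = nrow(v)
  )
}

#' Kruskal-Wallis rank test
#'
#' Wrapper around [stats::kruskal.test()] (midrank tie correction,
#' chi-square approximation on k - 1 degrees of freedom) returning the
#' package's tidy comparison row.
#'
#' @inheritParams anova_eta2
#' @return One-row tibble with `statistic` (H), `df`, `p_value`,
#'   `n_groups`, `n`.
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 11)
#' kruskal_wallis(cohort, "width_mm", "true_type")
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- check_group_data(data, value, group, min_per_group = 1L)
  if (nrow(v) < 3L) abort("need at least 3 observations in total")
  if (length(unique(v$x)) == 1L) {
    abort("all values identical: rank test undefined without variance")
  }
  kt <- kruskal.test(x ~ g, data = v)
  tibble::tibble(
    method = "Kruskal-Wallis", statistic = unname(kt$statistic),
    df = unname(kt$parameter), p_value = kt$p.value,
    n_groups = nlevels(v$g), n = nrow(v)
  )
}

#' Mann-Whitney U test with rank-biserial correlation
#'
#' Two-sample rank comparison via [stats::wilcox.test()] plus the
#' rank-biserial effect size `r_rb = 2U/(n1 n2) - 1`, oriented so a positive
#' value means the first group is stochastically larger. The p-value uses
#' exact enumeration when `n1 * n2 <= 400` and the data have no ties, and
#' the tie-corrected normal approximation otherwise.
#'
#' @inheritParams anova_eta2
#' @param group Grouping column with exactly two levels; the first level in
#'   sort (or factor) order is the reference group of the orientation.
#' @return One-row tibble with `statistic` (U of the first group),
#'   `p_value`, `effect_size` (r_rb), group labels and sizes.
#' @examples
#' cohort <- simulate_cohort(n = 200, seed = 12,
#'   covariates = covariate_model(sex_depth_shift = 1.5))
#' mann_whitney_rb(cohort, "depth_mm", "sex")   # F vs M
#' @export
mann_whitney_rb <- function(data, value, group) {
  v <- check_group_data(data, value, group, min_per_group = 1L)
  if (nlevels(v$g) != 2L) abort("`group` must have exactly two levels")
  x <- v$x[v$g == levels(v$g)[1]]
  y <- v$x[v$g == levels(v$g)[2]]
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 * n2 <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  u <- unname(wt$statistic)                    # U = #{x_i > y_j} (+ ties/2)
  tibble::tibble(
    method = paste0("Mann-Whitney U (", if (exact) "exact" else "normal approx.", ")"),
    statistic = u, p_value = wt$p.value,
    effect_size = 2 * u / (n1 * n2) - 1, effect_type = "rank_biserial",
    group1 = levels(v$g)[1], group2 = levels(v$g)[2], n1 = n1, n2 = n2
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with the asymptotic t-approximation
#' p-value, via [stats::cor.test()].
#'
#' @param data Data frame.
#' @param x,y Names of the two numeric columns (equal length >= 3 after
#'   dropping incomplete pairs).
#' @return One-row tibble with `statistic` (rho), `p_value`, `n`.
#' @examples
#' cohort <- simulate_cohort(n = 499, seed = 13)
#' spearman_rho(cohort, "age_years", "width_mm")   # ~ -0.11 by construction
#' @export
spearman_rho <- function(data, x, y) {
  check_columns(data, c(x, y))
  xv <- data[[x]]; yv <- data[[y]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) abort("need at least 3 complete pairs")
  if (length(unique(xv)) == 1L || length(unique(yv)) == 1L) {
    abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(
    method = "Spearman rank correlation",
    statistic = unname(ct$estimate), p_value = ct$p.value, n = length(xv)
  )
}

#' Pairwise post hoc comparisons
#'
#' All pairwise two-sample comparisons between groups with Welch's t-test
#' and Bonferroni correction (`p_adj = min(1, m * p)` over the m pairs).
#'
#' @inheritParams anova_eta2
#' @param method `"bonferroni_welch"` (default) or `"none"` (raw Welch
#'   p-values).
#' @return Tibble with one row per pair: group labels and sizes, mean
#'   difference, `statistic` (t), `p_value`, `p_adjusted`.
#' @examples
#' cohort <- simulate_cohort(n = 300, seed = 14)
#' pairwise_posthoc(cohort, "height_mm", "true_type")
#' @export
pairwise_posthoc <- function(data, value, group,
                             method = c("bonferroni_welch", "none")) {
  method <- match.arg(method)
  v <- check_group_data(data, value, group, min_per_group = 2L)
  lev <- levels(v$g)
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- v$x[v$g == pr[1]]; b <- v$x[v$g == pr[2]]
    tt <- t.test(a, b)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(a), n2 = length(b),
                   mean_diff = mean(a) - mean(b),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  })
  out$p_adjusted <- if (method == "none") out$p_value else {
    pmin(1, length(pairs) * out$p_value)
  }
  out
}

#' Analytic eta-squared of the three-type mixture
#'
#' Closed-form between/within variance decomposition of a dimension under
#' the three-component mixture: with type weights `p_k`, group means `m_k`
#' and group variances `v_k`,
#' `eta^2 = sum p_k (m_k - m)^2 / (sum p_k (m_k - m)^2 + sum p_k v_k)`.
#'
#' Two moment conventions are available. `"printed"` uses the tabulated
#' per-type mean/sd directly as the group moments — appropriate when the
#' table reports empirical moments of an observed cohort. `"truncated"`
#' uses the moments of the truncated normals actually sampled by
#' [simulate_cohort()] (via [truncnorm_moments()]) — this is the convention
#' that matches large-n simulated cohorts.
#'
#' @param params Parameter table from [morphotype_parameters()].
#' @param dimension One of `"depth_mm"`, `"height_mm"`, `"width_mm"`, or
#'   `NULL` (default) for all three.
#' @param moments `"printed"` or `"truncated"` (see Details).
#' @return Tibble with one row per dimension: `dimension`, `eta_squared`,
#'   `ss_between`, `ss_within` (per-record expected values), `moments`.
#' @examples
#' mixture_eta2(morphotype_parameters())
#' mixture_eta2(morphotype_parameters(), moments = "truncated")
#' @export
mixture_eta2 <- function(params = morphotype_parameters(), dimension = NULL,
                         moments = c("printed", "truncated")) {
  moments <- match.arg(moments)
  validate_morphotype_parameters(params)
  dims <- dimension %||% DIM_COLS
  purrr::map_dfr(dims, function(dm) {
    p <- params[params$dimension == dm, ]
    if (moments == "truncated") {
      mo <- purrr::pmap(list(p$mean, p$sd, p$min, p$max), truncnorm_moments)
      m_k <- purrr::map_dbl(mo, "mean"); v_k <- purrr::map_dbl(mo, "var")
    } else {
      m_k <- p$mean; v_k <- p$sd^2
    }
    w <- p$prevalence
    gm <- sum(w * m_k)
    ssb <- sum(w * (m_k - gm)^2)
    ssw <- sum(w * v_k)
    tibble::tibble(dimension = dm, eta_squared = ssb / (ssb + ssw),
                   ss_between = ssb, ss_within = ssw, moments = moments)
  })
}

check_group_data <- function(data, value, group, min_per_group = 2L) {
  check_columns(data, c(value, group))
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- is.finite(x) & !is.na(g)
  v <- data.frame(x = x[ok], g = droplevels(g[ok]))
  if (nlevels(v$g) < 2L) abort("need at least 2 groups")
  sizes <- table(v$g)
  if (any(sizes < min_per_group)) {
    abort(paste0("every group needs at least ", min_per_group, " value(s)"))
  }
  v
}
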