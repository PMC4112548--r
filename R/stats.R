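# Statistical summaries and tests applied to per-cell / per-embryo
# measurements: mean +/- SEM, Kruskal-Wallis with Dunn's multiple
# comparison, two-sample tests, and one-way ANOVA with Tukey HSD.

#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 2.
#' @return Named vector `c(mean, sem)` with SEM = sample SD / sqrt(n).
#' @export
mean_sem <- function(values) {
  n <- length(values)
  if (n < 2) stop("SEM needs n >= 2")
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

# groups: named list of numeric vectors -> long data
groups_to_long <- function(groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("empty group")
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1))),
                            levels = names(groups)))
}

#' Kruskal--Wallis omnibus test with Dunn's multiple comparison
#'
#' The omnibus H statistic and p-value come from the rank-based
#' Kruskal--Wallis test with tie correction
#' ([stats::kruskal.test()]; optionally a label-permutation p-value).
#' Pairwise comparisons use Dunn's z statistics,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' tie term `T = sum(t^3 - t) / (12 (N - 1))`, adjusted for multiplicity
#' (Bonferroni by default).
#'
#' @param groups named list of numeric vectors, >= 3 groups (use
#'   [two_sample_tests()] for 2).
#' @param p_adjust multiplicity adjustment for the Dunn p-values, any
#'   [stats::p.adjust()] method.
#' @param p_method `"asymptotic"` (chi-squared) or `"permutation"` for the
#'   omnibus p-value.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @return List with `H`, `df`, `p` (omnibus) and `pairwise` (data frame:
#'   comparison, z, p_unadjusted, p_adjusted).
#' @export
kw_dunn <- function(groups, p_adjust = "bonferroni",
                    p_method = c("asymptotic", "permutation"),
                    n_perm = 10000L) {
  p_method <- match.arg(p_method)
  if (length(groups) < 3)
    stop("need >= 3 groups (use two_sample_tests for 2)")
  long <- groups_to_long(groups)
  if (diff(range(long$value)) == 0) {
    # fully tied data: no evidence of any difference
    lv <- if (is.null(names(groups))) paste0("g", seq_along(groups)) else
      names(groups)
    pairs <- utils::combn(lv, 2)
    pw <- data.frame(comparison = paste(pairs[1, ], pairs[2, ],
                                        sep = " vs "),
                     z = 0, p_unadjusted = 1, p_adjusted = 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1, pairwise = pw))
  }
  kw <- stats::kruskal.test(value ~ group, data = long)
  H <- unname(kw$statistic)
  p <- unname(kw$p.value)
  if (p_method == "permutation")
    p <- kw_permutation_p(long$value, long$group, n_perm)

  r <- rank(long$value)
  N <- length(r)
  ties <- table(long$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  lv <- levels(long$group)
  rbar <- tapply(r, long$group, mean)
  ns <- tapply(r, long$group, length)
  pairs <- utils::combn(lv, 2)
  z <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    z[i] <- (rbar[a] - rbar[b]) / sqrt(s2 * (1 / ns[a] + 1 / ns[b]))
  }
  p_un <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
                   z = z, p_unadjusted = p_un,
                   p_adjusted = stats::p.adjust(p_un, method = p_adjust))
  list(H = H, df = unname(kw$parameter), p = p, pairwise = pw)
}

# Kruskal-Wallis H for a fixed rank vector under permuted group labels
kw_h_stat <- function(r, group_sizes, tie_denominator) {
  N <- length(r)
  ends <- cumsum(group_sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  ss <- 0
  for (i in seq_along(group_sizes)) {
    ri <- sum(r[starts[i]:ends[i]])
    ss <- ss + ri^2 / group_sizes[i]
  }
  h <- 12 / (N * (N + 1)) * ss - 3 * (N + 1)
  h / tie_denominator
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis H
kw_permutation_p <- function(values, group, n_perm) {
  r <- rank(values)
  N <- length(r)
  ties <- table(values)
  cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  sizes <- as.integer(table(group))
  h_obs <- kw_h_stat(r, sizes, cf)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    hp <- kw_h_stat(sample(r), sizes, cf)
    if (hp >= h_obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Two-sample comparison: Student's t or Mann--Whitney U
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param sided `"two.sided"`, `"less"` or `"greater"` (alternative:
#'   location of `a` relative to `b`).
#' @param parametric `TRUE` for Student's t-test (pooled variance),
#'   `FALSE` for the Mann--Whitney U (Wilcoxon rank-sum) test.
#' @return The p-value, with the full htest object in attribute `"test"`.
#' @export
two_sample_tests <- function(a, b, sided = "two.sided", parametric = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (parametric) {
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("zero variance in both samples; t-test undefined")
    ht <- stats::t.test(a, b, alternative = sided, var.equal = TRUE)
  } else {
    ht <- stats::wilcox.test(a, b, alternative = sided, exact = FALSE,
                             correct = FALSE)
  }
  structure(unname(ht$p.value), test = ht)
}

#' One-way ANOVA with Tukey's multiple comparison
#'
#' @param groups named list of numeric vectors, >= 3 groups with n >= 2
#'   each.
#' @return List with `F`, `df` (c(between, within)), `p` and `pairwise`
#'   (data frame: comparison, diff, p_adjusted from Tukey HSD).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 3) stop("need >= 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  long <- groups_to_long(groups)
  fit <- stats::aov(value ~ group, data = long)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = an[1, "F value"], df = an[, "Df"], p = an[1, "Pr(>F)"],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adjusted = tk[, "p adj"],
                             row.names = NULL))
}
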