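## Shared statistical tests. Each is verifiable against a closed form or
## brute-force enumeration (see the test suite); results are returned in a
## uniform list shape so downstream reports can serialize them.

test_result <- function(method, statistic, p_value, df = NA_real_,
                        exact = FALSE, degenerate = FALSE, extra = list()) {
  c(list(method = method, statistic = statistic, p_value = p_value,
         df = df, exact = exact, degenerate = degenerate), extra)
}

#' Student's t test (pooled-variance unpaired, or paired)
#'
#' Unpaired form uses the pooled-variance Student statistic; a paired test
#' is a one-sample t on the within-pair differences. Degenerate inputs are
#' resolved explicitly: zero pooled variance with equal means gives
#' `t = 0, p = 1`; zero variance with unequal means is flagged degenerate
#' (infinite statistic, p = 0).
#'
#' @param x,y Numeric samples (equal length if `paired`).
#' @param paired Paired test on differences.
#' @param welch Use the Welch (unequal-variance) form instead of pooled.
#' @return A list: `method`, `statistic`, `p_value`, `df`, `exact`,
#'   `degenerate`.
#' @examples
#' ttest(c(1, 2, 3), c(2, 3, 4))$statistic  # -1.2247
#' @export
ttest <- function(x, y, paired = FALSE, welch = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (length(x) < 2L) stop("paired test needs n >= 2")
    d <- x - y
    sd_d <- stats::sd(d)
    if (sd_d <= 1e-12 * max(1, abs(mean(d)))) {
      if (mean(d) == 0)
        return(test_result("paired t", 0, 1, df = length(d) - 1))
      return(test_result("paired t", sign(mean(d)) * Inf, 0,
                         df = length(d) - 1, degenerate = TRUE))
    }
    tt <- stats::t.test(d)
    return(test_result("paired t", unname(tt$statistic), tt$p.value,
                       df = unname(tt$parameter)))
  }
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (welch) {
    tt <- stats::t.test(x, y)
    return(test_result("Welch t", unname(tt$statistic), tt$p.value,
                       df = unname(tt$parameter)))
  }
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 1e-24 * max(1, mean(x)^2, mean(y)^2)) {
    if (mean(x) == mean(y))
      return(test_result("Student t", 0, 1, df = df))
    return(test_result("Student t", sign(mean(x) - mean(y)) * Inf, 0,
                       df = df, degenerate = TRUE))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  test_result("Student t", tstat, 2 * stats::pt(-abs(tstat), df), df = df)
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' @param groups Named (or unnamed) list of numeric samples, each `n >= 2`.
#' @return A list: `method`, `statistic` (F), `p_value`, `df` (numerator,
#'   denominator), and `tukey`, a `data.frame` of pairwise comparisons with
#'   Tukey-adjusted p-values from the studentized range distribution.
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  # constant data gives NaN F; resolve as no evidence against the null
  fstat <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  if (is.nan(fstat)) { fstat <- 0; pval <- 1; tukey$p_adj <- 1 }
  test_result("one-way ANOVA + Tukey HSD", fstat, pval,
              df = c(an[["Df"]][1], an[["Df"]][2]),
              extra = list(tukey = tukey))
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' The statistic is `U = sum over (x, y) pairs of [x > y] + ties/2`
#' (equivalently the rank-sum form). When the combined sample size is at
#' most `exact_max` the two-sided p-value is exact:
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` under the permutation null,
#' computed from the Wilcoxon distribution for untied data and by direct
#' enumeration over group labelings when ties are present (the closed-form
#' distribution does not cover ties, but enumeration does). Beyond
#' `exact_max` a normal approximation with tie correction and continuity
#' correction is used. Exposed under both of the field's names.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param exact_max Maximum combined size for the exact tail computation.
#' @return A list: `method`, `statistic` (U of the first sample),
#'   `p_value`, `exact`.
#' @export
mann_whitney <- function(x, y, exact_max = 16L) {
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (nx + ny <= exact_max) {
    if (!ties) {
      p_le <- stats::pwilcox(u, nx, ny)
      p_ge <- 1 - stats::pwilcox(u - 1, nx, ny)
    } else {
      us <- apply(utils::combn(nx + ny, nx), 2, function(idx)
        sum(r[idx]) - nx * (nx + 1) / 2)
      p_le <- mean(us <= u + 1e-9)
      p_ge <- mean(us >= u - 1e-9)
    }
    p <- min(1, 2 * min(p_le, p_ge))
    return(test_result("Mann-Whitney U (exact)", u, p, exact = TRUE))
  }
  mu <- nx * ny / 2
  tie_tab <- table(c(x, y))
  n <- nx + ny
  sig2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 == 0)  # all values identical
    return(test_result("Mann-Whitney U (normal approx.)", u, 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  test_result("Mann-Whitney U (normal approx.)", u,
              min(1, 2 * stats::pnorm(-abs(z))))
}

#' @rdname mann_whitney
#' @export
wilcoxon_rank_sum <- mann_whitney

#' Pearson correlation
#'
#' @param x,y Numeric samples, equal length `n >= 3`, both non-constant.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal-length samples with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input")
  stats::cor(x, y)
}
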