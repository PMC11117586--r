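#' Kruskal-Wallis test with adjusted eta-squared
#'
#' Rank-based one-way comparison of two or more independent groups. The H
#' statistic and chi-square p value come from [stats::kruskal.test()]
#' (midranks, tie-corrected); the effect size is the adjusted eta-squared
#' `(H - k + 1) / (n - k)`, clipped at 0, with the conventional anchors
#' 0.01 / 0.06 / 0.14 for small / moderate / large group influence.
#' Fully tied data (every observation equal) yield H = 0, p = 1.
#'
#' @param groups A list of numeric vectors, one per group (each non-empty,
#'   at least 3 observations in total).
#' @return A list of class `kw_result`: `H`, `df`, `p_value`, `eta_sq`,
#'   `k`, `n`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups) {
  if (any(lengths(groups) == 0)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  n <- sum(lengths(groups))
  k <- length(groups)
  stopifnot(k >= 2, n >= 3)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    h <- 0
    p <- 1
  } else {
    kt <- kruskal.test(groups)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(H = h, df = k - 1, p_value = p,
                 eta_sq = max(0, (h - k + 1) / (n - k)), k = k, n = n),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g, eta^2 = %.3f (k = %d, n = %d)\n",
              x$H, x$df, x$p_value, x$eta_sq, x$k, x$n))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based pairwise follow-up to a Kruskal-Wallis test: for each pair of
#' groups the z statistic is the difference of mean pooled midranks divided
#' by its tie-corrected standard error
#' `sqrt((N(N+1)/12 - T/(12(N-1))) * (1/n_i + 1/n_j))`, with
#' `T = sum(t^3 - t)` over tie groups. Two-sided p values; Bonferroni
#' adjustment `min(1, m * p)` with `m = k(k-1)/2` pairs.
#'
#' @inheritParams kruskal_wallis
#' @param method Multiple-comparison adjustment; only `"bonferroni"`.
#' @param alpha Significance level for the `significant` flag, applied to
#'   the adjusted p values.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(groups, method = "bonferroni", alpha = 0.05) {
  method <- match.arg(method)
  k <- length(groups)
  stopifnot(k >= 2)
  if (any(lengths(groups) == 0)) {
    stop("every group needs at least one observation", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, g, mean)
  sizes <- lengths(groups)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_base <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  z <- numeric(m)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    se <- sqrt(var_base * (1 / sizes[i1] + 1 / sizes[i2]))
    z[j] <- if (se == 0) 0 else (rbar[i1] - rbar[i2]) / se
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  tibble::tibble(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
                 z = z, p_raw = p_raw,
                 p_adjusted = pmin(1, m * p_raw),
                 significant = pmin(1, m * p_raw) < alpha)
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Signed-rank test on the nonzero paired differences (zeros dropped, as in
#' the classical procedure): `W` is the sum of positive-difference midranks.
#' The p value uses the exact null distribution when there are at most 25
#' nonzero pairs and no tied absolute differences, and the tie-corrected
#' normal approximation otherwise (via [stats::wilcox.test()]). The effect
#' size is the matched-pairs rank-biserial correlation
#' `rho = (W+ - W-) / (W+ + W-)`, in \[-1, 1\].
#'
#' @param x,y Equal-length paired numeric samples.
#' @return A list of class `wilcoxon_result`: `W`, `p_value`,
#'   `effect_size_rho`, `n_pairs` (after zero removal), and `degenerate`
#'   (`TRUE` when every difference is zero, leaving the test undefined).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; test undefined")
    return(structure(list(W = NA_real_, p_value = NA_real_,
                          effect_size_rho = NA_real_, n_pairs = 0L,
                          degenerate = TRUE), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  use_exact <- n <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = use_exact,
                                     correct = !use_exact))
  structure(list(W = w_plus, p_value = wt$p.value,
                 effect_size_rho = (w_plus - w_minus) / (w_plus + w_minus),
                 n_pairs = n, degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Wilcoxon signed-rank: undefined (all differences zero)\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank: W = %.1f, p = %.4g, rho = %.2f (n = %d)\n",
                x$W, x$p_value, x$effect_size_rho, x$n_pairs))
  }
  invisible(x)
}

#' A-priori sample size for a one-way ANOVA
#'
#' Smallest total sample size N, balanced over k groups, at which the
#' fixed-effects one-way ANOVA F test with noncentrality `lambda = f^2 * N`
#' and degrees of freedom `(k - 1, N - k)` reaches the target power at level
#' alpha. N is searched over multiples of k (balanced allocation, the
#' G*Power convention for this design), so the returned power is the actual
#' achieved power, slightly above the target.
#'
#' @param k Number of groups.
#' @param effect_size_f ANOVA effect size f (Cohen's convention; 0.25 is
#'   the customary "medium" anchor).
#' @param alpha Type-I error level.
#' @param target_power Desired power in (0, 1).
#' @param max_n Search ceiling; exceeding it raises an error.
#' @return A list of class `power_result`: `N` (total), `n_per_group`,
#'   `achieved_power`, plus the inputs.
#' @examples
#' required_sample_size(k = 3, effect_size_f = 0.25)
#' @export
required_sample_size <- function(k, effect_size_f, alpha = 0.05,
                                 target_power = 0.80, max_n = 1e6) {
  stopifnot(k >= 2, effect_size_f > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  power_at <- function(n_total) {
    df2 <- n_total - k
    if (df2 < 1) return(0)
    1 - pf(qf(1 - alpha, k - 1, df2), k - 1, df2,
           ncp = effect_size_f^2 * n_total)
  }
  n_total <- k
  while (power_at(n_total) < target_power) {
    n_total <- n_total + k
    if (n_total > max_n) {
      stop("target power unreachable within max_n observations", call. = FALSE)
    }
  }
  structure(list(N = n_total, n_per_group = n_total / k,
                 achieved_power = power_at(n_total), k = k,
                 effect_size_f = effect_size_f, alpha = alpha,
                 target_power = target_power),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("A-priori power: N = %d (%d x %d), f = %.2f, alpha = %.2f -> power %.4f (target %.2f)\n",
              x$N, x$k, x$n_per_group, x$effect_size_f, x$alpha,
              x$achieved_power, x$target_power))
  invisible(x)
}
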