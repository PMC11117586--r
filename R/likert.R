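#' Numeric coding of the 5-point confidence scale
#'
#' The confidence ratings are collected as keypad categories 1..5
#' ("Yes, sure" .. "No, sure", standardized to Strongly agree .. Strongly
#' disagree) and mapped onto the symmetric numeric scale
#' SA = 1, A = 0.5, N = 0, D = -0.5, SD = -1, which keeps equal intervals
#' between adjacent options.
#'
#' @param confidence_raw Integer vector with values in 1..5.
#' @return Numeric vector on the \[-1, 1\] scale.
#' @examples
#' likert_to_numeric(1:5)
#' @export
likert_to_numeric <- function(confidence_raw) {
  if (!all(confidence_raw %in% 1:5)) {
    stop("confidence_raw must be in 1..5", call. = FALSE)
  }
  c(1, 0.5, 0, -0.5, -1)[confidence_raw]
}

LIKERT_LABELS <- c("SA", "A", "N", "D", "SD")

#' Likert response distribution
#'
#' Relative frequencies over the five ordered confidence categories together
#' with their numeric scale values. `p` is indexed by raw category 1..5
#' (Strongly agree first), so `p = c(1, 0, 0, 0, 0)` is unanimous full
#' confidence.
#'
#' @param p Relative frequencies (or counts, which are normalized) over the
#'   5 categories; non-negative, summing to a positive total.
#' @param x Numeric scale values paired with `p`; defaults to the SA..SD
#'   coding `c(1, 0.5, 0, -0.5, -1)`.
#' @return An object of class `likert_distribution` with fields `p`, `x`,
#'   and scale width `d_x = max(x) - min(x)`.
#' @seealso [likert_from_responses()] to build one from raw ratings.
#' @export
likert_distribution <- function(p, x = c(1, 0.5, 0, -0.5, -1)) {
  stopifnot(length(p) == length(x), length(unique(x)) == length(x))
  if (any(p < 0) || sum(p) <= 0) {
    stop("p must be non-negative with a positive total", call. = FALSE)
  }
  p <- p / sum(p)
  structure(list(p = p, x = x, d_x = max(x) - min(x)),
            class = "likert_distribution")
}

#' @describeIn likert_distribution Build the distribution from raw 1..5
#'   ratings.
#' @param confidence_raw Integer ratings in 1..5.
#' @export
likert_from_responses <- function(confidence_raw) {
  if (!all(confidence_raw %in% 1:5)) {
    stop("confidence_raw must be in 1..5", call. = FALSE)
  }
  likert_distribution(tabulate(confidence_raw, nbins = 5))
}

#' Mean of a Likert distribution
#'
#' The probability-weighted mean of the numeric scale values,
#' `mu = sum(p_i * X_i)`, in \[-1, 1\] for the default coding.
#'
#' @param dist A [likert_distribution()].
#' @return Scalar mean.
#' @export
likert_mean <- function(dist) {
  stopifnot(inherits(dist, "likert_distribution"))
  sum(dist$p * dist$x)
}

#' Semantic label of a Likert mean
#'
#' Maps a mean on the \[-1, 1\] scale back to the category whose interval
#' contains it: SA for (0.75, 1\], A for (0.25, 0.75\], N for
#' \[-0.25, 0.25\], D for \[-0.75, -0.25), SD for \[-1, -0.75).
#'
#' @param mu_x Numeric vector of means in \[-1, 1\].
#' @return Character vector of labels among SA, A, N, D, SD.
#' @export
semantic_label <- function(mu_x) {
  if (any(!is.finite(mu_x)) || any(mu_x > 1) || any(mu_x < -1)) {
    stop("mu_x must be in [-1, 1]", call. = FALSE)
  }
  dplyr::case_when(
    mu_x > 0.75 ~ "SA",
    mu_x > 0.25 ~ "A",
    mu_x >= -0.25 ~ "N",
    mu_x >= -0.75 ~ "D",
    .default = "SD")
}

#' Shannon entropy of a Likert distribution
#'
#' `Ent = -sum(p_i * log2(p_i))` in bits, with `0 * log(0) = 0`. Zero for a
#' degenerate distribution, `log2(5)` for the uniform one; higher entropy
#' means a more uncertain, spread-out response pattern.
#'
#' @inheritParams likert_mean
#' @return Entropy in bits.
#' @export
likert_entropy <- function(dist) {
  stopifnot(inherits(dist, "likert_distribution"))
  p <- dist$p[dist$p > 0]
  -sum(p * log2(p))
}

#' Ordinal consensus of a Likert distribution
#'
#' The Tastle-Wierman agreement measure
#' `Cns = 1 + sum(p_i * log2(1 - |X_i - mu| / d_x))`, where `mu` is the
#' distribution mean and `d_x` the scale width. It equals 1 under complete
#' agreement (all mass on one category) and 0 under maximal dissensus (mass
#' split between the two scale extremes); unlike the standard deviation it
#' accounts for the ordinal spread of the responses.
#'
#' @inheritParams likert_mean
#' @return Consensus in \[0, 1\].
#' @export
likert_consensus <- function(dist) {
  stopifnot(inherits(dist, "likert_distribution"))
  mu <- likert_mean(dist)
  keep <- dist$p > 0
  1 + sum(dist$p[keep] * log2(1 - abs(dist$x[keep] - mu) / dist$d_x))
}
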