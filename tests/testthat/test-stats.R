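test_that("Kruskal-Wallis H, p and adjusted eta-squared on a worked example", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(kw$eta_sq, (7.2 - 2) / 6, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "observation")
})

test_that("fully tied groups give H = 0 and rank invariance holds", {
  kw0 <- kruskal_wallis(list(rep(5, 4), rep(5, 4), rep(5, 4)))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_value, 1)
  set.seed(21)
  g <- list(rnorm(12), rnorm(10) + 1, rnorm(15))
  a <- kruskal_wallis(g)
  b <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))  # monotone transform
  expect_equal(a$H, b$H, tolerance = 1e-12)
})

test_that("Dunn post hoc: ties, identical groups and Bonferroni arithmetic", {
  dn0 <- dunn_posthoc(list(a = rep(1, 5), b = rep(1, 5)))
  expect_equal(dn0$z, 0)
  expect_equal(dn0$p_raw, 1)
  set.seed(31)
  g <- list(NVR = rnorm(20), PFFV = rnorm(20), FV = rnorm(20) + 1)
  dn <- dunn_posthoc(g)
  expect_equal(nrow(dn), 3)
  expect_equal(dn$p_adjusted, pmin(1, 3 * dn$p_raw))
  expect_true(all(dn$p_adjusted >= dn$p_raw))
})

test_that("Dunn flags a planted two-SD location shift", {
  set.seed(77)
  hits <- 0
  for (i in 1:60) {
    g <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, mean = 2))
    dn <- dunn_posthoc(g)
    shifted <- dn$significant[(dn$group1 == "a" & dn$group2 == "c") |
                                (dn$group1 == "c" & dn$group2 == "a")]
    hits <- hits + as.integer(shifted)
  }
  expect_gte(hits / 60, 0.95)
})

test_that("paired Wilcoxon matches full sign-flip enumeration", {
  d <- c(1, 2, 3, 4, 5, -6)
  got <- wilcoxon_paired(d, rep(0, 6))
  want <- oracle_signed_rank(d)
  expect_equal(got$W, want$W)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, sd = 3), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    got <- wilcoxon_paired(d, rep(0, length(d)))
    want <- oracle_signed_rank(d)
    expect_equal(got$W, want$W)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("Wilcoxon effect size and degenerate input handling", {
  r <- wilcoxon_paired(c(2, 3, 4, 6, 9), c(1, 2, 3, 4, 5))
  expect_equal(r$effect_size_rho, 1)  # all differences positive
  r2 <- wilcoxon_paired(c(1, 2, 3, 4, 5), c(2, 3, 4, 6, 9))
  expect_equal(r2$effect_size_rho, -1)
  expect_warning(res <- wilcoxon_paired(1:4, 1:4), "zero")
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
  expect_error(wilcoxon_paired(1:3, 1:4), "equal length")
  # zeros dropped before ranking
  r3 <- wilcoxon_paired(c(5, 5, 7, 9), c(5, 5, 6, 7))
  expect_equal(r3$n_pairs, 2L)
})

test_that("a-priori noncentral-F sample size hits the three-group anchor", {
  res <- required_sample_size(k = 3, effect_size_f = 0.25, alpha = 0.05,
                              target_power = 0.80)
  expect_equal(res$N, 159)
  expect_equal(res$n_per_group, 53)
  expect_gte(res$achieved_power, 0.80)
  # one step of k fewer must fall short of the target
  pw <- function(N, k = 3, f = 0.25, a = 0.05)
    1 - pf(qf(1 - a, k - 1, N - k), k - 1, N - k, ncp = f^2 * N)
  expect_lt(pw(res$N - 3), 0.80)
})

test_that("sample size agrees with the noncentral-t route for two groups", {
  res <- required_sample_size(k = 2, effect_size_f = 0.25, alpha = 0.05,
                              target_power = 0.80)
  # two-sample t with d = 2f: power via noncentral t, balanced n = N/2
  power_t <- function(N, d = 0.5, a = 0.05) {
    n <- N / 2
    ncp <- d * sqrt(n / 2)
    q <- stats::qt(1 - a / 2, df = N - 2)
    1 - stats::pt(q, df = N - 2, ncp = ncp) +
      stats::pt(-q, df = N - 2, ncp = ncp)
  }
  cands <- seq(4, 400, by = 2)
  n_t <- cands[which(vapply(cands, power_t, numeric(1)) >= 0.80)[1]]
  expect_equal(res$N, n_t)
})

test_that("required sample size is monotone in effect size, alpha and power", {
  n_of <- function(f = 0.25, a = 0.05, pw = 0.8)
    required_sample_size(3, f, a, pw)$N
  expect_true(all(diff(vapply(c(0.1, 0.25, 0.4), function(f) n_of(f = f),
                              numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.1), function(a) n_of(a = a),
                              numeric(1))) <= 0))
  expect_true(all(diff(vapply(c(0.5, 0.8, 0.95), function(p) n_of(pw = p),
                              numeric(1))) >= 0))
  expect_gte(n_of(pw = 1e-6), 3)  # floor at k
  expect_error(required_sample_size(3, 1e-6, max_n = 3000), "unreachable")
})
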