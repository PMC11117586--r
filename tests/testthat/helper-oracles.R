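# Independent oracles and stream builders used across the suite.

# Brute-force greedy dispersion clustering, written independently of the
# package's compiled detector: plain R loop, recomputing the centroid from
# scratch at every step.
oracle_fixations <- function(samples, tolerance_px = 40, min_duration_ms = 80,
                             max_gap_ms = 100) {
  valid <- if ("validity" %in% names(samples)) as.logical(samples$validity)
           else rep(TRUE, nrow(samples))
  valid[is.na(valid)] <- FALSE
  valid <- valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  s <- samples[valid, ]
  out <- list()
  cluster <- integer(0)
  flush <- function(cluster) {
    if (length(cluster) < 1) return(NULL)
    dur <- s$t_ms[cluster[length(cluster)]] - s$t_ms[cluster[1]]
    if (dur < min_duration_ms) return(NULL)
    data.frame(onset_ms = s$t_ms[cluster[1]],
               offset_ms = s$t_ms[cluster[length(cluster)]],
               duration_ms = dur,
               centroid_x_px = mean(s$x_px[cluster]),
               centroid_y_px = mean(s$y_px[cluster]),
               n_samples = length(cluster))
  }
  for (i in seq_len(nrow(s))) {
    if (length(cluster) > 0) {
      cx <- mean(s$x_px[cluster])
      cy <- mean(s$y_px[cluster])
      gap <- s$t_ms[i] - s$t_ms[cluster[length(cluster)]]
      d <- sqrt((s$x_px[i] - cx)^2 + (s$y_px[i] - cy)^2)
      if (gap > max_gap_ms || d > tolerance_px) {
        out[[length(out) + 1]] <- flush(cluster)
        cluster <- integer(0)
      }
    }
    cluster <- c(cluster, i)
  }
  out[[length(out) + 1]] <- flush(cluster)
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), n_samples = integer(0))
  }
  res
}

# Random gaze stream: a wandering walk with occasional large jumps, variable
# sampling gaps and dropped/invalid samples - adversarial for the detector.
random_stream <- function(n) {
  t <- cumsum(sample(c(8, 16.7, 16.7, 16.7, 40, 130), n, replace = TRUE))
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- runif(1, 200, 1700)
  y[1] <- runif(1, 200, 900)
  for (i in 2:n) {
    if (runif(1) < 0.08) {  # saccade-like jump
      x[i] <- x[i - 1] + sample(c(-1, 1), 1) * runif(1, 60, 400)
      y[i] <- y[i - 1] + sample(c(-1, 1), 1) * runif(1, 60, 400)
    } else {
      x[i] <- x[i - 1] + rnorm(1, 0, 12)
      y[i] <- y[i - 1] + rnorm(1, 0, 12)
    }
  }
  tibble::tibble(t_ms = t, x_px = x, y_px = y,
                 validity = runif(n) > 0.05)
}

# Plant a known fixation sequence: centers at least `sep` apart, one sample
# every 1000/rate ms, Gaussian jitter, saccade gaps without samples.
plant_stream <- function(centers, durations_ms, gap_ms = 50, jitter_sd = 3,
                         rate_hz = 60) {
  dt <- 1000 / rate_hz
  t0 <- 0
  rows <- list()
  for (i in seq_len(nrow(centers))) {
    times <- seq(0, durations_ms[i], by = dt)
    rows[[i]] <- tibble::tibble(
      t_ms = t0 + times,
      x_px = centers[i, 1] + rnorm(length(times), 0, jitter_sd),
      y_px = centers[i, 2] + rnorm(length(times), 0, jitter_sd),
      validity = TRUE)
    t0 <- t0 + durations_ms[i] + dt + gap_ms
  }
  dplyr::bind_rows(rows)
}

# random well-separated centers for planted streams
spaced_centers <- function(n, sep = 120) {
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    repeat {
      p <- c(runif(1, 300, 1600), runif(1, 200, 900))
      if (i == 1 || sqrt(sum((p - out[i - 1, ])^2)) >= sep) break
    }
    out[i, ] <- p
  }
  out
}

# Exact paired Wilcoxon by full sign-flip enumeration (two-sided), for
# nonzero differences with untied absolute values.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(W = w_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}
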