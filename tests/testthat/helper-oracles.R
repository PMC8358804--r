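## Independent oracles used across the suite. Deliberately written as
## plain brute force, sharing no code path with the package internals.

## Exhaustive per-sample scan for the mean +/- k*SD response criterion.
oracle_detect <- function(w, b, window = c(1.4, 5), k = 2, min_run = 5) {
  idx <- which(w$time >= window[1] & w$time <= window[2])
  exc <- abs(w$voltage[idx] - b$mean) > k * b$sd
  n <- length(exc)
  if (min_run > n) return(FALSE)
  for (i in seq_len(n - min_run + 1)) {
    if (all(exc[i:(i + min_run - 1)])) return(TRUE)
  }
  FALSE
}

## Textbook tie-corrected Friedman chi-square from first principles.
oracle_friedman <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  stat_num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  tie_term <- sum(unlist(apply(m, 1, function(row) {
    tt <- table(row)
    tt^3 - tt
  })))
  stat_den <- n * k * (k + 1) - tie_term / (k - 1)
  stat_num / stat_den
}

## Exact two-sided Mann-Whitney p by counting pairwise wins (no ranks):
## U = #{(i, j): a_i > b_j} + 0.5 #{a_i == b_j}, enumerated over every
## assignment of the pooled values to the two groups.
oracle_mw_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, function(ii)
    u_of(pooled[ii], pooled[-ii]))
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

## Count 8-connected components by queue-based flood fill.
oracle_component_count <- function(mask) {
  d <- dim(mask)
  seen <- matrix(FALSE, d[1], d[2])
  count <- 0
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j] || seen[i, j]) next
    count <- count + 1
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= d[1] && c >= 1 && c <= d[2] &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

## Monte-Carlo studentized-range upper tail: P(q(k, df) > q_obs).
oracle_ptukey_mc <- function(q_obs, k, df, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  rng <- apply(z, 1, max) - apply(z, 1, min)
  s <- sqrt(stats::rchisq(n_draws, df) / df)
  mean(rng / s > q_obs)
}

## Paint a filled disk (pixel centers inside) onto a matrix; returns the
## matrix and the painted pixel count.
paint_disk <- function(img, x0, y0, r, value, pitch) {
  d <- dim(img)
  n <- 0
  for (row in seq_len(d[1])) {
    y <- (row - 0.5) * pitch
    if (abs(y - y0) > r) next
    for (col in seq_len(d[2])) {
      x <- (col - 0.5) * pitch
      if ((x - x0)^2 + (y - y0)^2 <= r^2) {
        img[row, col] <- value
        n <- n + 1
      }
    }
  }
  list(img = img, n = n)
}

## Quick constructed waveform on a uniform grid.
make_waveform <- function(voltage, rate = 24.4, level = 50) {
  waveform((seq_along(voltage) - 1) / rate, voltage, level)
}
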