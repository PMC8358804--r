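mk_long <- function(m) {
  data.frame(animal = rep(rownames(m) %||% seq_len(nrow(m)), ncol(m)),
             timepoint_day = rep(colnames(m) %||% seq_len(ncol(m)),
                                 each = nrow(m)),
             value = as.vector(m))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Friedman handles degenerate, perfect and random tables", {
  ## all subjects constant: statistic 0, p 1
  m0 <- matrix(5, 4, 3)
  r0 <- friedman_with_posthoc(mk_long(m0), value = "value")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  ## perfectly consistent ranks over k = 3 conditions: statistic = 2n
  for (n in c(4, 7, 10)) {
    m <- t(replicate(n, c(1, 2, 3))) + rnorm(n) * 0  # identical ranks
    m <- m + matrix(rnorm(n, sd = 0.001), n, 3)      # distinct subjects
    r <- friedman_with_posthoc(mk_long(m), value = "value")
    expect_equal(r$statistic, 2 * n, tolerance = 1e-10)
  }

  ## random tables match the first-principles tie-corrected oracle
  set.seed(101)
  for (i in 1:40) {
    n <- sample(3:8, 1); k <- sample(3:6, 1)
    m <- matrix(sample(1:4, n * k, replace = TRUE) + rnorm(n * k, sd = 0.1 * (i %% 2)),
                n, k)
    r <- friedman_with_posthoc(mk_long(m), value = "value")
    expect_equal(r$statistic, oracle_friedman(m), tolerance = 1e-10)
  }

  ## incomplete blocks are refused with the missing cell named
  d <- mk_long(matrix(1:12, 4, 3))
  expect_error(friedman_with_posthoc(d[-1, ], value = "value"),
               "missing cells")
})

test_that("Friedman and its post hoc are invariant to monotone transforms", {
  set.seed(31)
  m <- matrix(rnorm(8 * 4), 8, 4)
  a <- friedman_with_posthoc(mk_long(m), value = "value")
  b <- friedman_with_posthoc(mk_long(exp(m)), value = "value")
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$posthoc$p_adj, b$posthoc$p_adj)
})

test_that("Dunn post hoc reduces to the classic SE without ties", {
  set.seed(32)
  n <- 7; k <- 4
  m <- matrix(rnorm(n * k), n, k)
  r <- friedman_with_posthoc(mk_long(m), value = "value")
  rks <- t(apply(m, 1, rank))
  se <- sqrt(k * (k + 1) / (6 * n))
  z_manual <- abs(mean(rks[, 1]) - mean(rks[, 2])) / se
  expect_equal(r$posthoc$z[1], z_manual, tolerance = 1e-12)
})

test_that("Mann-Whitney exact p equals full-enumeration oracle", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  ## identical samples: U = n_a n_b / 2, p = 1
  r2 <- mann_whitney(c(2, 2, 5), c(2, 2, 5))
  ## (tied path) p must be 1-region and U at its null mean
  expect_equal(r2$statistic, 4.5)
  expect_gt(r2$p_value, 0.99)
  r3 <- mann_whitney(rep(3, 4), rep(3, 5))
  expect_equal(r3$statistic, 10)
  expect_equal(r3$p_value, 1)

  set.seed(71)
  for (i in 1:30) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    a <- sample(1:6, m, replace = TRUE)   # ties likely
    b <- sample(1:6, n, replace = TRUE)
    r <- mann_whitney(a, b)
    o <- oracle_mw_exact(a, b)
    expect_equal(r$statistic, o$u)
    expect_equal(r$p_value, o$p, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(72)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(exp(a), exp(b))$p_value)
})

test_that("one-way ANOVA: F equals t-squared for two groups", {
  set.seed(81)
  for (i in 1:10) {
    x <- rnorm(sample(4:9, 1)); y <- rnorm(sample(4:9, 1), mean = 0.5)
    r <- anova_oneway_posthoc(c(x, y), rep(c("a", "b"), c(length(x),
                                                          length(y))))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
  }
  ## all identical: F 0, p 1
  r0 <- anova_oneway_posthoc(rep(2, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  ## zero within-group variance with distinct means is flagged
  rInf <- anova_oneway_posthoc(rep(c(1, 2), each = 3),
                               rep(c("a", "b"), each = 3))
  expect_true(is.infinite(rInf$statistic))
  expect_match(rInf$notes, "zero within-group")
})

test_that("ANOVA F is invariant under affine transforms", {
  set.seed(82)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  a <- anova_oneway_posthoc(v, g)
  b <- anova_oneway_posthoc(3 * v - 7, g)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  f <- rep(c("lo", "hi"), 15)
  a2 <- anova_twoway(v, g, f)
  b2 <- anova_twoway(-2 * v + 1, g, f)
  expect_equal(a2$posthoc$F, b2$posthoc$F, tolerance = 1e-10)
})

test_that("Games-Howell p-values agree with ptukey and are familywise", {
  set.seed(83)
  v <- c(rnorm(8, 0, 1), rnorm(12, 1, 3), rnorm(6, 0.5, 0.5))
  g <- rep(c("a", "b", "c"), c(8, 12, 6))
  r <- anova_oneway_posthoc(v, g, posthoc = "games_howell")
  gh <- r$posthoc
  expect_equal(nrow(gh), 3)
  expect_true(all(gh$p_adj >= 0 & gh$p_adj <= 1))
  ## recompute one pair by hand
  x <- v[g == "a"]; y <- v[g == "b"]
  se2 <- var(x) / 8 + var(y) / 12
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / 8)^2 / 7 + (var(y) / 12)^2 / 11)
  expect_equal(gh$t[gh$a == "a" & gh$b == "b"], tt, tolerance = 1e-12)
  expect_equal(gh$p_adj[gh$a == "a" & gh$b == "b"],
               ptukey(abs(tt) * sqrt(2), 3, df, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("two-way ANOVA matches hand-computed balanced sums of squares", {
  ## balanced 2x2 with 2 replicates, worked by hand
  v <- c(1, 2, 4, 5, 2, 3, 9, 10)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(rep(c("b1", "b2"), each = 2), 2)
  r <- anova_twoway(v, A, B, "A", "B")
  n <- 8; gm <- mean(v)
  ssA <- 4 * sum((tapply(v, A, mean) - gm)^2)
  ssB <- 4 * sum((tapply(v, B, mean) - gm)^2)
  cellm <- tapply(v, interaction(A, B), mean)
  ssCells <- 2 * sum((cellm - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((v - rep(cellm[interaction(A, B)], 1))^2)
  eff <- r$posthoc
  expect_equal(eff$F[eff$term == "A"], (ssA / 1) / (ssE / 4),
               tolerance = 1e-10)
  expect_equal(eff$F[eff$term == "B"], (ssB / 1) / (ssE / 4),
               tolerance = 1e-10)
  expect_equal(eff$F[eff$term == "A:B"], (ssAB / 1) / (ssE / 4),
               tolerance = 1e-10)

  ## frequency-only effect: group stays non-significant
  set.seed(84)
  f2 <- rep(c(1, 2, 3), each = 40)
  g2 <- rep(rep(c("x", "y"), each = 20), 3)
  v2 <- 2 * f2 + rnorm(120)
  r2 <- anova_twoway(v2, g2, f2)
  expect_gt(r2$p_value, 0.01)
  expect_lt(r2$posthoc$p[2], 1e-10)

  ## empty cells are refused by name
  expect_error(anova_twoway(v[-(1:2)], A[-(1:2)], B[-(1:2)]),
               "empty design cells")
})

test_that("correlation table mirrors the report layout", {
  d <- data.frame(group = "g1", area_um2 = 1:10,
                  norm_od = seq(10, 1))
  ct <- correlation_table(d)
  expect_equal(ct$spearman, -1)
  expect_equal(ct$n, 10)

  ## independent pairs: small coefficient at n = 1000
  set.seed(85)
  d2 <- data.frame(group = "g2", area_um2 = rnorm(1000),
                   norm_od = rnorm(1000))
  ct2 <- correlation_table(d2)
  expect_lt(abs(ct2$pearson), 0.1)

  ## imposed rho recovered
  set.seed(86)
  z1 <- rnorm(180); z2 <- rnorm(180)
  rho <- -0.58
  d3 <- data.frame(group = "g3", area_um2 = z1,
                   norm_od = rho * z1 + sqrt(1 - rho^2) * z2)
  ct3 <- correlation_table(d3)
  expect_lt(abs(ct3$pearson - rho), 0.1)

  ## zero variance flagged undefined
  d4 <- data.frame(group = "g4", area_um2 = rep(1, 5),
                   norm_od = rnorm(5))
  ct4 <- correlation_table(d4)
  expect_false(ct4$defined)
  expect_true(is.na(ct4$pearson))

  expect_error(correlation_table(d[1:2, ]), ">= 3 pairs")
})

test_that("Bonferroni-adjusted p-values never fall below raw ones", {
  set.seed(87)
  m <- matrix(rnorm(6 * 4), 6, 4) + rep(c(0, 1, 0, 2), each = 6)
  r <- friedman_with_posthoc(mk_long(m), value = "value")
  expect_true(all(r$posthoc$p_adj >= r$posthoc$p_raw))
  expect_true(all(r$posthoc$p_adj <= 1))
})
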