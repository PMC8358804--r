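#' Statistical test result container
#'
#' Uniform return shape for the battery: test name, statistic, degrees of
#' freedom (or sample sizes), p-value, and an optional post hoc table of
#' pairwise adjusted p-values. Significance is always read at alpha = 0.05.
#'
#' @param test test name.
#' @param statistic statistic value.
#' @param df named numeric of degrees of freedom / sample sizes.
#' @param p_value p-value in `[0, 1]` (or NA when undefined).
#' @param posthoc optional data.frame of pairwise comparisons.
#' @param notes optional character notes (degeneracies etc.).
#' @return object of class `stat_result`.
#' @keywords internal
stat_result <- function(test, statistic, df, p_value, posthoc = NULL,
                        notes = character()) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc, alpha = 0.05,
                 notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (length(x$df))
    cat("  df:", paste(names(x$df), unlist(x$df), sep = "=",
                       collapse = ", "), "\n")
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  if (length(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

long_to_blocks <- function(table, value, subject, within) {
  need <- c(value, subject, within)
  if (!all(need %in% names(table)))
    stop_eq("table must have columns ", paste(need, collapse = ", "))
  subj <- factor(table[[subject]])
  cond <- factor(table[[within]])
  full <- expand.grid(s = levels(subj), c = levels(cond))
  have <- paste(subj, cond)
  miss <- full[!paste(full$s, full$c) %in% have, ]
  if (nrow(miss) > 0)
    stop_eq("incomplete blocks; missing cells: ",
            paste(paste0(miss$s, ":", miss$c), collapse = ", "))
  if (anyDuplicated(have)) stop_eq("duplicate (subject, condition) cells")
  m <- matrix(NA_real_, nlevels(subj), nlevels(cond),
              dimnames = list(levels(subj), levels(cond)))
  m[cbind(as.integer(subj), as.integer(cond))] <- table[[value]]
  m
}

#' Friedman test with Dunn-Bonferroni post hoc
#'
#' Repeated-measures comparison of a metric across conditions
#' (timepoints) within subjects (animals): the tie-corrected Friedman
#' chi-square, followed by the Dunn-type post hoc on within-subject mean
#' ranks (pairwise z on rank-mean differences, Bonferroni-adjusted over
#' all pairs) — the procedure statistical packages run under "Friedman +
#' Bonferroni". The Dunn standard error carries the same tie correction
#' as the Friedman statistic: grid-snapped threshold data are heavily
#' tied, and the no-tie SE sqrt(k(k+1)/(6n)) overstates the null
#' variance of a mean-rank difference in that case (it is recovered
#' exactly when there are no ties). Pairwise exact Wilcoxon
#' signed-rank tests are available as an alternative post hoc, but note
#' that with small n their Bonferroni-adjusted p-values have a hard floor
#' (e.g. n = 6, 15 pairs: min 15 * 2/64 = 0.47).
#'
#' When every subject is constant across conditions the test is degenerate
#' and reported as statistic 0, p = 1.
#'
#' @param table long data.frame.
#' @param value,subject,within column names: the metric, the subject id,
#'   and the repeated condition.
#' @param posthoc `"dunn"` (default) or `"wilcoxon"`.
#' @return a [stat_result] with post hoc columns `a`, `b`, `z` (or `V`),
#'   `p_raw`, `p_adj`.
#' @export
friedman_with_posthoc <- function(table, value = "value",
                                  subject = "animal",
                                  within = "timepoint_day",
                                  posthoc = c("dunn", "wilcoxon")) {
  posthoc <- match.arg(posthoc)
  m <- long_to_blocks(table, value, subject, within)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_eq("need >= 2 subjects and >= 2 conditions")
  cmb <- utils::combn(colnames(m), 2)
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    ph <- data.frame(a = cmb[1, ], b = cmb[2, ], z = 0, p_raw = 1,
                     p_adj = 1)
    return(stat_result("Friedman", 0, c(df = k - 1), 1, ph,
                       "degenerate: all subjects constant across conditions"))
  }
  ft <- stats::friedman.test(m)
  r <- t(apply(m, 1, rank))
  ph <- if (posthoc == "dunn") {
    ## variance of a within-block rank with ties:
    ## v_b = ((k^2 - 1) - sum_t (t^3 - t)/k) / 12, and
    ## Var(rbar_i - rbar_j) = (2k / (n (k-1))) * mean_b v_b
    ## (reduces to k(k+1)/(6n) without ties)
    vb <- apply(r, 1, function(rr) {
      tt <- table(rr)
      ((k^2 - 1) - sum(tt^3 - tt) / k) / 12
    })
    se <- sqrt(2 * k * mean(vb) / (n * (k - 1)))
    rbar <- colMeans(r)
    dif <- abs(rbar[cmb[1, ]] - rbar[cmb[2, ]])
    z <- if (se > 0) dif / se else ifelse(dif == 0, 0, Inf)
    p <- 2 * stats::pnorm(-z)
    data.frame(a = cmb[1, ], b = cmb[2, ], z = unname(z),
               p_raw = unname(p),
               p_adj = pmin(1, unname(p) * ncol(cmb)))
  } else {
    res <- apply(cmb, 2, function(pair) {
      w <- suppressWarnings(stats::wilcox.test(m[, pair[1]], m[, pair[2]],
                                               paired = TRUE))
      c(w$statistic, w$p.value)
    })
    data.frame(a = cmb[1, ], b = cmb[2, ], V = res[1, ],
               p_raw = res[2, ], p_adj = pmin(1, res[2, ] * ncol(cmb)))
  }
  rownames(ph) <- NULL
  stat_result("Friedman", unname(ft$statistic),
              c(df = unname(ft$parameter), n = n), ft$p.value, ph)
}

## Exact Mann-Whitney by full enumeration over group assignments; handles
## ties through midranks. Used when the sample is small and tied (the
## no-tie case goes through the exact network algorithm in wilcox.test).
mw_exact_enum <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  u_all <- colSums(matrix(rk[combs], nrow = m)) - m * (m + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided comparison of two independent samples. For combined sizes up
#' to `exact_max` (default 12, covering the study's group sizes) the exact
#' permutation p-value is used — through the standard exact algorithm when
#' there are no ties, and by full enumeration of all group assignments
#' (midranks) when there are. Larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max maximal combined size for the exact path in auto mode.
#' @return a [stat_result] with the U statistic of sample `a`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal"),
                         exact_max = 12) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0)
    stop_eq("both samples must be non-empty")
  m <- length(a); n <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1) {
    return(stat_result("Mann-Whitney U", m * n / 2, c(n_a = m, n_b = n),
                       1, notes = "all values tied across both samples"))
  }
  exact <- switch(mode, exact = TRUE, normal = FALSE,
                  auto = (m + n) <= exact_max)
  if (exact) {
    if (ties) {
      e <- mw_exact_enum(a, b)
      return(stat_result("Mann-Whitney U (exact, ties)", e$u,
                         c(n_a = m, n_b = n), e$p))
    }
    w <- stats::wilcox.test(a, b, exact = TRUE)
    return(stat_result("Mann-Whitney U (exact)", unname(w$statistic),
                       c(n_a = m, n_b = n), w$p.value))
  }
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                           correct = TRUE))
  stat_result("Mann-Whitney U (normal approx.)", unname(w$statistic),
              c(n_a = m, n_b = n), w$p.value)
}

## Games-Howell pairwise comparisons: Welch-type t on unpooled variances,
## Welch-Satterthwaite df, referred to the studentized-range distribution
## (q = t * sqrt(2)), familywise by construction.
games_howell <- function(values, group) {
  g <- split(values, group)
  k <- length(g)
  nm <- names(g)
  ni <- vapply(g, length, numeric(1))
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, stats::var, numeric(1))
  cmb <- utils::combn(k, 2)
  out <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- unname(vi[i] / ni[i] + vi[j] / ni[j])
    t <- unname(mi[i] - mi[j]) / sqrt(se2)
    df <- se2^2 / unname((vi[i] / ni[i])^2 / (ni[i] - 1) +
                           (vi[j] / ni[j])^2 / (ni[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(t = t, df = df, p = p)
  })
  data.frame(a = nm[cmb[1, ]], b = nm[cmb[2, ]], t = out["t", ],
             df = out["df", ], p_adj = out["p", ])
}

#' One-way ANOVA with Bonferroni and Games-Howell post hocs
#'
#' Standard fixed-effects one-way ANOVA (F from the usual sums of
#' squares), followed by pairwise comparisons: pooled-SD t tests with
#' Bonferroni adjustment, and/or Games-Howell comparisons for unequal
#' variances (Welch df, studentized-range reference distribution).
#'
#' @param values numeric response.
#' @param group grouping factor (>= 2 groups, each >= 2 values).
#' @param posthoc `"bonferroni"`, `"games_howell"` or `"both"` (default).
#' @return a [stat_result]; `posthoc` has columns `a`, `b`, `method`,
#'   `p_adj` (plus `t`, `df` for Games-Howell).
#' @export
anova_oneway_posthoc <- function(values, group,
                                 posthoc = c("both", "bonferroni",
                                             "games_howell")) {
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  if (nlevels(group) < 2) stop_eq("need >= 2 groups")
  if (any(table(group) < 2)) stop_eq("every group needs >= 2 values")
  within_var <- tapply(values, group, stats::var)
  means <- tapply(values, group, mean)
  if (length(unique(values)) == 1) {
    return(stat_result("one-way ANOVA", 0,
                       c(df1 = nlevels(group) - 1,
                         df2 = length(values) - nlevels(group)), 1,
                       notes = "degenerate: all values identical"))
  }
  if (all(within_var == 0) && length(unique(means)) > 1) {
    return(stat_result("one-way ANOVA", Inf,
                       c(df1 = nlevels(group) - 1,
                         df2 = length(values) - nlevels(group)), 0,
                       notes = "zero within-group variance with unequal means"))
  }
  fit <- stats::lm(values ~ group)
  an <- stats::anova(fit)
  ph <- NULL
  if (posthoc %in% c("both", "bonferroni")) {
    pt <- stats::pairwise.t.test(values, group,
                                 p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    idx <- which(!is.na(pt$p.value), arr.ind = TRUE)
    ph <- data.frame(a = rownames(pt$p.value)[idx[, 1]],
                     b = colnames(pt$p.value)[idx[, 2]],
                     method = "bonferroni", t = NA_real_, df = NA_real_,
                     p_adj = pt$p.value[idx])
  }
  if (posthoc %in% c("both", "games_howell")) {
    gh <- games_howell(values, group)
    gh <- data.frame(a = gh$a, b = gh$b, method = "games_howell",
                     t = gh$t, df = gh$df, p_adj = gh$p_adj)
    ph <- rbind(ph, gh)
  }
  rownames(ph) <- NULL
  stat_result("one-way ANOVA", an$`F value`[1],
              c(df1 = an$Df[1], df2 = an$Df[2]), an$`Pr(>F)`[1], ph)
}

#' Two-way ANOVA (group x frequency)
#'
#' Fixed-effects two-way ANOVA with interaction. Balanced designs reduce
#' to the classical sums of squares; unbalanced data use Type II sums of
#' squares (no interaction emphasis). Empty design cells are an error and
#' are listed.
#'
#' @param values numeric response.
#' @param f1,f2 the two factors (e.g. group and frequency region).
#' @param names_f1,names_f2 labels used in the output table.
#' @return a [stat_result]; `posthoc` slot carries the full effect table
#'   (`term`, `df`, `F`, `p`).
#' @export
anova_twoway <- function(values, f1, f2, names_f1 = "group",
                         names_f2 = "frequency") {
  f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) < 2 || nlevels(f2) < 2)
    stop_eq("both factors need >= 2 levels")
  tab <- table(f1, f2)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop_eq("empty design cells: ",
            paste(paste0(rownames(tab)[empty[, 1]], ":",
                         colnames(tab)[empty[, 2]]), collapse = ", "))
  }
  fit <- stats::lm(values ~ f1 * f2)
  an <- car::Anova(fit, type = 2)
  terms <- c(names_f1, names_f2, paste0(names_f1, ":", names_f2))
  eff <- data.frame(term = terms, df = an$Df[1:3],
                    F = an$`F value`[1:3], p = an$`Pr(>F)`[1:3])
  stat_result("two-way ANOVA (Type II)", eff$F[1],
              c(df_resid = an$Df[4]), eff$p[1], posthoc = eff)
}

#' Size-OD correlation table by group
#'
#' For each group: n, mean/SD of normalized OD and of button area, and
#' both the Pearson and Spearman correlation coefficients with their
#' p-values — mirroring the classic correlation-table layout of
#' quantitative-immunocytochemistry reports. Zero variance in either
#' variable flags the coefficient as undefined.
#'
#' @param buttons data.frame with per-button measurements.
#' @param area,od,group column names.
#' @return data.frame of class `correlation_table`, one row per group:
#'   `group`, `n`, `od_mean`, `od_sd`, `area_mean`, `area_sd`,
#'   `pearson`, `pearson_p`, `spearman`, `spearman_p`, `defined`.
#' @export
correlation_table <- function(buttons, area = "area_um2",
                              od = "norm_od", group = "group") {
  need <- c(area, od, group)
  if (!all(need %in% names(buttons)))
    stop_eq("`buttons` must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(buttons, buttons[[group]]), function(d) {
    x <- d[[area]]; y <- d[[od]]
    if (length(x) < 3) stop_eq("need >= 3 pairs per group")
    row <- data.frame(group = d[[group]][1], n = length(x),
                      od_mean = mean(y), od_sd = stats::sd(y),
                      area_mean = mean(x), area_sd = stats::sd(x),
                      pearson = NA_real_, pearson_p = NA_real_,
                      spearman = NA_real_, spearman_p = NA_real_,
                      defined = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      row$defined <- FALSE
      return(row)
    }
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    row$pearson <- unname(pe$estimate); row$pearson_p <- pe$p.value
    row$spearman <- unname(sp$estimate); row$spearman_p <- sp$p.value
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("correlation_table", "data.frame")
  res
}
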