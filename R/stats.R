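#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix: the pseudo-F statistic
#' \deqn{F = \frac{SS_A / (k-1)}{SS_W / (n-k)}}
#' with total and within-group sums of squares computed from squared
#' distances (\eqn{SS_T = \sum_{i<j} d_{ij}^2 / n}, \eqn{SS_W = \sum_g
#' \sum_{i<j \in g} d_{ij}^2 / n_g}, \eqn{SS_A = SS_T - SS_W}); the p-value
#' is the proportion of label permutations with \eqn{F_{perm} \ge F_{obs}},
#' including the observed labeling.
#'
#' @param d Symmetric distance matrix.
#' @param groups Group labels, one per row of `d`; at least two groups with
#'   at least two members each.
#' @param n_perm Number of random label permutations (default 999).
#' @param seed Optional RNG seed.
#' @return List of class `"permanova_result"`: `statistic`, `value`
#'   (pseudo-F), `p_value`, `n_permutations`, `df`, `ss`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("permanova: one group label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("permanova: need >= 2 groups")
  if (any(sizes < 2)) {
    stop("permanova: group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (max(abs(d - t(d))) > 1e-8) stop("permanova: asymmetric distance matrix")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d^2
  k <- length(sizes)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  f_obs <- permanova_f(d2, groups, sizes, ss_t, k, n)
  f_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    f_perm[b] <- permanova_f(d2, groups[sample.int(n)], sizes, ss_t, k, n)$f
  }
  p <- (1 + sum(f_perm >= f_obs$f - 1e-12)) / (1 + n_perm)
  structure(list(statistic = "pseudo-F", value = f_obs$f, p_value = p,
                 n_permutations = n_perm, df = c(k - 1, n - k),
                 ss = list(total = ss_t, between = f_obs$ss_a,
                           within = f_obs$ss_w)),
            class = "permanova_result")
}

permanova_f <- function(d2, labels, sizes, ss_t, k, n) {
  ss_w <- 0
  for (g in names(sizes)) {
    idx <- which(labels == g)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_a <- ss_t - ss_w
  list(f = (ss_a / (k - 1)) / (ss_w / (n - k)), ss_a = ss_a, ss_w = ss_w)
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", signif(x$value, 4), " df =",
      paste(x$df, collapse = "/"), " p =", signif(x$p_value, 4),
      " (", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard fixed-effects one-way ANOVA followed by Tukey's honest
#' significant difference test on all group pairs (studentized-range
#' distribution with pooled variance). Degenerate inputs are handled
#' explicitly: with zero pooled variance, identical group means give p = 1
#' everywhere and distinct means give p = 0 with a warning.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @return List of class `"anova_tukey_result"`: `f`, `p_value`, `df`, and
#'   `tukey`, a data frame with `group1`, `group2`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop("anova_tukey: values and groups lengths differ")
  }
  if (any(!is.finite(values))) stop("anova_tukey: non-finite values")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("anova_tukey: need >= 2 groups")
  if (any(sizes < 2)) {
    stop("anova_tukey: group(s) with < 2 values: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  g <- factor(groups)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  gm <- tapply(values, g, mean)
  n <- length(values)
  k <- nlevels(g)
  ss_w <- sum((values - gm[as.character(g)])^2)
  if (ss_w == 0) {
    same <- max(gm) - min(gm) == 0
    tk <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     diff = gm[pairs[2, ]] - gm[pairs[1, ]],
                     lwr = NA_real_, upr = NA_real_,
                     p_adj = if (same) 1 else
                       ifelse(gm[pairs[2, ]] == gm[pairs[1, ]], 1, 0),
                     stringsAsFactors = FALSE, row.names = NULL)
    if (!same) {
      warning("anova_tukey: zero within-group variance with unequal means")
    }
    return(structure(list(f = if (same) 0 else Inf,
                          p_value = if (same) 1 else 0,
                          df = c(k - 1, n - k), tukey = tk),
                     class = "anova_tukey_result"))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$g
  cmp <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tk <- data.frame(group1 = vapply(cmp, `[`, character(1), 2),
                   group2 = vapply(cmp, `[`, character(1), 1),
                   diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                   upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(f = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                 df = an[["Df"]], tukey = tk),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat("One-way ANOVA: F =", signif(x$f, 4), " p =", signif(x$p_value, 4),
      "\nTukey HSD:\n")
  print(x$tukey)
  invisible(x)
}

#' Per-timepoint treatment-vs-control testing of a relative time series
#'
#' Fits a two-factor fixed-effects ANOVA (treatment, timepoint,
#' interaction) on the chamber-level values of one parameter, then tests
#' each fiber arm against the control at every timepoint using the pooled
#' error term, Bonferroni-correcting across all (timepoint x treatment)
#' contrasts — the "# indicates p < 0.05" convention of relative
#' time-course panels. Chamber measurements are treated as independent
#' replicates within each cell; within-chamber autocorrelation is not
#' modeled.
#'
#' @param ts Long time-series table of one parameter.
#' @param meta Sample metadata.
#' @param control Control treatment label.
#' @param alpha Flagging level after correction.
#' @return List of class `"timeseries_test_result"`: `anova` (two-way
#'   table), `contrasts` (data frame with `treatment`, `timepoint_h`,
#'   `diff`, `p_raw`, `p_bonferroni`, `flag`), `m` (number of contrasts).
#' @export
timeseries_test <- function(ts, meta, control = "cellulose", alpha = 0.05) {
  ts <- as.data.frame(ts)
  par <- unique(ts$parameter)
  if (length(par) != 1) {
    stop("timeseries_test: table must contain exactly one parameter")
  }
  md <- meta[match(ts$sample_id, meta$sample_id), ]
  df <- data.frame(value = ts$value,
                   treatment = factor(md$treatment),
                   timepoint = factor(md$timepoint_h))
  cells <- table(df$treatment, df$timepoint)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("timeseries_test: empty cell(s): ",
         paste(sprintf("%s@%sh", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  }
  if (any(cells < 2)) {
    stop("timeseries_test: need >= 2 chambers per (treatment, timepoint)")
  }
  fit <- stats::aov(value ~ treatment * timepoint, data = df)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  treats <- setdiff(levels(df$treatment), control)
  tps <- levels(df$timepoint)
  m <- length(treats) * length(tps)
  out <- expand.grid(treatment = treats, timepoint_h = as.numeric(tps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$diff <- NA_real_
  out$p_raw <- NA_real_
  for (r in seq_len(nrow(out))) {
    sel_t <- df$treatment == out$treatment[r] &
      df$timepoint == as.character(out$timepoint_h[r])
    sel_c <- df$treatment == control &
      df$timepoint == as.character(out$timepoint_h[r])
    n1 <- sum(sel_t)
    n2 <- sum(sel_c)
    delta <- mean(df$value[sel_t]) - mean(df$value[sel_c])
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    out$diff[r] <- delta
    out$p_raw[r] <- if (se == 0) {
      if (delta == 0) 1 else 0
    } else {
      2 * stats::pt(-abs(delta / se), df_err)
    }
  }
  out$p_bonferroni <- pmin(1, m * out$p_raw)
  out$flag <- out$p_bonferroni < alpha
  structure(list(anova = an, contrasts = out, m = m, parameter = par,
                 alpha = alpha),
            class = "timeseries_test_result")
}

#' @export
print.timeseries_test_result <- function(x, ...) {
  cat("Two-way ANOVA on '", x$parameter, "' with ", x$m,
      " Bonferroni-corrected treatment-vs-control contrasts; ",
      sum(x$contrasts$flag), " flagged at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}
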