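feature_order <- c("bacterial_load", "beta_bc", "beta_uu", "evenness",
                   "lps", "flagellin")

#' Assemble the six-parameter chamber feature matrix
#'
#' Builds, for every chamber at the evaluation timepoint (48 h after
#' treatment initiation by default, i.e. 120 h), the composite profile used
#' to judge fiber sensitivity: bacterial load, Bray-Curtis and unweighted
#' UniFrac distance of the chamber to its own pre-treatment (72 h)
#' composition, Pielou evenness, and bioactive LPS and flagellin levels.
#'
#' Scalar parameters (load, evenness, LPS, flagellin) are first expressed
#' relative to the control arm per timepoint and then relative to the 72 h
#' baseline. The two beta distances enter raw: they are already
#' baseline-referenced by construction (distance to the chamber's own 72 h
#' composition, identically zero at baseline), and a control ratio at the
#' single evaluation timepoint would divide a donor's whole column by one
#' constant — immaterial after the within-donor scaling below, while
#' undefined when stable control chambers drift by exactly zero. Each
#' column is then min-max scaled to `[0, 1]` within donor so no single
#' parameter dominates the composite Bray-Curtis distance.
#'
#' @param study An [make_study()] result, or a list with elements `counts`,
#'   `meta`, `loads`, `tree` and either `assay` + `standards` or
#'   `mamp_true`.
#' @param mamp `"assay"` quantifies LPS/flagellin from the reporter-cell
#'   dilution series through the fitted 4PL standard curves; `"true"` uses
#'   latent concentrations directly (simulation diagnostics only).
#' @param eval_time Evaluation timepoint in hours (default baseline + 48).
#' @param baseline_h Pre-treatment baseline timepoint.
#' @param normalize Apply the control/baseline normalization rules; turn
#'   off only for noise-free diagnostic runs where control chambers have
#'   exactly zero beta distance.
#' @param scaling Per-column scaling within donor: `"minmax"` (default),
#'   `"zscore"` (shifted to be non-negative), or `"none"`.
#' @param control Control treatment label.
#' @return Object of class `"feature_matrix"`: list with `features`
#'   (chambers x 6 matrix), `chambers` (metadata rows), `scaling` records,
#'   `eval_time`.
#' @export
assemble_features <- function(study, mamp = c("assay", "true"),
                              eval_time = NULL, baseline_h = NULL,
                              normalize = TRUE,
                              scaling = c("minmax", "zscore", "none"),
                              control = "cellulose") {
  mamp <- match.arg(mamp)
  scaling <- match.arg(scaling)
  cfg <- study$config
  if (is.null(baseline_h)) {
    baseline_h <- if (!is.null(cfg)) cfg$stabilization_end_h else 72
  }
  if (is.null(eval_time)) eval_time <- baseline_h + 48
  meta <- study$meta
  counts <- study$counts

  at <- meta$timepoint_h %in% c(baseline_h, eval_time)
  scalar_ids <- meta$sample_id[at]

  loads <- study$loads
  load_ts <- timeseries_table(
    scalar_ids, "bacterial_load",
    loads$load[match(scalar_ids, loads$sample_id)]
  )
  even_ts <- timeseries_table(
    scalar_ids, "evenness",
    apply(counts[scalar_ids, , drop = FALSE], 1, pielou_evenness)
  )
  if (mamp == "assay") {
    sub <- study$assay[study$assay$sample_id %in% scalar_ids, ]
    # samples outside the assay's dynamic range are set to the nearest
    # quantifiable bound (LOD/ULOQ substitution), the usual bioassay policy
    qt <- quantify_mamp(sub, study$standards, censor = TRUE)
    lps <- qt[qt$analyte == "lps", ]
    fla <- qt[qt$analyte == "flagellin", ]
    lps_ts <- timeseries_table(scalar_ids, "lps",
                               lps$concentration[match(scalar_ids, lps$sample_id)])
    fla_ts <- timeseries_table(scalar_ids, "flagellin",
                               fla$concentration[match(scalar_ids, fla$sample_id)])
  } else {
    mt <- study$mamp_true
    lps_ts <- timeseries_table(scalar_ids, "lps",
                               mt$lps[match(scalar_ids, mt$sample_id)])
    fla_ts <- timeseries_table(scalar_ids, "flagellin",
                               mt$flagellin[match(scalar_ids, mt$sample_id)])
  }
  scalars <- rbind(load_ts, even_ts, lps_ts, fla_ts)
  if (normalize) {
    scalars <- relative_to_control(scalars, meta, control = control)
    scalars <- relative_to_baseline(scalars, meta, baseline_h = baseline_h)
    assert_relative_invariants(scalars, meta, control = control,
                               baseline_h = baseline_h)
  }

  beta_counts <- counts[scalar_ids, , drop = FALSE]
  bc_ts <- beta_evolution(beta_counts, meta, "bray_curtis",
                          reference_h = baseline_h, relative = FALSE)
  uu_ts <- beta_evolution(beta_counts, meta, "unweighted_unifrac",
                          tree = study$tree, reference_h = baseline_h,
                          relative = FALSE)

  long <- rbind(as.data.frame(scalars), as.data.frame(bc_ts),
                as.data.frame(uu_ts))
  md <- meta[match(long$sample_id, meta$sample_id), ]
  long <- long[md$timepoint_h == eval_time, ]
  md <- md[md$timepoint_h == eval_time, ]
  long$chamber_id <- paste(md$donor, md$treatment, md$chamber, sep = ".")

  chambers <- unique(md[, c("donor", "treatment", "chamber")])
  chambers$chamber_id <- paste(chambers$donor, chambers$treatment,
                               chambers$chamber, sep = ".")
  fmat <- matrix(NA_real_, nrow(chambers), length(feature_order),
                 dimnames = list(chambers$chamber_id, feature_order))
  for (p in feature_order) {
    sub <- long[long$parameter == p, ]
    fmat[sub$chamber_id, p] <- sub$value
  }
  if (anyNA(fmat)) {
    gaps <- which(is.na(fmat), arr.ind = TRUE)
    stop("assemble_features: missing parameter values: ",
         paste(sprintf("%s/%s", rownames(fmat)[gaps[, 1]],
                       colnames(fmat)[gaps[, 2]]), collapse = ", "))
  }

  scale_rec <- list()
  if (scaling != "none") {
    for (d in unique(chambers$donor)) {
      rows <- chambers$donor == d
      block <- fmat[rows, , drop = FALSE]
      rec <- list()
      for (p in feature_order) {
        v <- block[, p]
        if (scaling == "minmax") {
          rng <- range(v)
          if (diff(rng) == 0) {
            warning("assemble_features: constant column '", p,
                    "' for donor ", d, "; scaled to zeros")
            block[, p] <- 0
          } else {
            block[, p] <- (v - rng[1]) / diff(rng)
          }
          rec[[p]] <- rng
        } else { # zscore, shifted to be non-negative
          mu <- mean(v)
          sdv <- stats::sd(v)
          if (sdv == 0) {
            warning("assemble_features: constant column '", p,
                    "' for donor ", d, "; scaled to zeros")
            block[, p] <- 0
          } else {
            z <- (v - mu) / sdv
            block[, p] <- z - min(z)
          }
          rec[[p]] <- c(mu, sdv)
        }
      }
      fmat[rows, ] <- block
      scale_rec[[d]] <- rec
    }
  }
  structure(list(features = fmat, chambers = chambers, scaling = scaling,
                 scaling_record = scale_rec, eval_time = eval_time,
                 baseline_h = baseline_h, normalized = normalize),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Composite feature matrix:", nrow(x$features), "chambers x",
      ncol(x$features), "parameters at", x$eval_time, "h (",
      x$scaling, "scaling )\n")
  invisible(x)
}

#' Composite Bray-Curtis distance over feature rows
#'
#' @param fm A [assemble_features()] result (or a bare non-negative
#'   matrix).
#' @return Symmetric distance matrix over chambers.
#' @export
feature_distance <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
  bray_curtis_matrix(x, normalize = FALSE)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower double-centering of \eqn{-\tfrac12 D^2} followed by a symmetric
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues, which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis, are reported and
#' by default left uncorrected; `correction = "cailliez"` adds the smallest
#' constant to off-diagonal distances making the configuration Euclidean.
#' Axis signs are fixed deterministically: the largest-magnitude coordinate
#' on each axis is made positive.
#'
#' @param d Symmetric distance matrix with zero diagonal, `n >= 3`.
#' @param n_axes Number of axes to keep (`NULL` = all positive axes).
#' @param correction `"none"` or `"cailliez"`.
#' @return Object of class `"pcoa_result"`: `coordinates`, `eigenvalues`
#'   (all, decreasing), `proportion_explained` (over positive eigenvalues),
#'   `negative_eigenvalues` summary, `correction`.
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("pcoa: need at least 3 objects")
  if (ncol(d) != n) stop("pcoa: distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("pcoa: asymmetric distance matrix")
  if (any(diag(d) != 0)) stop("pcoa: nonzero diagonal")
  if (correction == "cailliez") {
    cc <- cailliez_constant(d)
    if (cc > 0) d <- d + cc * (1 - diag(n))
  }
  b <- gower_center(-0.5 * d^2)
  eg <- eigen(b, symmetric = TRUE)
  vals <- eg$values
  tol <- 1e-8 * max(1, abs(vals[1]))
  pos <- which(vals > tol)
  if (length(pos) == 0) {
    coords <- matrix(numeric(0), n, 0, dimnames = list(rownames(d), NULL))
  } else {
    coords <- eg$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(vals[pos]), length(pos))
    # deterministic axis orientation
    for (k in seq_len(ncol(coords))) {
      i <- which.max(abs(coords[, k]))
      if (coords[i, k] < 0) coords[, k] <- -coords[, k]
    }
    dimnames(coords) <- list(rownames(d),
                             paste0("Axis", seq_len(ncol(coords))))
  }
  keep <- if (is.null(n_axes)) ncol(coords) else min(n_axes, ncol(coords))
  prop <- if (length(pos) > 0) vals[pos] / sum(vals[pos]) else numeric(0)
  structure(
    list(coordinates = coords[, seq_len(keep), drop = FALSE],
         all_coordinates = coords,
         eigenvalues = vals,
         proportion_explained = prop,
         negative_eigenvalues = list(count = sum(vals < -tol),
                                     min = min(vals),
                                     sum = sum(vals[vals < 0])),
         correction = correction),
    class = "pcoa_result"
  )
}

gower_center <- function(a) {
  n <- nrow(a)
  rm <- rowMeans(a)
  cm <- colMeans(a)
  a - outer(rm, rep(1, n)) - outer(rep(1, n), cm) + mean(a)
}

# Cailliez (1983) constant: largest eigenvalue of the 2n x 2n companion
# problem built from the centered -D^2/2 and -D/2 matrices.
cailliez_constant <- function(d) {
  n <- nrow(d)
  d1 <- gower_center(-0.5 * d^2)
  d2 <- gower_center(-0.5 * d)
  sp <- rbind(cbind(matrix(0, n, n), 2 * d1),
              cbind(-diag(n), -4 * d2))
  max(Re(eigen(sp, only.values = TRUE)$values))
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "objects,", ncol(x$all_coordinates),
      "positive axes\n")
  if (length(x$proportion_explained) >= 2) {
    cat("  axis 1-2 explain",
        sprintf("%.1f%% + %.1f%%", 100 * x$proportion_explained[1],
                100 * x$proportion_explained[2]), "\n")
  }
  if (x$negative_eigenvalues$count > 0) {
    cat("  ", x$negative_eigenvalues$count, "negative eigenvalue(s), min",
        signif(x$negative_eigenvalues$min, 3), "\n")
  }
  invisible(x)
}

#' Correlation arrows of features on the first two PCoA axes
#'
#' Arrow for feature \eqn{j} is the pair of Pearson correlations between
#' the feature column and the first two principal coordinates, the usual
#' way variable vectors are overlaid on an ordination.
#'
#' @param fm A [assemble_features()] result (or matrix).
#' @param p A [pcoa()] result with at least 2 axes.
#' @return Matrix features x 2 of arrow components, norm at most sqrt(2).
#' @export
variable_vectors <- function(fm, p) {
  x <- if (inherits(fm, "feature_matrix")) fm$features else as.matrix(fm)
  coords <- p$all_coordinates
  if (ncol(coords) < 2) stop("variable_vectors: need >= 2 retained axes")
  arrows <- matrix(0, ncol(x), 2,
                   dimnames = list(colnames(x), c("Axis1", "Axis2")))
  for (j in seq_len(ncol(x))) {
    if (stats::sd(x[, j]) == 0) {
      warning("variable_vectors: zero-variance feature '", colnames(x)[j],
              "'; arrow set to 0")
      next
    }
    arrows[j, 1] <- stats::cor(x[, j], coords[, 1])
    arrows[j, 2] <- stats::cor(x[, j], coords[, 2])
  }
  arrows
}

#' Cellulose-cellulose / cellulose-fiber distance contrast for one donor
#'
#' Extracts, from a chamber distance matrix, the within-control pairwise
#' distances (`d_cc`) and the control-by-fiber distances (`d_ci`, `d_cp`),
#' each unordered pair counted once.
#'
#' @param d Chamber distance matrix (e.g. [feature_distance()]).
#' @param chambers Chamber metadata with columns `chamber_id`, `donor`,
#'   `treatment` matching the rows of `d`.
#' @param donor Donor to extract.
#' @param control Control treatment label.
#' @param fibers Fiber treatment labels.
#' @return Object of class `"distance_contrast"`: list with `donor`, `d`
#'   (donor submatrix), `treatment` labels, `sets` (named list of distance
#'   vectors `d_cc`, `d_ci`, `d_cp`), `means`.
#' @export
distance_contrast <- function(d, chambers, donor, control = "cellulose",
                              fibers = c("inulin", "psyllium")) {
  rows <- chambers$donor == donor
  if (!any(rows)) stop("distance_contrast: unknown donor ", donor)
  ids <- chambers$chamber_id[rows]
  treatment <- chambers$treatment[rows]
  dd <- d[ids, ids, drop = FALSE]
  ci <- which(treatment == control)
  if (length(ci) < 2) {
    stop("distance_contrast: need >= 2 control chambers (d_cc undefined)")
  }
  sets <- list(d_cc = dd[ci, ci][upper.tri(matrix(0, length(ci), length(ci)))])
  for (f in fibers) {
    fi <- which(treatment == f)
    if (length(fi) < 1) {
      stop("distance_contrast: no ", f, " chambers for donor ", donor)
    }
    sets[[paste0("d_c", substr(f, 1, 1))]] <- as.numeric(dd[ci, fi])
  }
  structure(list(donor = donor, d = dd, treatment = treatment,
                 control = control, fibers = fibers, sets = sets,
                 means = vapply(sets, mean, numeric(1))),
            class = "distance_contrast")
}

#' Classify a donor as fiber-sensitive or fiber-resistant
#'
#' Tests whether the composite distance between control and fiber-treated
#' chambers exceeds the distance among control chambers. Two routes are
#' always computed: a one-way ANOVA across the three distance sets followed
#' by Tukey HSD (the conventional test), and a one-sided chamber-label
#' permutation test of `mean(d_cf) - mean(d_cc)` for each fiber, which
#' respects the exchangeability structure of pairwise distances by
#' permuting the nine chamber treatment labels rather than the pairs.
#' Fiber-level p-values carry an additional Bonferroni factor 2 for the two
#' fiber contrasts. The donor is called sensitive when, under the selected
#' method, any fiber's corrected p-value is below `alpha` and the contrast
#' is an increase.
#'
#' @param contrast A [distance_contrast()].
#' @param method `"permutation"` (default) or `"anova_tukey"`.
#' @param alpha Significance level.
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed for the permutations.
#' @return Object of class `"sensitivity_call"`: one-row data frame with
#'   donor, status, mean distances, per-fiber corrected p-values for both
#'   methods, method and alpha.
#' @export
classify_donor <- function(contrast, method = c("permutation", "anova_tukey"),
                           alpha = 0.05, n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  sets <- contrast$sets
  fibers <- contrast$fibers
  means <- contrast$means
  diffs <- means[-1] - means[1]

  all_d <- unlist(sets)
  degenerate <- max(all_d) - min(all_d) < 1e-12

  # ANOVA + Tukey route
  if (degenerate) {
    p_tukey <- rep(1, length(fibers))
  } else {
    grp <- rep(names(sets), lengths(sets))
    at <- anova_tukey(unlist(sets, use.names = FALSE), grp)
    p_tukey <- vapply(seq_along(fibers), function(k) {
      key <- paste0("d_c", substr(fibers[k], 1, 1))
      row <- at$tukey[(at$tukey$group1 == "d_cc" & at$tukey$group2 == key) |
                        (at$tukey$group1 == key & at$tukey$group2 == "d_cc"), ]
      row$p_adj[1]
    }, numeric(1))
  }
  p_tukey_corr <- pmin(1, 2 * p_tukey)

  # chamber-label permutation route
  if (degenerate) {
    p_perm <- rep(1, length(fibers))
  } else {
    if (!is.null(seed)) set.seed(seed)
    p_perm <- permutation_contrast_p(contrast$d, contrast$treatment,
                                     contrast$control, fibers, n_perm)
  }
  p_perm_corr <- pmin(1, 2 * p_perm)

  p_used <- if (method == "permutation") p_perm_corr else p_tukey_corr
  sensitive <- any(p_used < alpha & diffs > 0)

  out <- data.frame(
    donor = contrast$donor,
    status = if (sensitive) "sensitive" else "resistant",
    d_cc = means[["d_cc"]],
    stringsAsFactors = FALSE
  )
  for (k in seq_along(fibers)) {
    key <- paste0("d_c", substr(fibers[k], 1, 1))
    out[[key]] <- means[[key]]
    out[[paste0("p_perm_", fibers[k])]] <- p_perm_corr[k]
    out[[paste0("p_tukey_", fibers[k])]] <- p_tukey_corr[k]
  }
  out$method <- method
  out$alpha <- alpha
  class(out) <- c("sensitivity_call", class(out))
  out
}

# One-sided Monte-Carlo p-values for mean(d_cf) - mean(d_cc) under
# permutation of the full chamber treatment-label vector.
permutation_contrast_p <- function(d, treatment, control, fibers, n_perm) {
  n <- length(treatment)
  perm <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- sample.int(n)
  lab <- matrix(treatment[perm], n, n_perm)
  zc <- lab == control
  dc <- d %*% zc                               # n x B
  n_c <- sum(treatment == control)
  within_c <- colSums(dc * zc) / (n_c * (n_c - 1))   # mean over ordered pairs
  obs_zc <- treatment == control
  obs_within <- sum(d[obs_zc, obs_zc]) / (n_c * (n_c - 1))
  vapply(fibers, function(f) {
    zf <- lab == f
    n_f <- sum(treatment == f)
    cross <- colSums(dc * zf) / (n_c * n_f)
    stat <- cross - within_c
    obs_zf <- treatment == f
    obs <- sum(d[obs_zc, obs_zf]) / (n_c * n_f) - obs_within
    (1 + sum(stat >= obs - 1e-12)) / (1 + n_perm)
  }, numeric(1))
}

#' Run the full sensitivity pipeline on a study
#'
#' Assembles the six-parameter feature matrix, computes per-donor composite
#' Bray-Curtis distances and contrasts, classifies every donor, and
#' computes the all-donor PCoA with variable vectors.
#'
#' @param study An [make_study()] result (or equivalent list).
#' @param method Significance method passed to [classify_donor()].
#' @param alpha Significance level.
#' @param n_perm Permutations per contrast.
#' @param seed Optional RNG seed for the permutation tests.
#' @param outdir Optional directory; when given, writes `features.tsv`,
#'   `distances.tsv`, `pcoa.tsv`, `vectors.tsv`, `calls.tsv`.
#' @inheritParams assemble_features
#' @return List with `calls` (data frame, one row per donor), `features`,
#'   `distance` (all-chamber matrix), `pcoa`, `vectors`, `contrasts`.
#' @export
run_sensitivity <- function(study, method = c("permutation", "anova_tukey"),
                            alpha = 0.05, n_perm = 9999, seed = NULL,
                            mamp = c("assay", "true"), eval_time = NULL,
                            outdir = NULL) {
  method <- match.arg(method)
  mamp <- match.arg(mamp)
  fm <- assemble_features(study, mamp = mamp, eval_time = eval_time)
  d_all <- feature_distance(fm)
  pc <- pcoa(d_all, n_axes = 2)
  vec <- variable_vectors(fm, pc)
  donors <- unique(fm$chambers$donor)
  contrasts <- vector("list", length(donors))
  names(contrasts) <- donors
  calls <- vector("list", length(donors))
  for (i in seq_along(donors)) {
    sub <- fm$chambers$donor == donors[i]
    dd <- feature_distance(fm$features[fm$chambers$chamber_id[sub], ,
                                       drop = FALSE])
    contrasts[[i]] <- distance_contrast(dd, fm$chambers[sub, ], donors[i])
    calls[[i]] <- classify_donor(contrasts[[i]], method = method,
                                 alpha = alpha, n_perm = n_perm, seed = seed)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  res <- list(calls = calls, features = fm, distance = d_all, pcoa = pc,
              vectors = vec, contrasts = contrasts)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_tsv(data.frame(chamber_id = rownames(fm$features),
                         fm$chambers[, c("donor", "treatment", "chamber")],
                         fm$features, check.names = FALSE),
              file.path(outdir, "features.tsv"))
    write_tsv(data.frame(chamber_id = rownames(d_all), d_all,
                         check.names = FALSE),
              file.path(outdir, "distances.tsv"))
    write_tsv(data.frame(chamber_id = rownames(pc$coordinates),
                         pc$coordinates, check.names = FALSE),
              file.path(outdir, "pcoa.tsv"))
    write_tsv(data.frame(feature = rownames(vec), vec, check.names = FALSE),
              file.path(outdir, "vectors.tsv"))
    write_tsv(calls, file.path(outdir, "calls.tsv"))
  }
  res
}
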