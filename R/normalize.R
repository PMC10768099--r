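#' Express a time series relative to the control (cellulose) arm
#'
#' For each donor, parameter and timepoint, every value is divided by the
#' arithmetic mean of the same donor's control-arm values at that timepoint,
#' so the control arm averages exactly 1 everywhere and treated arms become
#' fold-changes relative to control. This is the first of the two
#' presentation rules applied to all MBRA readouts.
#'
#' @param ts A long time-series table (`sample_id`, `parameter`, `value`).
#' @param meta Sample metadata ([read_metadata()] shape).
#' @param control Control treatment label (default `"cellulose"`).
#' @param mean_fun Aggregation across control chambers: `"arithmetic"`
#'   (default) or `"geometric"`.
#' @return The normalized table with attribute `control_normalized = TRUE`.
#' @export
relative_to_control <- function(ts, meta, control = "cellulose",
                                mean_fun = c("arithmetic", "geometric")) {
  mean_fun <- match.arg(mean_fun)
  ts <- validate_timeseries(as.data.frame(ts))
  if (any(ts$value < 0)) {
    stop("relative_to_control: negative values; ratios need a ratio scale")
  }
  md <- meta[match(ts$sample_id, meta$sample_id), ]
  if (any(is.na(md$sample_id))) {
    stop("relative_to_control: samples missing from metadata")
  }
  mm <- cbind(ts, md[, c("donor", "treatment", "timepoint_h")])
  out <- ts
  key_all <- paste(mm$donor, mm$parameter, mm$timepoint_h, sep = "\r")
  ctrl <- mm[mm$treatment == control, ]
  if (nrow(ctrl) == 0) stop("relative_to_control: no control samples")
  key_ctrl <- paste(ctrl$donor, ctrl$parameter, ctrl$timepoint_h, sep = "\r")
  agg <- if (mean_fun == "arithmetic") {
    tapply(ctrl$value, key_ctrl, mean)
  } else {
    exp(tapply(log(ctrl$value), key_ctrl, mean))
  }
  missing <- setdiff(unique(key_all), names(agg))
  if (length(missing) > 0) {
    stop("relative_to_control: no control values for (donor, parameter, ",
         "timepoint): ", paste(gsub("\r", "/", missing), collapse = "; "))
  }
  denom <- as.numeric(agg[key_all])
  if (any(denom == 0)) {
    bad <- unique(key_all[denom == 0])
    stop("relative_to_control: control mean is zero for: ",
         paste(gsub("\r", "/", bad), collapse = "; "))
  }
  out$value <- mm$value / denom
  out <- validate_timeseries(out)
  attr(out, "control_normalized") <- TRUE
  attr(out, "baseline_normalized") <- isTRUE(attr(ts, "baseline_normalized"))
  out
}

#' Normalize each arm to its pre-treatment baseline
#'
#' The second presentation rule: for each donor, treatment arm and
#' parameter, values are divided by that arm's mean value at the last
#' pre-treatment timepoint (72 h in the MBRA design), so all arms start the
#' treatment phase at 1. Idempotent: once the baseline mean is 1, applying
#' the rule again changes nothing.
#'
#' @param ts A long time-series table, typically already
#'   control-normalized.
#' @param meta Sample metadata.
#' @param baseline_h Baseline timepoint in hours (default 72).
#' @return The normalized table with attribute `baseline_normalized = TRUE`.
#' @export
relative_to_baseline <- function(ts, meta, baseline_h = 72) {
  was_control <- isTRUE(attr(ts, "control_normalized"))
  ts <- validate_timeseries(as.data.frame(ts))
  md <- meta[match(ts$sample_id, meta$sample_id), ]
  if (any(is.na(md$sample_id))) {
    stop("relative_to_baseline: samples missing from metadata")
  }
  mm <- cbind(ts, md[, c("donor", "treatment", "timepoint_h")])
  key_all <- paste(mm$donor, mm$treatment, mm$parameter, sep = "\r")
  base <- mm[mm$timepoint_h == baseline_h, ]
  if (nrow(base) == 0) {
    stop("relative_to_baseline: no samples at baseline ", baseline_h, " h")
  }
  key_base <- paste(base$donor, base$treatment, base$parameter, sep = "\r")
  agg <- tapply(base$value, key_base, mean)
  missing <- setdiff(unique(key_all), names(agg))
  if (length(missing) > 0) {
    stop("relative_to_baseline: no baseline value for (donor, treatment, ",
         "parameter): ", paste(gsub("\r", "/", missing), collapse = "; "))
  }
  denom <- as.numeric(agg[key_all])
  if (any(denom == 0)) {
    bad <- unique(key_all[denom == 0])
    stop("relative_to_baseline: baseline value is zero for: ",
         paste(gsub("\r", "/", bad), collapse = "; "))
  }
  out <- ts
  out$value <- mm$value / denom
  out <- validate_timeseries(out)
  attr(out, "control_normalized") <- was_control
  attr(out, "baseline_normalized") <- TRUE
  out
}

#' Assert the normalization invariants of a relative series
#'
#' Checks that the control-arm mean is 1 at every (donor, parameter,
#' timepoint) and/or that every arm's mean is 1 at the baseline timepoint,
#' according to the table's provenance flags.
#'
#' @param ts Normalized long table.
#' @param meta Sample metadata.
#' @param control Control treatment label.
#' @param baseline_h Baseline timepoint.
#' @param tol Numerical tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
assert_relative_invariants <- function(ts, meta, control = "cellulose",
                                       baseline_h = 72, tol = 1e-10) {
  mm <- merge(as.data.frame(ts), meta, by = "sample_id", sort = FALSE)
  if (isTRUE(attr(ts, "control_normalized"))) {
    ctrl <- mm[mm$treatment == control, ]
    means <- tapply(ctrl$value,
                    paste(ctrl$donor, ctrl$parameter, ctrl$timepoint_h),
                    mean)
    if (any(abs(means - 1) > tol)) {
      stop("invariant violated: control mean != 1 at some timepoint")
    }
  }
  if (isTRUE(attr(ts, "baseline_normalized"))) {
    base <- mm[mm$timepoint_h == baseline_h, ]
    means <- tapply(base$value,
                    paste(base$donor, base$treatment, base$parameter), mean)
    if (any(abs(means - 1) > tol)) {
      stop("invariant violated: arm mean != 1 at baseline")
    }
  }
  invisible(TRUE)
}

#' Within-chamber beta-diversity evolution
#'
#' For each chamber, computes the dissimilarity between its community at
#' every post-reference timepoint and its own community at the reference
#' timepoint (the last pre-treatment sample, 72 h by default), for
#' timepoints strictly after the reference. Optionally the resulting series
#' is expressed relative to the control arm.
#'
#' @param counts Count matrix, samples x taxa.
#' @param meta Sample metadata.
#' @param metric `"bray_curtis"` or `"unweighted_unifrac"`.
#' @param tree Required for UniFrac.
#' @param reference_h Reference timepoint (hours).
#' @param relative Pass the raw distances through [relative_to_control()].
#' @param control Control treatment label.
#' @param min_count Presence threshold for UniFrac.
#' @return Long time-series table with parameter `beta_bc` or `beta_uu`.
#' @export
beta_evolution <- function(counts, meta,
                           metric = c("bray_curtis", "unweighted_unifrac"),
                           tree = NULL, reference_h = 72, relative = TRUE,
                           control = "cellulose", min_count = 1) {
  metric <- match.arg(metric)
  param <- if (metric == "bray_curtis") "beta_bc" else "beta_uu"
  if (metric == "unweighted_unifrac" && is.null(tree)) {
    stop("beta_evolution: UniFrac requires a tree")
  }
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  if (any(is.na(meta$sample_id))) {
    stop("beta_evolution: count table samples missing from metadata")
  }
  chamber <- paste(meta$donor, meta$treatment, meta$chamber, sep = ".")
  idx <- which(meta$timepoint_h > reference_h)
  if (length(idx) == 0) {
    stop("beta_evolution: no samples after the reference timepoint")
  }
  ref_of <- function(ch) {
    r <- which(chamber == ch & meta$timepoint_h == reference_h)
    if (length(r) != 1) {
      stop("beta_evolution: chamber ", ch, " lacks a unique sample at ",
           reference_h, " h")
    }
    r
  }
  refs <- vapply(unique(chamber), ref_of, integer(1))
  pair_ref <- refs[chamber[idx]]
  if (metric == "bray_curtis") {
    prop <- counts / rowSums(counts)
    vals <- vapply(seq_along(idx), function(k) {
      i <- idx[k]
      j <- pair_ref[k]
      sum(abs(prop[i, ] - prop[j, ])) / sum(prop[i, ] + prop[j, ])
    }, numeric(1))
  } else {
    vals <- unifrac_pairs(counts, cbind(pair_ref, idx), tree,
                          min_count = min_count)
  }
  ts <- timeseries_table(meta$sample_id[idx], param, vals)
  if (relative) ts <- relative_to_control(ts, meta, control = control)
  ts
}
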