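#' Assemble a run report from a pipeline output directory
#'
#' Reads the TSV outputs of [write_study()] and [run_sensitivity()] from a
#' run directory, verifies file integrity against `manifest.tsv` (writing
#' the manifest on first call), and produces a per-donor summary table. If
#' the directory holds a `truth.tsv` (synthetic runs), a confusion table of
#' calls against planted labels is appended.
#'
#' @param run_dir Directory containing `calls.tsv` (and optionally
#'   `truth.tsv`, `pcoa.tsv`, ...).
#' @param write Write `summary.tsv`, `report.md` and `manifest.tsv` into
#'   the run directory.
#' @return Object of class `"run_report"`: list with `summary` (data
#'   frame), `confusion` (table or `NULL`), `manifest`.
#' @export
build_report <- function(run_dir, write = TRUE) {
  calls_path <- file.path(run_dir, "calls.tsv")
  if (!file.exists(calls_path)) {
    stop("build_report: missing ", calls_path,
         "; rerun the sensitivity stage (run_sensitivity with outdir)")
  }
  files <- sort(setdiff(list.files(run_dir),
                        c("manifest.tsv", "report.md", "summary.tsv")))
  sums <- tools::md5sum(file.path(run_dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  man_path <- file.path(run_dir, "manifest.tsv")
  if (file.exists(man_path)) {
    old <- read_tsv(man_path, required = c("file", "md5"))
    common <- intersect(old$file, manifest$file)
    bad <- common[old$md5[match(common, old$file)] !=
                    manifest$md5[match(common, manifest$file)]]
    if (length(bad) > 0) {
      stop("build_report: checksum mismatch (file tampered or stale): ",
           paste(bad, collapse = ", "))
    }
  }
  calls <- read_tsv(calls_path, required = c("donor", "status"))
  summary_df <- calls
  confusion <- NULL
  truth_path <- file.path(run_dir, "truth.tsv")
  if (file.exists(truth_path)) {
    truth <- read_tsv(truth_path, required = c("donor", "sensitive"))
    joined <- merge(calls[, c("donor", "status")], truth, by = "donor")
    confusion <- table(called = joined$status,
                       planted = ifelse(joined$sensitive, "sensitive",
                                        "resistant"))
  }
  if (write) {
    write_tsv(summary_df, file.path(run_dir, "summary.tsv"))
    write_tsv(manifest, man_path)
    lines <- c("# Fiber-sensitivity run report", "",
               paste("Donors:", nrow(summary_df)), "",
               paste0("- ", summary_df$donor, ": ", summary_df$status))
    if (!is.null(confusion)) {
      lines <- c(lines, "", "Calls vs planted truth:",
                 utils::capture.output(print(confusion)))
    }
    writeLines(lines, file.path(run_dir, "report.md"))
  }
  structure(list(summary = summary_df, confusion = confusion,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report:", nrow(x$summary), "donor(s)\n")
  print(x$summary[, intersect(c("donor", "status"), names(x$summary))])
  if (!is.null(x$confusion)) {
    cat("\nCalls vs planted truth:\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Diagnostic PCoA scatter with variable vectors
#'
#' Base-graphics convenience plot of a composite ordination: chambers on
#' the first two principal coordinates, colored by treatment, with
#' feature-correlation arrows overlaid. Purely diagnostic; no computation
#' reads figures.
#'
#' @param res A [run_sensitivity()] result.
#' @param arrow_scale Multiplier applied to the correlation arrows.
#' @export
plot_pcoa <- function(res, arrow_scale = NULL) {
  xy <- res$pcoa$coordinates[, 1:2, drop = FALSE]
  tr <- factor(res$features$chambers$treatment)
  pe <- res$pcoa$proportion_explained
  if (is.null(arrow_scale)) arrow_scale <- 0.8 * max(abs(xy))
  plot(xy, col = as.integer(tr), pch = 19, asp = 1,
       xlab = sprintf("Axis 1 (%.1f%%)", 100 * pe[1]),
       ylab = sprintf("Axis 2 (%.1f%%)", 100 * pe[2]))
  graphics::arrows(0, 0, res$vectors[, 1] * arrow_scale,
                   res$vectors[, 2] * arrow_scale,
                   length = 0.08, col = "grey40")
  graphics::text(res$vectors * arrow_scale * 1.1,
                 labels = rownames(res$vectors), cex = 0.7, col = "grey20")
  graphics::legend("topright", legend = levels(tr), col = seq_along(levels(tr)),
                   pch = 19, bty = "n", cex = 0.8)
  invisible(res)
}
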