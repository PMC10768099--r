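#' Read a taxon-by-sample count table from TSV
#'
#' The file must have a header row of taxon ids and sample ids in the first
#' column. Cells must be non-negative integers; violations are reported with
#' the offending sample and taxon.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, samples in rows, taxa in columns.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_count_table: no taxon columns in ", path)
  samples <- as.character(df[[1]])
  taxa <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("read_count_table: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(taxa)) {
    stop("read_count_table: duplicate taxon ids: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("read_count_table: invalid count at sample '", samples[bad[1, 1]],
         "', taxon '", taxa[bad[1, 2]], "': ", m[bad[1, , drop = FALSE]])
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(samples, taxa)
  validate_count_table(m)
  m
}

validate_count_table <- function(counts) {
  if (any(counts < 0)) stop("count table: negative entries")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count table: samples and taxa must be named")
  }
  if (any(rowSums(counts) == 0)) {
    stop("count table: all-zero sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  }
  invisible(counts)
}

#' Write a count table as TSV
#'
#' @param counts Integer matrix, samples in rows, taxa in columns.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick tree with branch lengths
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("read_newick: unbalanced ')' at character ", i, " of ", path)
    }
  }
  if (depth != 0L) {
    stop("read_newick: ", depth, " unclosed '(' in ", path)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("read_newick: parse error in ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("read_newick: parse error in ", path)
  if (is.null(tree$edge.length)) {
    stop("read_newick: branch lengths are required on every edge")
  }
  if (any(tree$edge.length < 0)) stop("read_newick: negative branch length")
  tree
}

#' Write a tree as Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' @param path Tab-separated file with columns `sample_id`, `donor`,
#'   `treatment`, `chamber`, `timepoint_h`.
#' @return Validated data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(meta)
}

treatment_levels <- c("cellulose", "inulin", "psyllium", "antibiotic")

validate_metadata <- function(meta) {
  need <- c("sample_id", "donor", "treatment", "chamber", "timepoint_h")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("metadata: missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(meta$treatment), treatment_levels)
  if (length(bad) > 0) {
    stop("metadata: unknown treatment(s): ", paste(bad, collapse = ", "))
  }
  if (any(meta$timepoint_h < 0)) stop("metadata: negative timepoint_h")
  key <- interaction(meta$donor, meta$treatment, meta$chamber,
                     meta$timepoint_h, drop = TRUE)
  if (anyDuplicated(key)) {
    stop("metadata: duplicated (donor, treatment, chamber, timepoint)")
  }
  if (anyDuplicated(meta$sample_id)) stop("metadata: duplicate sample ids")
  meta
}

#' Write a data frame as TSV
#'
#' Plain tab-separated UTF-8 with '.' decimal separator, full precision.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @param required Character vector of columns that must be present.
#' @return Data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      stop("read_tsv(", path, "): missing column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  df
}

#' Build a long-format time-series table
#'
#' The common exchange shape for per-sample scalar readouts: one row per
#' (sample, parameter) pair.
#'
#' @param sample_id Sample identifiers.
#' @param parameter Parameter name, one of `bacterial_load`, `beta_bc`,
#'   `beta_uu`, `evenness`, `lps`, `flagellin`.
#' @param value Numeric values, finite.
#' @return Data frame with class `"timeseries_table"`.
#' @export
timeseries_table <- function(sample_id, parameter, value) {
  ts <- data.frame(sample_id = as.character(sample_id),
                   parameter = as.character(parameter),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  validate_timeseries(ts)
}

ts_parameters <- c("bacterial_load", "beta_bc", "beta_uu", "evenness",
                   "lps", "flagellin")

validate_timeseries <- function(ts) {
  if (!all(c("sample_id", "parameter", "value") %in% names(ts))) {
    stop("timeseries table needs columns sample_id, parameter, value")
  }
  if (any(!is.finite(ts$value))) stop("timeseries table: non-finite values")
  if (anyDuplicated(ts[, c("sample_id", "parameter")])) {
    stop("timeseries table: duplicate (sample, parameter) pairs")
  }
  class(ts) <- unique(c("timeseries_table", class(ts)))
  ts
}
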