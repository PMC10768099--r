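#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' Computes \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)} over the
#' shared taxon universe. Vectors may be counts or proportions; named vectors
#' are outer-joined on names with absent taxa treated as zero.
#'
#' @param u,v Non-negative numeric vectors. If both are named, they are
#'   aligned on the union of their names; otherwise they must have equal
#'   length and are aligned positionally.
#' @return A dissimilarity in `[0, 1]`: 0 for identical vectors, 1 for
#'   vectors with disjoint support.
#' @examples
#' bray_curtis(c(6, 2), c(2, 2)) # 4/12 = 1/3
#' @export
bray_curtis <- function(u, v) {
  uv <- align_abundances(u, v)
  u <- uv$u
  v <- uv$v
  if (any(u < 0) || any(v < 0)) {
    stop("bray_curtis: abundances must be non-negative")
  }
  denom <- sum(u + v)
  if (denom == 0) {
    stop("bray_curtis: undefined for two all-zero vectors")
  }
  sum(abs(u - v)) / denom
}

align_abundances <- function(u, v) {
  if (!is.null(names(u)) && !is.null(names(v))) {
    universe <- union(names(u), names(v))
    uu <- stats::setNames(numeric(length(universe)), universe)
    vv <- uu
    uu[names(u)] <- u
    vv[names(v)] <- v
    list(u = uu, v = vv)
  } else {
    if (length(u) != length(v)) {
      stop("abundance vectors must share a taxon universe: ",
           "name both vectors or give them equal length")
    }
    list(u = as.numeric(u), v = as.numeric(v))
  }
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param x Numeric matrix, samples in rows, taxa in columns.
#' @param normalize Divide each row by its total first, so that samples of
#'   unequal sequencing depth are compared on proportions (default `TRUE`).
#' @return Symmetric matrix of Bray-Curtis dissimilarities with zero
#'   diagonal, dimnames taken from `rownames(x)`.
#' @export
bray_curtis_matrix <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis_matrix: negative abundances")
  totals <- rowSums(x)
  if (any(totals == 0)) {
    stop("bray_curtis_matrix: all-zero sample(s): ",
         paste(rownames(x)[totals == 0], collapse = ", "))
  }
  if (normalize) x <- x / totals
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- sum(abs(x[i, ] - x[j, ]))
      den <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- num / den
    }
  }
  d
}

#' Unweighted UniFrac distance between two samples
#'
#' Presence/absence phylogenetic dissimilarity: the branch length unique to
#' one sample's observed lineages divided by the branch length observed in
#' either sample. A branch counts as observed for a sample when at least one
#' tip descending from it is present in that sample.
#'
#' @param u,v Abundance (or presence) vectors named by taxon. Taxa with value
#'   `>= min_count` are treated as present.
#' @param tree A rooted `phylo` tree with branch lengths whose tip labels
#'   cover all present taxa.
#' @param min_count Detection threshold (default 1); counts below it are
#'   treated as absent, absorbing low-level sequencing noise.
#' @return Dissimilarity in `[0, 1]`.
#' @export
unweighted_unifrac <- function(u, v, tree, min_count = 1) {
  pu <- presence_set(u, min_count)
  pv <- presence_set(v, min_count)
  check_tips(c(pu, pv), tree)
  inc <- edge_tip_incidence(tree)
  unifrac_from_incidence(pu, pv, inc, tree$edge.length)
}

presence_set <- function(u, min_count) {
  if (is.null(names(u))) stop("unifrac: abundance vectors must be named by taxon")
  names(u)[u >= min_count]
}

check_tips <- function(taxa, tree) {
  missing <- setdiff(unique(taxa), tree$tip.label)
  if (length(missing) > 0) {
    stop("unifrac: taxa absent from tree: ", paste(missing, collapse = ", "))
  }
}

# Logical edges x tips matrix: entry TRUE when the tip descends from the edge.
# Cached per tree via an attribute-free memo on the calling side; cheap for
# the tree sizes used here (<= a few hundred tips).
edge_tip_incidence <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  # postorder: children are resolved before their parent edge
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1L]
    child <- po$edge[k, 2L]
    below[[parent]] <- c(below[[parent]], below[[child]])
  }
  inc <- matrix(FALSE, nedge, ntip,
                dimnames = list(NULL, tree$tip.label))
  for (k in seq_len(nedge)) {
    inc[k, below[[tree$edge[k, 2L]]]] <- TRUE
  }
  inc
}

unifrac_from_incidence <- function(pu, pv, inc, edge_len) {
  in_u <- inc[, pu, drop = FALSE]
  in_v <- inc[, pv, drop = FALSE]
  obs_u <- rowSums(in_u) > 0
  obs_v <- rowSums(in_v) > 0
  observed <- obs_u | obs_v
  unique_b <- xor(obs_u, obs_v)
  total <- sum(edge_len[observed])
  if (total == 0) {
    stop("unifrac: no observed branch length (both samples empty?)")
  }
  sum(edge_len[unique_b]) / total
}

#' Pairwise unweighted UniFrac distance matrix
#'
#' @param x Count matrix, samples in rows, taxa (tree tips) in columns.
#' @inheritParams unweighted_unifrac
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unifrac_matrix <- function(x, tree, min_count = 1) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("unifrac_matrix: columns must be named by taxon")
  check_tips(colnames(x), tree)
  inc <- edge_tip_incidence(tree)
  # edges x samples observation matrix in one multiply
  pres <- t(x >= min_count)                       # tips x samples
  pres <- pres[colnames(inc), , drop = FALSE]
  obs <- (inc %*% pres) > 0                        # edges x samples
  len <- tree$edge.length
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  totals <- colSums(obs * len)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- sum(len[obs[, i] & obs[, j]])
      either <- totals[i] + totals[j] - shared
      if (either == 0) stop("unifrac_matrix: empty sample pair")
      d[i, j] <- d[j, i] <- (either - shared) / either
    }
  }
  d
}

#' UniFrac for many (reference, query) sample pairs at once
#'
#' Used by the beta-evolution pipeline where each chamber is compared only to
#' its own reference timepoint, so a full pairwise matrix would be wasteful.
#'
#' @param x Count matrix (samples x taxa).
#' @param pairs Two-column matrix of row indices or row names into `x`.
#' @inheritParams unweighted_unifrac
#' @return Numeric vector of distances, one per row of `pairs`.
#' @export
unifrac_pairs <- function(x, pairs, tree, min_count = 1) {
  x <- as.matrix(x)
  check_tips(colnames(x), tree)
  inc <- edge_tip_incidence(tree)
  pres <- t(x >= min_count)
  pres <- pres[colnames(inc), , drop = FALSE]
  obs <- (inc %*% pres) > 0
  len <- tree$edge.length
  if (is.character(pairs)) pairs <- matrix(match(pairs, rownames(x)), ncol = 2)
  i <- if (is.character(pairs[, 1])) match(pairs[, 1], rownames(x)) else pairs[, 1]
  j <- if (is.character(pairs[, 2])) match(pairs[, 2], rownames(x)) else pairs[, 2]
  oi <- obs[, i, drop = FALSE]
  oj <- obs[, j, drop = FALSE]
  uniq <- colSums((oi != oj) * len)
  either <- colSums((oi | oj) * len)
  if (any(either == 0)) stop("unifrac_pairs: empty sample pair")
  unname(uniq / either)
}

#' Pielou evenness of a community
#'
#' \eqn{J = H / \ln S} where \eqn{H} is Shannon entropy (natural log) over
#' non-zero proportions and \eqn{S} the observed richness. A single-taxon
#' community is maximally uneven and returns 0 by convention.
#'
#' @param u Non-negative abundance vector with at least one non-zero entry.
#' @return Evenness in `[0, 1]`.
#' @examples
#' pielou_evenness(c(3, 1)) # about 0.811
#' @export
pielou_evenness <- function(u) {
  if (any(u < 0)) stop("pielou_evenness: negative abundances")
  u <- u[u > 0]
  if (length(u) == 0) stop("pielou_evenness: all-zero vector")
  s <- length(u)
  if (s == 1L) return(0)
  p <- u / sum(u)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Aggregate a count table to a coarser taxonomic level
#'
#' @param counts Count matrix, samples in rows, taxa in columns.
#' @param mapping Named character vector mapping taxon id to group label.
#'   Taxa missing from the mapping are assigned to `"Other"`.
#' @param relative Return per-sample proportions instead of counts.
#' @param collapse_below Groups whose overall mean relative abundance is
#'   below this fraction are pooled into `"others"` (e.g. `0.01` reproduces
#'   the common "families below 1%" presentation); `NULL` disables pooling.
#' @return Matrix, samples x groups.
#' @export
aggregate_taxa <- function(counts, mapping, relative = FALSE,
                           collapse_below = NULL) {
  counts <- as.matrix(counts)
  if (length(mapping) == 0) stop("aggregate_taxa: empty mapping")
  groups <- mapping[colnames(counts)]
  groups[is.na(groups)] <- "Other"
  agg <- t(rowsum(t(counts), group = groups))
  if (!is.null(collapse_below)) {
    prop <- agg / rowSums(agg)
    minor <- colMeans(prop) < collapse_below
    if (any(minor)) {
      kept <- agg[, !minor, drop = FALSE]
      agg <- cbind(kept, others = rowSums(agg[, minor, drop = FALSE]))
    }
  }
  if (relative) agg <- agg / rowSums(agg)
  agg
}
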