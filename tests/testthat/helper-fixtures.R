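# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package implementation.

# Four-tip balanced tree used in worked examples: ((A:1,B:1):1,(C:1,D:1):1);
balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# Brute-force unweighted UniFrac: build each tip's root-to-tip edge path by
# walking parent pointers, take unions over each sample's present tips, and
# compare edge sets directly.
oracle_unifrac <- function(present_u, present_v, tree) {
  root <- length(tree$tip.label) + 1L
  path_edges <- function(tip) {
    node <- match(tip, tree$tip.label)
    edges <- integer(0)
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  edges_u <- unique(unlist(lapply(present_u, path_edges)))
  edges_v <- unique(unlist(lapply(present_v, path_edges)))
  uniq <- union(setdiff(edges_u, edges_v), setdiff(edges_v, edges_u))
  obs <- union(edges_u, edges_v)
  sum(tree$edge.length[uniq]) / sum(tree$edge.length[obs])
}

# Textbook one-way ANOVA + Tukey computed from first principles (sums of
# squares and the studentized range distribution), independent of aov().
oracle_anova_tukey <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  means <- tapply(values, g, mean)
  sizes <- tapply(values, g, length)
  grand <- mean(values)
  ss_b <- sum(sizes * (means - grand)^2)
  ss_w <- sum((values - means[as.character(g)])^2)
  f <- (ss_b / (k - 1)) / (ss_w / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  mse <- ss_w / (n - k)
  pairs <- utils::combn(levels(g), 2)
  p_tukey <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    stats::ptukey(q, k, n - k, lower.tail = FALSE)
  })
  list(f = f, p = p,
       tukey = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          p_adj = p_tukey))
}

# Small default-design study used by several integration tests.
small_study <- function(seed = 11, sensitive = c(TRUE, FALSE)) {
  prof <- random_donor_profiles(length(sensitive), sensitive = sensitive,
                                n_taxa = 16, seed = seed)
  cfg <- mbra_config(sampling_times_h = c(0, 72, 96, 120),
                     sequencing_depth = 5000)
  make_study(prof, cfg, seed = seed)
}
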