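test_that("PERMANOVA pseudo-F matches the established implementation", {
  set.seed(3)
  x <- matrix(rgamma(80, 2), 16, 5)
  groups <- rep(c("a", "b"), each = 8)
  d <- bray_curtis_matrix(x, normalize = FALSE)
  res <- permanova(d, groups, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(res$value, ref$F[1], tolerance = 1e-10)
  expect_equal(res$df, c(1, 14))
})

test_that("maximally separated groups reach the minimal permutation p", {
  # two tight clusters at distance 1, zero within
  d <- matrix(1, 8, 8)
  d[1:4, 1:4] <- 0
  d[5:8, 5:8] <- 0
  diag(d) <- 0
  res <- permanova(d, rep(c("a", "b"), each = 4), n_perm = 999, seed = 2)
  # only relabelings reproducing the two clusters tie the observed F
  # (2 of the 70 possible splits), so p concentrates near 2/70
  expect_gte(res$p_value, 1 / (999 + 1))
  expect_lte(res$p_value, 0.05)
})

test_that("PERMANOVA is invariant to joint reordering and seeded", {
  set.seed(9)
  x <- matrix(rgamma(60, 2), 12, 5)
  groups <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis_matrix(x, normalize = FALSE)
  ord <- sample(12)
  r1 <- permanova(d, groups, n_perm = 199, seed = 7)
  r2 <- permanova(d[ord, ord], groups[ord], n_perm = 199, seed = 7)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  r3 <- permanova(d, groups, n_perm = 199, seed = 7)
  expect_identical(r1$p_value, r3$p_value)
  expect_error(permanova(d, c(rep("a", 11), "b")), "size 1")
})

test_that("one-way ANOVA + Tukey matches a first-principles oracle", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    sizes <- sample(3:7, k, replace = TRUE)
    values <- rnorm(sum(sizes))
    groups <- rep(letters[1:k], sizes)
    res <- anova_tukey(values, groups)
    ref <- oracle_anova_tukey(values, groups)
    expect_equal(res$f, ref$f, tolerance = 1e-6)
    expect_equal(res$p_value, ref$p, tolerance = 1e-6)
    key_res <- paste(pmin(res$tukey$group1, res$tukey$group2),
                     pmax(res$tukey$group1, res$tukey$group2))
    key_ref <- paste(pmin(ref$tukey$group1, ref$tukey$group2),
                     pmax(ref$tukey$group1, ref$tukey$group2))
    expect_equal(res$tukey$p_adj[order(key_res)],
                 ref$tukey$p_adj[order(key_ref)], tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("near-degenerate groups separate cleanly", {
  values <- c(0, 0, 0, 10, 10, 10, 0, 0, 0.01)
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_tukey(values, groups)
  ref <- oracle_anova_tukey(values, groups)
  expect_equal(res$f, ref$f, tolerance = 1e-6)
  expect_equal(res$tukey$p_adj, ref$tukey$p_adj, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("degenerate variance cases follow the documented conventions", {
  same <- anova_tukey(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$f, 0)
  expect_equal(same$tukey$p_adj, 1)
  expect_warning(
    sep <- anova_tukey(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
    "unequal means")
  expect_equal(sep$tukey$p_adj, 0)
})

test_that("with two groups Tukey reduces to the ANOVA p-value", {
  set.seed(17)
  values <- rnorm(12)
  groups <- rep(c("a", "b"), each = 6)
  res <- anova_tukey(values, groups)
  expect_lt(abs(res$tukey$p_adj - res$p_value), 1e-9)
})

test_that("per-timepoint two-way testing flags only real deviations", {
  meta <- expand.grid(chamber = 1:3, treatment = c("cellulose", "inulin"),
                      timepoint_h = c(96, 120, 144), donor = "D1",
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s.c%d.t%g", meta$treatment, meta$chamber,
                            meta$timepoint_h)
  # identical arms: nothing flagged
  set.seed(19)
  base <- rnorm(nrow(meta), 1, 0.01)
  null_ts <- timeseries_table(meta$sample_id, "bacterial_load", base)
  null_ts$value[meta$treatment == "inulin"] <-
    null_ts$value[meta$treatment == "cellulose"]
  res0 <- timeseries_test(null_ts, meta)
  expect_false(any(res0$flag <- res0$contrasts$flag))
  # planted step in the treated arm is flagged at every timepoint
  step <- base
  step[meta$treatment == "inulin"] <- step[meta$treatment == "inulin"] + 5
  res1 <- timeseries_test(timeseries_table(meta$sample_id, "bacterial_load",
                                           step), meta)
  expect_true(all(res1$contrasts$flag))
  # Bonferroni arithmetic: m contrasts multiply the raw p
  expect_equal(res1$contrasts$p_bonferroni,
               pmin(1, res1$m * res1$contrasts$p_raw))
  expect_equal(res1$m, 3)
})

test_that("two-way testing rejects designs with empty cells", {
  meta <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    donor = "D1", treatment = c("cellulose", "cellulose", "inulin", "inulin"),
    chamber = c(1, 2, 1, 2), timepoint_h = c(96, 96, 120, 120)
  )
  ts <- timeseries_table(meta$sample_id, "lps", 1:4)
  expect_error(timeseries_test(ts, meta), "empty cell")
})
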