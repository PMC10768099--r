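test_that("retention time and dilution rate follow the protocol constants", {
  cfg <- mbra_config()
  rt <- retention_time(cfg)
  expect_equal(as.numeric(rt), 8)
  expect_equal(attr(rt, "dilution_rate"), 0.125)
  expect_equal(as.numeric(retention_time(mbra_config(volume_ml = 3,
                                                     flow_ml_per_h = 3))), 1)
  expect_error(retention_time(mbra_config(flow_ml_per_h = 0)))
})

test_that("zero growth gives exponential washout matching the closed form", {
  n <- 5
  prof <- donor_profile("D1", paste0("t", 1:n), rep(1 / n, n), rep(0, n))
  cfg <- mbra_config(equilibration_h = 0, sampling_times_h = c(0, 8, 16),
                     end_h = 16, stabilization_end_h = 8, jitter_sdlog = 0)
  traj <- simulate_chamber(prof, "cellulose", cfg, jitter = FALSE)
  ratio <- traj["8", ] / traj["0", ]
  expect_equal(unname(ratio), rep(exp(-1), n), tolerance = 0.01)
  expect_equal(unname(traj["16", 1] / traj["0", 1]), exp(-2), tolerance = 0.02)
})

test_that("without dilution a single taxon plateaus at carrying capacity", {
  prof <- donor_profile("D1", "t1", 1, 0.3)
  cfg <- mbra_config(equilibration_h = 240, sampling_times_h = c(0, 240),
                     end_h = 240)
  traj <- simulate_chamber(prof, "cellulose", cfg, jitter = FALSE)
  expect_equal(unname(traj["240", 1]), cfg$carrying_capacity,
               tolerance = 1e-3)
})

test_that("a resistant donor's arms are generatively identical", {
  prof <- random_donor_profiles(1, sensitive = FALSE, n_taxa = 10, seed = 9)[[1]]
  cfg <- mbra_config(sampling_times_h = c(0, 72, 120), end_h = 120)
  a <- simulate_chamber(prof, "cellulose", cfg, seed = 5)
  b <- simulate_chamber(prof, "inulin", cfg, seed = 5)
  expect_identical(a, b)
})

test_that("taxon order carries no hidden positional dependence", {
  prof <- random_donor_profiles(1, sensitive = TRUE, n_taxa = 8, seed = 21)[[1]]
  cfg <- mbra_config(sampling_times_h = c(0, 72, 120), end_h = 120)
  perm <- sample(8)
  prof_p <- donor_profile("D1", prof$taxon_ids[perm],
                          prof$baseline_props[perm], prof$growth_rates[perm],
                          prof$inulin_effects[perm],
                          prof$psyllium_effects[perm],
                          prof$sensitivity_delta, prof$gram_negative[perm],
                          prof$flagellated[perm], prof$lps_yield[perm],
                          prof$fla_yield[perm])
  a <- simulate_chamber(prof, "inulin", cfg, jitter = FALSE)
  b <- simulate_chamber(prof_p, "inulin", cfg, jitter = FALSE)
  expect_equal(b, a[, prof_p$taxon_ids], tolerance = 1e-12)
  expect_equal(simulate_mamp(b, prof_p), simulate_mamp(a, prof),
               tolerance = 1e-12)
})

test_that("Dirichlet-multinomial sampling is calibrated and deterministic", {
  latent <- c(t1 = 500, t2 = 300, t3 = 150, t4 = 50)
  p <- latent / sum(latent)
  depth <- 2000
  # near-multinomial limit
  set.seed(1)
  big_theta <- sample_counts(matrix(latent, 1, dimnames = list("s", names(latent))),
                             depth, theta = 1e9)
  se <- sqrt(p * (1 - p) * depth)
  expect_true(all(abs(big_theta - depth * p) < 5 * se))
  # determinism
  c1 <- sample_counts(latent, depth, 200, seed = 33)
  c2 <- sample_counts(latent, depth, 200, seed = 33)
  expect_identical(c1, c2)
  # Monte-Carlo mean of replicate draws matches the latent proportions
  set.seed(8)
  reps <- sample_counts(matrix(rep(latent, 1000), 1000, 4, byrow = TRUE,
                               dimnames = list(NULL, names(latent))),
                        depth, theta = 200)
  props <- reps / depth
  se_mc <- apply(props, 2, sd) / sqrt(1000)
  expect_true(all(abs(colMeans(props) - p) < 3 * se_mc + 1e-4))
  expect_error(sample_counts(c(0, 0, 0), depth, 200), "all-zero")
})

test_that("load observation noise follows the configured CV", {
  totals <- rep(1e8, 1000)
  expect_equal(simulate_load(totals, cv = 0), totals)
  set.seed(12)
  obs <- simulate_load(totals, cv = 0.2)
  cv_hat <- sd(obs) / mean(obs)
  expect_gt(cv_hat, 0.17)
  expect_lt(cv_hat, 0.23)
  # noise-free observation preserves monotone growth
  grow <- seq(1e6, 1e8, length.out = 20)
  expect_true(all(diff(simulate_load(grow, 0)) > 0))
})

test_that("MAMP production is the yield-weighted sum over flagged taxa", {
  prof <- donor_profile("D1", c("gn", "fl"), c(0.5, 0.5), c(0.3, 0.3),
                        gram_negative = c(TRUE, FALSE),
                        flagellated = c(FALSE, TRUE),
                        lps_yield = c(2e-6, 0), fla_yield = c(0, 3e-6))
  traj <- matrix(c(1e8, 5e7), 1, dimnames = list("s", c("gn", "fl")))
  mm <- simulate_mamp(traj, prof)
  expect_equal(mm$lps, 2e-6 * 1e8)
  expect_equal(mm$flagellin, 3e-6 * 5e7)
  expect_equal(simulate_mamp(traj * 2, prof)$lps, 2 * mm$lps)
  no_fla <- donor_profile("D1", c("a", "b"), c(0.5, 0.5), c(0.3, 0.3),
                          gram_negative = c(TRUE, TRUE),
                          lps_yield = c(1e-6, 1e-6))
  expect_equal(simulate_mamp(traj, no_fla)$flagellin, 0)
})

test_that("a full study reproduces the published design shape", {
  prof <- random_donor_profiles(6, sensitive = FALSE, n_taxa = 10, seed = 2)
  cfg <- mbra_config(sampling_times_h = c(0, 72, 120), end_h = 120)
  st <- make_study(prof, cfg, seed = 2)
  chambers <- unique(st$meta[, c("donor", "treatment", "chamber")])
  expect_equal(nrow(chambers), 6 * 3 * 3) # nine chambers per donor
  expect_equal(nrow(st$meta), 54 * 3)
  expect_setequal(unique(st$meta$treatment),
                  c("cellulose", "inulin", "psyllium"))
  expect_setequal(st$tree$tip.label, colnames(st$counts))
  expect_true(ape::is.rooted(st$tree))
  # truth lists exactly the planted sensitive donors
  expect_equal(st$truth$sensitive, st$truth$sensitivity_delta > 0)
})

test_that("a minimal study counts samples correctly and is deterministic", {
  prof <- random_donor_profiles(1, n_taxa = 6, seed = 14)
  cfg <- mbra_config(sampling_times_h = c(72, 120), end_h = 120,
                     n_replicate_chambers = 1)
  st <- make_study(prof, cfg, seed = 14)
  expect_equal(nrow(st$meta), 3 * 2) # 3 treatments x 2 timepoints
  st2 <- make_study(prof, cfg, seed = 14)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$loads, st2$loads)
  expect_identical(ape::write.tree(st$tree), ape::write.tree(st2$tree))
  expect_error(make_study(c(prof, prof), cfg, seed = 1), "duplicate donor")
})

test_that("study files round-trip through the run directory", {
  st <- small_study(seed = 6, sensitive = FALSE)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_identical(read_count_table(file.path(dir, "counts.tsv")), st$counts)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(meta$sample_id, st$meta$sample_id)
  loads <- read_tsv(file.path(dir, "loads.tsv"), required = c("sample_id", "load"))
  expect_equal(loads$load, st$loads$load, tolerance = 1e-12)
  tree <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tree$tip.label, st$tree$tip.label)
})

test_that("the antibiotic disturbance arm kills a taxon subset at 72 h", {
  prof <- random_donor_profiles(1, n_taxa = 12, seed = 61)
  cfg <- mbra_config(sampling_times_h = c(0, 72, 96, 120), end_h = 120,
                     jitter_sdlog = 0, load_noise_cv = 0)
  st <- make_study(prof, cfg, seed = 61,
                   treatments = c("cellulose", "antibiotic"))
  expect_setequal(unique(st$meta$treatment), c("cellulose", "antibiotic"))
  lat <- st$latent
  md <- st$meta
  tot <- rowSums(lat)
  # disturbance depresses total abundance right after the kill
  abx96 <- tot[md$treatment == "antibiotic" & md$timepoint_h == 96]
  cel96 <- tot[md$treatment == "cellulose" & md$timepoint_h == 96]
  expect_lt(mean(abx96), mean(cel96))
  # identical before treatment (no jitter)
  expect_equal(tot[md$treatment == "antibiotic" & md$timepoint_h == 72],
               tot[md$treatment == "cellulose" & md$timepoint_h == 72],
               tolerance = 1e-10, ignore_attr = TRUE)
  # composition is disturbed, not just scaled
  bc <- beta_evolution(st$counts, st$meta, "bray_curtis", relative = FALSE)
  bmd <- st$meta[match(bc$sample_id, st$meta$sample_id), ]
  expect_gt(mean(bc$value[bmd$treatment == "antibiotic" &
                            bmd$timepoint_h == 96]),
            mean(bc$value[bmd$treatment == "cellulose" &
                            bmd$timepoint_h == 96]))
})
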