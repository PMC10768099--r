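#' Generative profile of a fecal donor's microbiota
#'
#' Bundles the donor-specific parameters the study simulator draws on: the
#' equilibrium community handed to the bioreactor, per-taxon growth rates,
#' multiplicative growth modifiers under each soluble fiber, and per-taxon
#' MAMP yields. A fiber-resistant donor has `sensitivity_delta = 0` and all
#' fiber effects equal to 1; a sensitive donor has some taxa whose growth is
#' boosted under inulin and/or psyllium.
#'
#' @param donor_id Identifier, e.g. `"D1"`.
#' @param taxon_ids Taxon identifiers (shared across donors of a study).
#' @param baseline_props Relative abundances at inoculation; must sum to 1.
#' @param growth_rates Intrinsic growth rates, per hour.
#' @param inulin_effects,psyllium_effects Multiplicative growth modifiers
#'   applied during the treatment window (1 = no response); strictly > 0.
#' @param sensitivity_delta Scalar effect-size summary; 0 means resistant
#'   and then all fiber effects must be 1.
#' @param gram_negative,flagellated Per-taxon logical flags controlling
#'   which taxa shed LPS and flagellin.
#' @param lps_yield,fla_yield MAMP produced per unit abundance
#'   (standard-equivalent units per cell).
#' @return A validated list of class `"donor_profile"`.
#' @export
donor_profile <- function(donor_id, taxon_ids, baseline_props, growth_rates,
                          inulin_effects = rep(1, length(taxon_ids)),
                          psyllium_effects = rep(1, length(taxon_ids)),
                          sensitivity_delta = 0,
                          gram_negative = rep(FALSE, length(taxon_ids)),
                          flagellated = rep(FALSE, length(taxon_ids)),
                          lps_yield = rep(0, length(taxon_ids)),
                          fla_yield = rep(0, length(taxon_ids))) {
  n <- length(taxon_ids)
  lens <- vapply(list(baseline_props, growth_rates, inulin_effects,
                      psyllium_effects, gram_negative, flagellated,
                      lps_yield, fla_yield), length, integer(1))
  if (any(lens != n)) stop("donor_profile: per-taxon fields must match taxon_ids")
  if (any(baseline_props < 0)) stop("donor_profile: negative baseline proportions")
  if (abs(sum(baseline_props) - 1) > 1e-8) {
    stop("donor_profile: baseline_props must sum to 1")
  }
  if (any(inulin_effects <= 0) || any(psyllium_effects <= 0)) {
    stop("donor_profile: fiber effects must be > 0")
  }
  if (sensitivity_delta < 0) stop("donor_profile: sensitivity_delta must be >= 0")
  if (sensitivity_delta == 0 &&
      (any(inulin_effects != 1) || any(psyllium_effects != 1))) {
    stop("donor_profile: sensitivity_delta = 0 requires all fiber effects = 1")
  }
  if (any(lps_yield < 0) || any(fla_yield < 0)) {
    stop("donor_profile: MAMP yields must be >= 0")
  }
  structure(
    list(donor_id = as.character(donor_id), taxon_ids = as.character(taxon_ids),
         baseline_props = as.numeric(baseline_props),
         growth_rates = as.numeric(growth_rates),
         inulin_effects = as.numeric(inulin_effects),
         psyllium_effects = as.numeric(psyllium_effects),
         sensitivity_delta = sensitivity_delta,
         gram_negative = as.logical(gram_negative),
         flagellated = as.logical(flagellated),
         lps_yield = as.numeric(lps_yield), fla_yield = as.numeric(fla_yield)),
    class = "donor_profile"
  )
}

#' Draw a set of random donor profiles over a shared taxon universe
#'
#' Taxon membership flags (gram-negative, flagellated) are drawn once and
#' shared by all donors, as they are properties of the taxa; compositions,
#' growth rates, MAMP yields and fiber responses are donor-specific.
#' Sensitive donors get `1 + delta` growth modifiers on a random subset of
#' taxa, drawn independently for inulin and psyllium.
#'
#' @param n_donors Number of donors.
#' @param sensitive Logical vector (length `n_donors` or recycled): which
#'   donors carry a planted fiber response.
#' @param n_taxa Taxa in the shared universe.
#' @param delta Planted effect size for sensitive donors; the default 3
#'   makes responding taxa grow 4x faster under fiber.
#' @param responder_frac Fraction of taxa responding in a sensitive donor.
#' @param mu_range Range of intrinsic growth rates (per hour); kept above
#'   the 0.125/h dilution rate so no taxon washes out of the control arms.
#' @param seed Optional RNG seed.
#' @return List of [donor_profile()] objects named by donor id.
#' @export
random_donor_profiles <- function(n_donors, sensitive = FALSE, n_taxa = 24,
                                  delta = 3, responder_frac = 0.3,
                                  mu_range = c(0.25, 0.40), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sensitive <- rep_len(sensitive, n_donors)
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  gram_neg <- stats::runif(n_taxa) < 0.5
  flag <- stats::runif(n_taxa) < 0.3
  # every study needs at least two LPS and two flagellin producers
  if (sum(gram_neg) < 2) gram_neg[sample.int(n_taxa, 2)] <- TRUE
  if (sum(flag) < 2) flag[sample.int(n_taxa, 2)] <- TRUE
  profiles <- vector("list", n_donors)
  for (d in seq_len(n_donors)) {
    # uneven rank-abundance: a few dominant taxa plus a tail of rare ones
    # whose presence flickers around the sequencing detection limit, as in
    # real 16S data (this is what makes unweighted UniFrac informative)
    props <- as.numeric(rdirichlet_one(rep(0.3, n_taxa)))
    mu <- stats::runif(n_taxa, mu_range[1], mu_range[2])
    inu <- rep(1, n_taxa)
    psy <- rep(1, n_taxa)
    dlt <- 0
    if (sensitive[d]) {
      dlt <- delta
      n_resp <- max(1L, round(responder_frac * n_taxa))
      inu[sample.int(n_taxa, n_resp)] <- 1 + delta
      psy[sample.int(n_taxa, n_resp)] <- 1 + delta
    }
    lps_y <- ifelse(gram_neg, stats::rlnorm(n_taxa, log(2e-5), 0.5), 0)
    fla_y <- ifelse(flag, stats::rlnorm(n_taxa, log(1.5e-5), 0.5), 0)
    profiles[[d]] <- donor_profile(
      donor_id = sprintf("D%d", d), taxon_ids = taxa,
      baseline_props = props, growth_rates = mu,
      inulin_effects = inu, psyllium_effects = psy,
      sensitivity_delta = dlt, gram_negative = gram_neg,
      flagellated = flag, lps_yield = lps_y, fla_yield = fla_y
    )
  }
  names(profiles) <- vapply(profiles, `[[`, character(1), "donor_id")
  profiles
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Effective growth modifier at a given fiber concentration: the log effect
# scales linearly in concentration, anchored at the protocol's 0.02%.
effective_fiber_effect <- function(effect, fiber_conc_pct,
                                   anchor_pct = 0.02) {
  exp(log(effect) * fiber_conc_pct / anchor_pct)
}

#' Integrate a batch of chambers through the chemostat model
#'
#' Community dynamics follow logistic growth with dilution:
#' \deqn{dx_i/dt = x_i [\mu_i g_i(t) (1 - X/K) - D(t)]}
#' with \eqn{X = \sum_i x_i}, carrying capacity \eqn{K}, dilution rate
#' \eqn{D = } flow/volume (zero during the static equilibration window),
#' and \eqn{g_i(t)} the fiber growth modifier, equal to 1 before treatment
#' starts and in the control arm. Integration is explicit Euler with step
#' `cfg$dt_h` and non-negativity clamping.
#'
#' @param x0 Matrix taxa x chambers of initial absolute abundances.
#' @param mu Matrix (or vector recycled) of growth rates, taxa x chambers.
#' @param g_treat Matrix of growth modifiers applied from
#'   `cfg$stabilization_end_h` on, taxa x chambers (1 for control columns).
#' @param cfg An [mbra_config()].
#' @param kill Optional matrix of survival fractions applied once when the
#'   treatment window opens (antibiotic disturbance arm); 1 elsewhere.
#' @return 3D array taxa x chambers x sampling times (dimnames on time).
#' @keywords internal
integrate_chambers <- function(x0, mu, g_treat, cfg, kill = NULL) {
  x <- as.matrix(x0)
  n_taxa <- nrow(x)
  m <- ncol(x)
  mu <- matrix(mu, n_taxa, m)
  g_treat <- matrix(g_treat, n_taxa, m)
  dt <- cfg$dt_h
  k_cap <- cfg$carrying_capacity
  d_rate <- dilution_rate(cfg)
  times <- cfg$sampling_times_h
  n_steps <- round(cfg$end_h / dt)
  snap_step <- round(times / dt)
  if (any(abs(snap_step * dt - times) > 1e-9)) {
    stop("integrate_chambers: sampling times must be multiples of dt_h")
  }
  out <- array(NA_real_, dim = c(n_taxa, m, length(times)),
               dimnames = list(rownames(x), colnames(x), times))
  mu_treat <- mu * g_treat
  treat_step <- round(cfg$stabilization_end_h / dt)
  eq_step <- round(cfg$equilibration_h / dt)
  hit <- match(0L, snap_step)
  if (!is.na(hit)) out[, , hit] <- x
  killed <- is.null(kill)
  for (step in seq_len(n_steps)) {
    if (!killed && step > treat_step) {
      x <- x * kill
      killed <- TRUE
    }
    mu_eff <- if (step > treat_step) mu_treat else mu
    d_eff <- if (step > eq_step) d_rate else 0
    s <- 1 - colSums(x) / k_cap
    x <- x + dt * x * (mu_eff * rep(s, each = n_taxa) - d_eff)
    x[x < 0] <- 0
    hit <- match(step, snap_step)
    if (!is.na(hit)) {
      if (any(x > 1e12 * k_cap)) {
        stop("integrate_chambers: trajectory exploded (x > 1e12 K)")
      }
      out[, , hit] <- x
    }
  }
  out
}

#' Simulate the latent trajectory of one chamber
#'
#' @param profile A [donor_profile()].
#' @param treatment One of `"cellulose"`, `"inulin"`, `"psyllium"`.
#' @param cfg An [mbra_config()].
#' @param seed Optional RNG seed (affects the initial-composition jitter).
#' @param jitter Apply per-chamber lognormal jitter to the initial
#'   composition (the replicate-variation mechanism); `FALSE` gives the
#'   deterministic trajectory.
#' @return Matrix sampling times x taxa of absolute abundances.
#' @export
simulate_chamber <- function(profile, treatment, cfg, seed = NULL,
                             jitter = TRUE) {
  treatment <- match.arg(treatment, c("cellulose", "inulin", "psyllium"))
  if (!is.null(seed)) set.seed(seed)
  x0 <- chamber_initial(profile, cfg, jitter)
  g <- chamber_modifier(profile, treatment, cfg)
  snaps <- integrate_chambers(matrix(x0, ncol = 1),
                              profile$growth_rates, g, cfg)
  traj <- t(matrix(snaps[, 1, ], nrow = dim(snaps)[1]))
  dimnames(traj) <- list(cfg$sampling_times_h, profile$taxon_ids)
  traj
}

chamber_initial <- function(profile, cfg, jitter) {
  props <- profile$baseline_props
  if (jitter) {
    props <- props * stats::rlnorm(length(props), 0, cfg$jitter_sdlog)
    props <- props / sum(props)
  }
  props * cfg$init_frac * cfg$carrying_capacity
}

chamber_modifier <- function(profile, treatment, cfg) {
  base <- switch(treatment,
                 cellulose = rep(1, length(profile$taxon_ids)),
                 inulin = profile$inulin_effects,
                 psyllium = profile$psyllium_effects)
  effective_fiber_effect(base, cfg$fiber_conc_pct)
}

#' Dirichlet-multinomial sequencing of latent abundances
#'
#' Each sample's taxon proportions are perturbed by a Dirichlet draw with
#' concentration `theta` (library-preparation overdispersion), then `depth`
#' reads are drawn multinomially.
#'
#' @param traj Matrix samples x taxa of latent abundances (or a single
#'   vector).
#' @param depth Reads per sample.
#' @param theta Dirichlet concentration; large values approach a pure
#'   multinomial.
#' @param seed Optional RNG seed.
#' @return Integer count matrix, samples x taxa.
#' @export
sample_counts <- function(traj, depth, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1)
  counts <- matrix(0L, nrow(traj), ncol(traj), dimnames = dimnames(traj))
  for (i in seq_len(nrow(traj))) {
    tot <- sum(traj[i, ])
    if (tot == 0) stop("sample_counts: all-zero latent sample (row ", i, ")")
    p <- rdirichlet_one(theta * traj[i, ] / tot)
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, p))
  }
  counts
}

#' qPCR-style bacterial load observation
#'
#' Observed load is the latent total abundance times multiplicative
#' lognormal noise with mean 1 and the configured coefficient of variation.
#'
#' @param totals Latent total abundances (numeric vector).
#' @param cv Coefficient of variation of the noise (`0` = noise-free).
#' @param seed Optional RNG seed.
#' @return Numeric vector of observed loads.
#' @export
simulate_load <- function(totals, cv, seed = NULL) {
  if (cv < 0) stop("simulate_load: cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (cv == 0) return(as.numeric(totals))
  sdlog <- sqrt(log(1 + cv^2))
  totals * stats::rlnorm(length(totals), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' True MAMP concentrations implied by a latent community
#'
#' Bioactive LPS is the yield-weighted sum over gram-negative taxa;
#' flagellin the yield-weighted sum over flagellated taxa. Linear in
#' abundance by construction.
#'
#' @param traj Matrix samples x taxa of latent abundances.
#' @param profile The [donor_profile()] supplying flags and yields.
#' @return Data frame with columns `lps` and `flagellin`, one row per
#'   sample.
#' @export
simulate_mamp <- function(traj, profile) {
  if (is.null(dim(traj))) traj <- matrix(traj, nrow = 1)
  w_lps <- profile$lps_yield * profile$gram_negative
  w_fla <- profile$fla_yield * profile$flagellated
  data.frame(lps = as.numeric(traj %*% w_lps),
             flagellin = as.numeric(traj %*% w_fla),
             row.names = rownames(traj))
}

#' Simulate a complete MBRA study
#'
#' Emulates the published design: each donor is cultured under cellulose
#' (control), inulin, and psyllium in `cfg$n_replicate_chambers` replicate
#' chambers, sampled on `cfg$sampling_times_h` from inoculation (0 h) to the
#' end of the run, with fiber delivered from `cfg$stabilization_end_h`.
#' Returns 16S-like counts, metadata, qPCR loads, true and assay-read MAMP
#' levels, a random rooted phylogeny over the taxa, and the planted truth.
#'
#' @param profiles List of [donor_profile()]s sharing one taxon universe.
#' @param cfg An [mbra_config()].
#' @param seed RNG seed; with the config it fully determines every output.
#' @param treatments Treatment arms to simulate. Besides the fiber arms, an
#'   `"antibiotic"` disturbance arm (positive control) is available: when
#'   its feed opens at `stabilization_end_h`, a random half of the donor's
#'   taxa suffer a uniform 90% kill. Off by default.
#' @return An object of class `"mbra_study"`: list with elements `counts`,
#'   `meta`, `loads`, `mamp_true`, `assay`, `standards`, `tree`, `truth`,
#'   `latent`, `profiles`, `config`, `seed`.
#' @export
make_study <- function(profiles, cfg = mbra_config(), seed = 1,
                       treatments = c("cellulose", "inulin", "psyllium")) {
  treatments <- match.arg(treatments, treatment_levels, several.ok = TRUE)
  if (length(profiles) == 0) stop("make_study: need at least one donor")
  if (inherits(profiles, "donor_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, `[[`, character(1), "donor_id")
  if (anyDuplicated(ids)) stop("make_study: duplicate donor ids")
  names(profiles) <- ids
  taxa <- profiles[[1]]$taxon_ids
  for (p in profiles) {
    if (!identical(p$taxon_ids, taxa)) {
      stop("make_study: all donors must share one taxon universe")
    }
  }
  set.seed(seed)
  tree <- ape::rtree(length(taxa), tip.label = taxa, br = stats::rexp, rate = 4)

  n_ch <- cfg$n_replicate_chambers
  grid <- expand.grid(chamber = seq_len(n_ch), treatment = treatments,
                      donor = ids, stringsAsFactors = FALSE)
  grid <- grid[, c("donor", "treatment", "chamber")]
  m <- nrow(grid)
  n_taxa <- length(taxa)
  x0 <- matrix(0, n_taxa, m)
  mu <- matrix(0, n_taxa, m)
  g <- matrix(1, n_taxa, m)
  kill <- matrix(1, n_taxa, m)
  abx_target <- lapply(stats::setNames(ids, ids), function(d) {
    if ("antibiotic" %in% treatments) {
      sample.int(n_taxa, max(1L, n_taxa %/% 2L))
    } else {
      integer(0)
    }
  })
  for (j in seq_len(m)) {
    p <- profiles[[grid$donor[j]]]
    x0[, j] <- chamber_initial(p, cfg, jitter = TRUE)
    mu[, j] <- p$growth_rates
    if (grid$treatment[j] == "antibiotic") {
      kill[abx_target[[grid$donor[j]]], j] <- 0.1
    } else {
      g[, j] <- chamber_modifier(p, grid$treatment[j], cfg)
    }
  }
  chamber_ids <- sprintf("%s.%s.c%d", grid$donor, grid$treatment, grid$chamber)
  colnames(x0) <- chamber_ids
  snaps <- integrate_chambers(x0, mu, g, cfg,
                              kill = if ("antibiotic" %in% treatments)
                                kill else NULL)

  times <- cfg$sampling_times_h
  meta <- do.call(rbind, lapply(seq_along(times), function(ti) {
    data.frame(sample_id = sprintf("%s.t%g", chamber_ids, times[ti]),
               donor = grid$donor, treatment = grid$treatment,
               chamber = grid$chamber, timepoint_h = times[ti],
               stringsAsFactors = FALSE)
  }))
  latent <- t(do.call(cbind, lapply(seq_along(times), function(ti) {
    snaps[, , ti, drop = TRUE]
  })))
  if (n_taxa == 1) latent <- matrix(latent, ncol = 1)
  rownames(latent) <- meta$sample_id
  colnames(latent) <- taxa

  counts <- sample_counts(latent, cfg$sequencing_depth, cfg$theta)
  loads <- data.frame(sample_id = meta$sample_id,
                      load = simulate_load(rowSums(latent), cfg$load_noise_cv),
                      stringsAsFactors = FALSE)
  mamp_true <- do.call(rbind, lapply(ids, function(d) {
    rows <- meta$donor == d
    mm <- simulate_mamp(latent[rows, , drop = FALSE], profiles[[d]])
    data.frame(sample_id = meta$sample_id[rows], mm,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  assay <- simulate_assay(mamp_true, cfg)
  standards <- simulate_standards(cfg)
  truth <- data.frame(
    donor = ids,
    sensitivity_delta = vapply(profiles, `[[`, numeric(1), "sensitivity_delta"),
    sensitive = vapply(profiles, `[[`, numeric(1), "sensitivity_delta") > 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(counts = counts, meta = validate_metadata(meta), loads = loads,
         mamp_true = mamp_true, assay = assay, standards = standards,
         tree = tree, truth = truth, latent = latent, profiles = profiles,
         config = cfg, seed = seed),
    class = "mbra_study"
  )
}

simulate_assay <- function(mamp_true, cfg) {
  dil <- cfg$dilution_factors
  rows <- vector("list", 2L * nrow(mamp_true))
  k <- 0L
  for (an in c("lps", "flagellin")) {
    curve <- cfg$assay_curves[[an]]
    for (i in seq_len(nrow(mamp_true))) {
      conc <- mamp_true[[an]][i] / dil
      y <- fourpl(conc, curve) +
        stats::rnorm(length(dil), 0, cfg$absorbance_sd)
      k <- k + 1L
      rows[[k]] <- data.frame(sample_id = mamp_true$sample_id[i],
                              analyte = an, dilution_factor = dil,
                              absorbance = y, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulate_standards <- function(cfg) {
  out <- do.call(rbind, lapply(c("lps", "flagellin"), function(an) {
    curve <- cfg$assay_curves[[an]]
    data.frame(analyte = an, concentration = cfg$standard_concs,
               absorbance = fourpl(cfg$standard_concs, curve) +
                 stats::rnorm(length(cfg$standard_concs),
                              0, cfg$absorbance_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.mbra_study <- function(x, ...) {
  cat("MBRA study:", length(x$profiles), "donor(s),",
      length(unique(x$meta$treatment)), "treatment arm(s),",
      nrow(x$counts), "samples,", ncol(x$counts), "taxa\n")
  cat("  sampling:", paste(range(x$meta$timepoint_h), collapse = "-"),
      "h; treatment from", x$config$stabilization_end_h, "h; seed", x$seed, "\n")
  invisible(x)
}

#' Write all study files to a directory
#'
#' Emits `counts.tsv`, `metadata.tsv`, `loads.tsv`, `mamp_true.tsv`,
#' `assay_readouts.tsv`, `standards.tsv`, `tree.nwk`, `truth.tsv`, plus a
#' `run_log.tsv` recording the seed.
#'
#' @param study An [make_study()] result.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_table(study$counts, file.path(dir, "counts.tsv"))
  write_tsv(study$meta, file.path(dir, "metadata.tsv"))
  write_tsv(study$loads, file.path(dir, "loads.tsv"))
  write_tsv(study$mamp_true, file.path(dir, "mamp_true.tsv"))
  write_tsv(study$assay, file.path(dir, "assay_readouts.tsv"))
  write_tsv(study$standards, file.path(dir, "standards.tsv"))
  write_newick(study$tree, file.path(dir, "tree.nwk"))
  write_tsv(study$truth, file.path(dir, "truth.tsv"))
  write_tsv(data.frame(key = "seed", value = study$seed),
            file.path(dir, "run_log.tsv"))
  invisible(dir)
}
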