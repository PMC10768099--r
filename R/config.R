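#' MBRA chemostat and study configuration
#'
#' Captures the physical and observational parameters of a minibioreactor
#' array run. Defaults mirror the published MBRA protocol: 15 mL chambers
#' fed at 1.875 mL/h (8 h retention time), a 16 h static equilibration after
#' inoculation, 72 h of stabilization before fiber treatment, and a 240 h
#' endpoint, with fiber delivered at 0.02% (w/v) and three replicate
#' chambers per donor and treatment arm.
#'
#' @param volume_ml Chamber volume in mL.
#' @param flow_ml_per_h Medium flow in mL/h once flow starts.
#' @param equilibration_h Static (no-flow) period after inoculation, hours.
#' @param stabilization_end_h Hour at which fiber treatment begins.
#' @param end_h Final hour of the run.
#' @param sampling_times_h Sampling grid in hours.
#' @param fiber_conc_pct Fiber concentration (% w/v) in the treated feed;
#'   the planted log growth effect scales linearly in this value with the
#'   default 0.02% as the anchor.
#' @param n_replicate_chambers Replicate chambers per donor x treatment.
#' @param sequencing_depth Reads per sample for the 16S emulation.
#' @param theta Dirichlet-multinomial concentration (overdispersion;
#'   larger is closer to multinomial).
#' @param load_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on qPCR bacterial load.
#' @param dt_h Euler integration step, hours (must be <= 0.1).
#' @param carrying_capacity Community carrying capacity, arbitrary cells/mL.
#' @param init_frac Initial total abundance as a fraction of capacity.
#' @param jitter_sdlog Lognormal sd of per-chamber initial-composition
#'   jitter (replicate-to-replicate variation).
#' @param dilution_factors Assay dilution series applied to every sample.
#' @param absorbance_sd Additive Gaussian noise on simulated absorbances.
#' @param assay_curves Per-analyte true 4PL parameters used to generate
#'   reporter-cell readouts (named list of lists with `a`, `d`, `c`, `b`).
#' @param standard_concs Concentrations of the calibration standards.
#' @return A validated list of class `"mbra_config"`.
#' @export
mbra_config <- function(volume_ml = 15,
                        flow_ml_per_h = 1.875,
                        equilibration_h = 16,
                        stabilization_end_h = 72,
                        end_h = 240,
                        sampling_times_h = seq(0, 240, by = 24),
                        fiber_conc_pct = 0.02,
                        n_replicate_chambers = 3,
                        sequencing_depth = 10000,
                        theta = 200,
                        load_noise_cv = 0.1,
                        dt_h = 0.05,
                        carrying_capacity = 1e9,
                        init_frac = 0.05,
                        jitter_sdlog = 0.3,
                        dilution_factors = 10^(0:5),
                        absorbance_sd = 0.02,
                        assay_curves = list(
                          lps = list(a = 0.05, d = 2.0, c = 10, b = 1.2),
                          flagellin = list(a = 0.05, d = 1.8, c = 5, b = 1.1)
                        ),
                        standard_concs = c(0.1, 0.3, 1, 3, 10, 30, 100, 300)) {
  cfg <- list(volume_ml = volume_ml, flow_ml_per_h = flow_ml_per_h,
              equilibration_h = equilibration_h,
              stabilization_end_h = stabilization_end_h, end_h = end_h,
              sampling_times_h = sort(unique(sampling_times_h)),
              fiber_conc_pct = fiber_conc_pct,
              n_replicate_chambers = n_replicate_chambers,
              sequencing_depth = sequencing_depth, theta = theta,
              load_noise_cv = load_noise_cv, dt_h = dt_h,
              carrying_capacity = carrying_capacity, init_frac = init_frac,
              jitter_sdlog = jitter_sdlog,
              dilution_factors = sort(dilution_factors),
              absorbance_sd = absorbance_sd, assay_curves = assay_curves,
              standard_concs = standard_concs)
  validate_mbra_config(cfg)
}

validate_mbra_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$volume_ml <= 0) stop("mbra_config: volume_ml must be > 0")
  if (cfg$flow_ml_per_h <= 0) stop("mbra_config: flow_ml_per_h must be > 0")
  if (cfg$dt_h <= 0 || cfg$dt_h > 0.1) {
    stop("mbra_config: dt_h must be in (0, 0.1]")
  }
  if (cfg$stabilization_end_h >= cfg$end_h) {
    stop("mbra_config: stabilization_end_h must be before end_h")
  }
  if (any(cfg$sampling_times_h < 0) || any(cfg$sampling_times_h > cfg$end_h)) {
    stop("mbra_config: sampling times must lie within [0, end_h]")
  }
  if (cfg$sequencing_depth < 1) stop("mbra_config: sequencing_depth must be >= 1")
  if (cfg$theta <= 0) stop("mbra_config: theta must be > 0")
  if (cfg$load_noise_cv < 0) stop("mbra_config: load_noise_cv must be >= 0")
  if (cfg$equilibration_h < 0) stop("mbra_config: equilibration_h must be >= 0")
  class(cfg) <- "mbra_config"
  cfg
}

#' Hydraulic retention time of the chemostat
#'
#' Volume divided by flow; with the protocol defaults (15 mL, 1.875 mL/h)
#' this is 8 h. The dilution rate is its reciprocal.
#'
#' @param cfg An [mbra_config()].
#' @return Retention time in hours, with the dilution rate (1/h) attached
#'   as attribute `"dilution_rate"`.
#' @examples
#' retention_time(mbra_config()) # 8
#' @export
retention_time <- function(cfg) {
  if (cfg$volume_ml <= 0 || cfg$flow_ml_per_h <= 0) {
    stop("retention_time: volume and flow must be positive")
  }
  rt <- cfg$volume_ml / cfg$flow_ml_per_h
  attr(rt, "dilution_rate") <- 1 / rt
  rt
}

#' Chemostat dilution rate (1/h)
#'
#' @param cfg An [mbra_config()].
#' @return Flow / volume in 1/h.
#' @export
dilution_rate <- function(cfg) {
  as.numeric(1 / retention_time(cfg))
}

#' Load a study configuration from a YAML file
#'
#' Keys map onto [mbra_config()] arguments plus a top-level `seed`. Unknown
#' keys are rejected; absent keys fall back to defaults, so an empty file
#' yields the default configuration.
#'
#' @param path Path to a YAML file (empty file allowed).
#' @return List with elements `config` (an `mbra_config`) and `seed`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(formals(mbra_config)), "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  seed <- raw$seed
  raw$seed <- NULL
  cfg <- do.call(mbra_config, raw)
  list(config = cfg, seed = if (is.null(seed)) NULL else as.integer(seed))
}
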