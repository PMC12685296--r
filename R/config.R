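#' Simulation configuration for synthetic 8-cell embryos
#'
#' Collects every tunable of the synthetic time-lapse generator: imaging
#' calibration, polarization-timing structure (early-polarizing probability and
#' onset windows), apical-domain rendering parameters, compaction dynamics, and
#' the conditional division-symmetry / fate probabilities used for lineage
#' tables.
#'
#' Times are minutes from movie start, lengths are micrometres, angles degrees.
#' Early-polarizing (EP) onsets are drawn uniformly within `ep_onset_window`
#' minutes of the cell's third cleavage; late-polarizing (LP) onsets come from
#' a normal distribution truncated to fall after both compaction onset and the
#' EP window, so ground-truth labels are consistent by construction.
#'
#' @param n_embryos number of embryos to simulate.
#' @param cells_per_embryo blastomeres per embryo at the 8-cell stage.
#' @param frame_interval minutes between movie frames.
#' @param pixel_size micrometres per pixel (x and y).
#' @param z_step micrometres between z-slices.
#' @param z_halfrange z-slices cover `[-z_halfrange, z_halfrange]` micrometres
#'   about the embryo mid-plane.
#' @param t_end movie duration in minutes (frames at `0, frame_interval, ...`).
#' @param cell_radius blastomere radius in micrometres.
#' @param ep_probability probability that a blastomere polarizes early.
#' @param ep_onset_window EP onsets are uniform in `[0, ep_onset_window]`
#'   minutes post-cleavage.
#' @param lp_onset_mean,lp_onset_sd mean / sd (minutes, absolute movie time) of
#'   the truncated-normal LP onset distribution.
#' @param cleavage_max third-cleavage completion times are drawn on the frame
#'   grid uniformly in `[0, cleavage_max]` minutes.
#' @param domain_arc_fraction apical-domain length as a fraction of the cell's
#'   contact-free cortical arc.
#' @param domain_enrichment multiplicative cortical intensity factor of the
#'   domain over baseline cortex.
#' @param domain_depth z-extent of the rendered domain in micrometres.
#' @param compaction_start minutes at which inter-blastomere angles start
#'   ramping from 60 degrees.
#' @param compaction_rate ramp slope in degrees per minute (60 up to
#'   `compaction_max_angle`).
#' @param compaction_max_angle ramp ceiling in degrees (`< 180`; equal discs
#'   degenerate to coincident centres at 180).
#' @param noise_sd additive Gaussian noise sd, in intensity units (baseline
#'   cortex is `intensity_cortex`); negative values are clipped to zero.
#' @param intensity_cytoplasm,intensity_cortex,intensity_nucleus rendered mean
#'   intensities (arbitrary units).
#' @param nucleus_radius nucleus radius, micrometres.
#' @param nucleus_offset_ep,nucleus_offset_lp outward (apical) displacement of
#'   the nucleus centre from the cell centre, micrometres, for EP / LP cells.
#' @param p_sym_given_ep,p_sym_given_lp probability of a symmetric 8-to-16-cell
#'   division given the mother's polarity class.
#' @param p_te_given_polar,p_te_given_apolar probability that a daughter is
#'   trophectoderm (outer, marker-positive) given it inherited / did not
#'   inherit the apical domain.
#' @param seed integer seed; all generator randomness flows from it.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
simulation_config <- function(n_embryos = 1L,
                              cells_per_embryo = 8L,
                              frame_interval = 20,
                              pixel_size = 1.0,
                              z_step = 2.0,
                              z_halfrange = 6.0,
                              t_end = 320,
                              cell_radius = 15,
                              ep_probability = 0.1,
                              ep_onset_window = 60,
                              lp_onset_mean = 220,
                              lp_onset_sd = 40,
                              cleavage_max = 40,
                              domain_arc_fraction = 0.4,
                              domain_enrichment = 2.0,
                              domain_depth = 6.0,
                              compaction_start = 100,
                              compaction_rate = 1.0,
                              compaction_max_angle = 170,
                              noise_sd = 0,
                              intensity_cytoplasm = 100,
                              intensity_cortex = 300,
                              intensity_nucleus = 200,
                              nucleus_radius = 5,
                              nucleus_offset_ep = 6,
                              nucleus_offset_lp = 0,
                              p_sym_given_ep = 0.717,
                              p_sym_given_lp = 0.387,
                              p_te_given_polar = 0.90,
                              p_te_given_apolar = 0.20,
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c("ep_probability", "p_sym_given_ep", "p_sym_given_lp",
             "p_te_given_polar", "p_te_given_apolar")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stopf("configuration error: '%s' must be a probability in [0, 1]", p)
  }
  if (cfg$frame_interval <= 0)
    stopf("configuration error: frame_interval must be > 0")
  if (cfg$domain_arc_fraction <= 0 || cfg$domain_arc_fraction >= 1)
    stopf("configuration error: domain_arc_fraction must be in (0, 1)")
  if (cfg$ep_onset_window < 0 || cfg$lp_onset_mean < 0)
    stopf("configuration error: onset times must be non-negative")
  if (cfg$domain_depth < cfg$z_step)
    stopf("configuration error: domain_depth (%g) < z_step (%g)",
          cfg$domain_depth, cfg$z_step)
  if (cfg$compaction_max_angle >= 180 || cfg$compaction_max_angle <= 60)
    stopf("configuration error: compaction_max_angle must be in (60, 180)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic embryo simulation config\n")
  cat(sprintf("  %d embryo(s) x %d cells, frames every %g min to t = %g min\n",
              x$n_embryos, x$cells_per_embryo, x$frame_interval, x$t_end))
  cat(sprintf("  EP probability %.3g (onset U[0, %g] post-cleavage); LP onset N(%g, %g) truncated\n",
              x$ep_probability, x$ep_onset_window, x$lp_onset_mean, x$lp_onset_sd))
  cat(sprintf("  domain: %.0f%% of free arc, %.2gx enrichment, %g um depth; noise sd %g\n",
              100 * x$domain_arc_fraction, x$domain_enrichment, x$domain_depth,
              x$noise_sd))
  cat(sprintf("  compaction: 60 deg -> %g deg from t = %g at %g deg/min; seed %d\n",
              x$compaction_max_angle, x$compaction_start, x$compaction_rate,
              as.integer(x$seed)))
  invisible(x)
}

#' Apical-domain detection thresholds
#'
#' The three-criterion apical-domain rule: the candidate cortical arc must span
#' between `length_fraction_min` and `length_fraction_max` of the contact-free
#' cortex (bounds inclusive), its mean intensity must strictly exceed
#' `intensity_ratio_threshold` times the mean of the remaining contact-free
#' cortex, and arcs passing both must persist across a contiguous z-slab of at
#' least `depth_min` micrometres (consecutive-slice angular overlap of at least
#' `z_overlap_min`).
#'
#' @param length_fraction_min,length_fraction_max admissible arc-length
#'   fraction of the contact-free cortex (defaults 0.33 and 0.80).
#' @param intensity_ratio_threshold domain-over-remaining-cortex mean intensity
#'   ratio that must be strictly exceeded (default 1.5).
#' @param depth_min minimum z-slab thickness in micrometres (default 3).
#' @param z_overlap_min minimum fractional angular overlap between passing arcs
#'   on consecutive z-slices for them to count as the same domain.
#' @param candidate_tie_tol relative tolerance within which candidate-arc
#'   means count as tied during the window search (the longest tied arc
#'   wins); stabilizes the selected arc against sampling noise. 0 restores
#'   exact-tie behaviour.
#' @param persistence number of consecutive positive frames required before a
#'   polarization onset is accepted (default 2; set 1 to disable).
#'
#' @return an object of class `detect_config`.
#' @export
detection_config <- function(length_fraction_min = 0.33,
                             length_fraction_max = 0.80,
                             intensity_ratio_threshold = 1.5,
                             depth_min = 3.0,
                             z_overlap_min = 0.5,
                             candidate_tie_tol = 0.05,
                             persistence = 2L) {
  if (!(length_fraction_min > 0 && length_fraction_min < length_fraction_max &&
        length_fraction_max < 1))
    stopf("configuration error: need 0 < length_fraction_min < length_fraction_max < 1")
  if (intensity_ratio_threshold <= 1)
    stopf("configuration error: intensity_ratio_threshold must be > 1")
  if (depth_min <= 0) stopf("configuration error: depth_min must be > 0")
  if (persistence < 1) stopf("configuration error: persistence must be >= 1")
  if (candidate_tie_tol < 0 || candidate_tie_tol >= 1)
    stopf("configuration error: candidate_tie_tol must be in [0, 1)")
  structure(list(length_fraction_min = length_fraction_min,
                 length_fraction_max = length_fraction_max,
                 intensity_ratio_threshold = intensity_ratio_threshold,
                 depth_min = depth_min,
                 z_overlap_min = z_overlap_min,
                 candidate_tie_tol = candidate_tie_tol,
                 persistence = as.integer(persistence)),
            class = "detect_config")
}

#' @export
print.detect_config <- function(x, ...) {
  cat("Apical-domain detection config\n")
  cat(sprintf("  length fraction in [%.2f, %.2f]; intensity ratio > %.2f\n",
              x$length_fraction_min, x$length_fraction_max,
              x$intensity_ratio_threshold))
  cat(sprintf("  depth >= %g um (z-overlap >= %.0f%%); temporal persistence %d frame(s)\n",
              x$depth_min, 100 * x$z_overlap_min, x$persistence))
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' @param cfg a `sim_config` or `detect_config` object.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   reconstructed config object.
#' @export
write_config <- function(cfg, path) {
  kind <- if (inherits(cfg, "sim_config")) "sim_config" else
    if (inherits(cfg, "detect_config")) "detect_config" else
      stopf("unsupported config class")
  yaml::write_yaml(c(list(.config_class = kind), unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  kind <- raw$.config_class %||% stopf("not a blastopol config file: %s", path)
  raw$.config_class <- NULL
  switch(kind,
         sim_config = do.call(simulation_config, raw),
         detect_config = do.call(detection_config, raw),
         stopf("unknown config class '%s'", kind))
}
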