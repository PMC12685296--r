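#' Simulate lineage records for 8-cell blastomeres
#'
#' Draws, for every blastomere of every simulated embryo, its polarity class
#' (early- vs late-polarizing), third-cleavage completion time, ground-truth
#' polarization onset, 8-to-16-cell division symmetry, and the polarity,
#' position, marker status and fate (trophectoderm vs inner cell mass) of both
#' daughters. Early-polarizing (EP) flags are independent Bernoulli draws per
#' cell; division symmetry is drawn conditional on the mother's class;
#' daughter apical-domain inheritance follows the division type exactly
#' (symmetric: both daughters polar; asymmetric: exactly one); fates are drawn
#' conditional on daughter polarity.
#'
#' Cleavage times fall on the movie frame grid; onsets are quantized up to the
#' next frame. EP onsets are uniform within the configured post-cleavage
#' window; LP onsets are truncated-normal, constrained to fall after both
#' compaction onset and the EP window so that ground-truth labels are
#' internally consistent.
#'
#' @param config a [simulation_config()] object.
#' @return a data.frame with one row per blastomere: `embryo`, `cell`, `ep`
#'   (logical ground truth), `class` (`"EP"`/`"LP"`), `cleavage_min`,
#'   `onset_min` (absolute movie minutes), `division`
#'   (`"symmetric"`/`"asymmetric"`), and for each daughter `d*_polar`,
#'   `d*_position` (`"outer"`/`"inner"`), `d*_marker`, `d*_fate`
#'   (`"TE"`/`"ICM"`).
#' @export
#' @examples
#' cfg <- simulation_config(n_embryos = 3, seed = 7)
#' lin <- generate_lineage_table(cfg)
#' table(lin$class, lin$division)
generate_lineage_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  draw_lineage_table(config)
}

# RNG-stream version: assumes the caller has seeded .Random.seed.
draw_lineage_table <- function(config) {
  n_cells <- config$n_embryos * config$cells_per_embryo
  embryo <- rep(seq_len(config$n_embryos), each = config$cells_per_embryo)
  cell <- rep(seq_len(config$cells_per_embryo), config$n_embryos)

  timing <- draw_timing(config, n_cells)

  p_sym <- ifelse(timing$ep, config$p_sym_given_ep, config$p_sym_given_lp)
  symmetric <- stats::runif(n_cells) < p_sym
  d1_polar <- rep(TRUE, n_cells)                  # asymmetric: daughter 1 polar
  d2_polar <- symmetric

  d1_fate <- draw_fate(d1_polar, config)
  d2_fate <- draw_fate(d2_polar, config)

  data.frame(
    embryo = embryo, cell = cell,
    ep = timing$ep, class = ifelse(timing$ep, "EP", "LP"),
    cleavage_min = timing$cleavage, onset_min = timing$onset,
    division = ifelse(symmetric, "symmetric", "asymmetric"),
    d1_polar = d1_polar, d2_polar = d2_polar,
    d1_position = ifelse(d1_fate == "TE", "outer", "inner"),
    d2_position = ifelse(d2_fate == "TE", "outer", "inner"),
    d1_marker = ifelse(d1_fate == "TE", TRUE, d1_polar),
    d2_marker = ifelse(d2_fate == "TE", TRUE, d2_polar),
    d1_fate = d1_fate, d2_fate = d2_fate,
    stringsAsFactors = FALSE
  )
}

draw_fate <- function(polar, config) {
  p <- ifelse(polar, config$p_te_given_polar, config$p_te_given_apolar)
  ifelse(stats::runif(length(polar)) < p, "TE", "ICM")
}

# Per-cell polarity class, cleavage and ground-truth onset times (absolute
# movie minutes, quantized to the frame grid).
draw_timing <- function(config, n_cells) {
  fi <- config$frame_interval
  ep <- stats::runif(n_cells) < config$ep_probability
  n_frames_cleave <- floor(config$cleavage_max / fi)
  cleavage <- fi * sample.int(n_frames_cleave + 1L, n_cells, replace = TRUE) - fi

  onset <- numeric(n_cells)
  # EP: uniform in (0, window] post-cleavage, quantized up to the frame grid
  u <- stats::runif(n_cells, 0, config$ep_onset_window)
  onset_ep <- cleavage + fi * pmax(1, ceiling(u / fi))
  # LP: truncated normal, after compaction onset and outside the EP window
  lb <- pmax(config$compaction_start, cleavage + config$ep_onset_window + fi)
  plo <- stats::pnorm(lb, config$lp_onset_mean, config$lp_onset_sd)
  v <- stats::runif(n_cells, plo, 1)
  onset_lp <- fi * ceiling(stats::qnorm(v, config$lp_onset_mean,
                                        config$lp_onset_sd) / fi)
  onset <- ifelse(ep, onset_ep, onset_lp)
  list(ep = ep, cleavage = cleavage, onset = onset)
}
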