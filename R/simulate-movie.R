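#' Render a synthetic time-lapse movie of one 8-cell embryo
#'
#' Renders blastomeres as equal discs (spherical caps across z) whose centres
#' sit on a ring; compaction is emulated by shrinking the neighbour
#' centre-to-centre distance so that the circle-circle contact angle follows
#' the configured ramp (60 degrees up to `compaction_max_angle`). Where discs
#' overlap, pixels are assigned to the nearest centre, so label masks form a
#' Voronoi partition of the disc union and each cell's contact-free cortex is
#' exactly the part of its circle outside all other discs.
#'
#' From each cell's ground-truth onset frame onward, a contiguous cortical arc
#' centred on the cell's outward direction and covering `domain_arc_fraction`
#' of the contact-free arc is rendered at `domain_enrichment` times the
#' baseline cortical intensity, on every z-slice within `domain_depth / 2` of
#' the mid-plane. Nuclei are rendered as spheres, displaced apically for
#' early-polarizing cells. Additive Gaussian noise (clipped at zero) is
#' applied last.
#'
#' @param config a [simulation_config()] object (`n_embryos` is ignored; one
#'   embryo per call).
#' @return a list with components `stack` (an `embryo_stack`: intensity,
#'   label and nucleus arrays ordered `[t, z, y, x]`, times, z-offsets and
#'   calibration), `truth` (per-cell ground-truth data.frame: class, cleavage,
#'   onset, rendered domain arc at onset, nominal apical-nucleus distance) and
#'   `lineage` (the matching lineage table from the same random stream).
#' @export
#' @examples
#' cfg <- simulation_config(t_end = 60, z_halfrange = 2, seed = 3)
#' mov <- render_embryo_movie(cfg)
#' dim(mov$stack$intensity)
render_embryo_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  cfg1 <- config
  cfg1$n_embryos <- 1L
  lineage <- draw_lineage_table(cfg1)

  n <- config$cells_per_embryo
  r <- config$cell_radius
  px <- config$pixel_size
  times <- seq(0, config$t_end, by = config$frame_interval)
  zoff <- seq(-config$z_halfrange, config$z_halfrange, by = config$z_step)
  nt <- length(times); nz <- length(zoff)

  # ring radius over time from the compaction angle ramp
  theta_t <- compaction_angle(times, config)
  d_t <- 2 * r * cos(deg2rad(theta_t / 2))          # neighbour distance
  ring_t <- d_t / (2 * sin(pi / n))

  side <- 2 * ceiling((max(ring_t) + r) / px) + 9L
  ctr_px <- (side + 1) / 2                          # embryo centre, pixels
  xg <- matrix(rep(seq_len(side), each = side), side, side)   # x by column
  yg <- matrix(rep(seq_len(side), times = side), side, side)  # y by row

  phi <- 2 * pi * (seq_len(n) - 1) / n              # outward directions

  intensity <- array(0, c(nt, nz, side, side))
  labels <- array(0L, c(nt, nz, side, side))
  nuclei <- array(0L, c(nt, nz, side, side))
  domain_arcs <- matrix(NA_real_, n, 2)             # realized arc at onset
  cortex_w <- 2 * px

  nuc_off <- ifelse(lineage$ep, config$nucleus_offset_ep,
                    config$nucleus_offset_lp)

  for (ti in seq_len(nt)) {
    t_min <- times[ti]
    cx <- ctr_px + ring_t[ti] * cos(phi) / px
    cy <- ctr_px + ring_t[ti] * sin(phi) / px
    for (zi in seq_len(nz)) {
      rz <- sqrt(max(r^2 - zoff[zi]^2, 0))
      if (rz <= 0) next
      dist_um <- lapply(seq_len(n), function(i)
        px * sqrt((xg - cx[i])^2 + (yg - cy[i])^2))
      lab <- matrix(0L, side, side)
      best <- matrix(Inf, side, side)
      for (i in seq_len(n)) {
        upd <- dist_um[[i]] <= rz & dist_um[[i]] < best
        lab[upd] <- i
        best[upd] <- dist_um[[i]][upd]
      }
      img <- matrix(0, side, side)
      img[lab > 0L] <- config$intensity_cytoplasm
      nuc <- matrix(0L, side, side)

      for (i in seq_len(n)) {
        cortex_idx <- which(lab == i & dist_um[[i]] > rz - cortex_w)
        if (length(cortex_idx) == 0L) next
        img[cortex_idx] <- config$intensity_cortex
        if (t_min >= lineage$onset_min[i] &&
            abs(zoff[zi]) <= config$domain_depth / 2) {
          arc <- domain_arc_at(i, cx, cy, rz, px, phi[i], config, n)
          if (!is.null(arc)) {
            ang <- rad2deg(atan2(yg[cortex_idx] - cy[i], xg[cortex_idx] - cx[i]))
            in_dom <- ang_diff(ang, rad2deg(phi[i])) <= arc$half_width
            img[cortex_idx[in_dom]] <-
              config$intensity_cortex * config$domain_enrichment
            if (zi == which.min(abs(zoff)) && is.na(domain_arcs[i, 1])) {
              domain_arcs[i, ] <- wrap360(rad2deg(phi[i]) +
                                            c(-arc$half_width, arc$half_width))
            }
          }
        }
        # nucleus: sphere at mid-plane height, apically displaced centre
        rn_z2 <- config$nucleus_radius^2 - zoff[zi]^2
        if (rn_z2 > 0) {
          ncx <- cx[i] + nuc_off[i] * cos(phi[i]) / px
          ncy <- cy[i] + nuc_off[i] * sin(phi[i]) / px
          nd <- px * sqrt((xg - ncx)^2 + (yg - ncy)^2)
          nidx <- which(lab == i & nd <= sqrt(rn_z2))
          nuc[nidx] <- i
          img[nidx] <- config$intensity_nucleus
        }
      }
      if (config$noise_sd > 0)
        img <- pmax(img + stats::rnorm(length(img), 0, config$noise_sd), 0)
      intensity[ti, zi, , ] <- img
      labels[ti, zi, , ] <- lab
      nuclei[ti, zi, , ] <- nuc
    }
  }

  stack <- new_embryo_stack(intensity, labels, nuclei, times, zoff,
                            pixel_size = px, z_step = config$z_step,
                            frame_interval = config$frame_interval,
                            center = c(y = ctr_px, x = ctr_px))
  truth <- data.frame(
    cell = seq_len(n),
    ep = lineage$ep, class = lineage$class,
    cleavage_min = lineage$cleavage_min,
    onset_min = lineage$onset_min,
    domain_start_deg = domain_arcs[, 1],
    domain_end_deg = domain_arcs[, 2],
    nucleus_offset_um = nuc_off,
    apical_nucleus_dist_um = r - nuc_off - config$nucleus_radius
  )
  list(stack = stack, truth = truth, lineage = lineage, config = config)
}

# Nominal inter-blastomere contact angle (degrees) at time t under the
# configured ramp: flat at 60 before compaction_start, then linear, capped.
compaction_angle <- function(t_min, config) {
  pmin(pmax(60 + config$compaction_rate * (t_min - config$compaction_start),
            60), config$compaction_max_angle)
}

# Realized apical-domain arc for cell i at one slice: half-width (degrees)
# about the outward direction covering domain_arc_fraction of the cell's
# contact-free angular measure, clipped to the contiguous free run that
# contains the outward direction.
domain_arc_at <- function(i, cx, cy, rz, px, phi_i, config, n) {
  grid <- seq(0, 359.5, by = 0.5)
  free <- rep(TRUE, length(grid))
  bx <- (cx[i] + rz * cos(deg2rad(grid)) / px)
  by <- (cy[i] + rz * sin(deg2rad(grid)) / px)
  for (j in seq_len(n)) {
    if (j == i) next
    dj <- px * sqrt((bx - cx[j])^2 + (by - cy[j])^2)
    free <- free & dj >= rz
  }
  if (!any(free)) return(NULL)
  free_meas <- sum(free) * 0.5
  half_width <- 0.5 * config$domain_arc_fraction * free_meas
  # clip to the contiguous free run around the outward direction
  off <- ang_diff(grid, rad2deg(phi_i))
  ord <- order(off)
  reach <- 0
  for (k in ord) {               # grow symmetric neighbourhood while free
    if (!free[k]) break
    reach <- off[k]
  }
  list(half_width = min(half_width, reach))
}
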