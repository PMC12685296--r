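#' Extract a contact-free cortical intensity profile
#'
#' Samples image intensity along a cell's boundary, excluding every boundary
#' pixel that lies within the contact-exclusion band of any neighbouring cell.
#' One sample is taken per boundary pixel; arc position is the cumulative
#' Euclidean step length in micrometres. Samples are ordered by angular
#' position about the cell centroid, measured counterclockwise from the
#' embryo-centre-to-cell-centroid axis, so outward-facing arcs are centred at
#' 0 degrees.
#'
#' @param image 2D intensity matrix (one t, z slice), indexed `[y, x]`.
#' @param cell_mask logical matrix, the cell's region (simply connected).
#' @param neighbor_masks logical matrix (union of all other cells) or a list
#'   of such matrices; `NULL` for an isolated cell.
#' @param pixel_size micrometres per pixel.
#' @param band_px contact-exclusion band half-width in pixels (default 2):
#'   boundary pixels within this many dilations of a neighbour are dropped.
#' @param embryo_center `c(y, x)` in pixels; defaults to the image centre.
#'   Defines the 0-degree (outward) reference axis.
#' @param sample_band optional depth in pixels over which each boundary
#'   sample is averaged along the inward radial direction (emulating a line
#'   trace with thickness); the default 0 takes one sample per boundary
#'   pixel.
#' @param cell_id,t,z optional identifiers carried through to the output.
#'
#' @return a `cortical_profile`: data.frame with columns `arc_um`,
#'   `angle_deg` (signed, in (-180, 180], 0 = outward), `intensity`, `ds_um`
#'   (step length owned by each sample) and `run` (contiguity run id;
#'   contact exclusions split the profile into runs). Attributes:
#'   `total_length_um` (contact-free length), `centroid`, `cell_id`, `t`, `z`.
#' @export
extract_contact_free_profile <- function(image, cell_mask, neighbor_masks,
                                         pixel_size = 1, band_px = 2L,
                                         embryo_center = NULL,
                                         sample_band = 0,
                                         cell_id = NA, t = NA, z = NA) {
  stopifnot(is.matrix(image), is.matrix(cell_mask))
  if (is.list(neighbor_masks))
    neighbor_masks <- Reduce(`|`, neighbor_masks)
  if (is.null(embryo_center))
    embryo_center <- c(y = (nrow(image) + 1) / 2, x = (ncol(image) + 1) / 2)

  bnd <- ordered_boundary(cell_mask)
  if (nrow(bnd) == 0L)
    stop(errorCondition("empty cell mask", class = c("blastopol_empty_profile",
                                                     "error", "condition")))
  keep <- rep(TRUE, nrow(bnd))
  if (!is.null(neighbor_masks) && any(neighbor_masks)) {
    excl <- dilate_n(neighbor_masks, band_px)
    keep <- !excl[cbind(bnd[, 1], bnd[, 2])]
  }
  if (!any(keep))
    stop(errorCondition("cell has no contact-free boundary",
                        class = c("blastopol_empty_profile", "error",
                                  "condition")))
  bnd <- bnd[keep, , drop = FALSE]

  ctr <- mask_centroid(cell_mask)
  ref <- atan2(ctr["y"] - embryo_center["y"], ctr["x"] - embryo_center["x"])
  ang <- rad2deg(atan2(bnd[, 1] - ctr["y"], bnd[, 2] - ctr["x"]) - ref)
  ang <- ((ang + 180) %% 360) - 180            # signed, outward at 0
  ord <- order(ang)
  bnd <- bnd[ord, , drop = FALSE]
  ang <- ang[ord]

  n <- nrow(bnd)
  step <- c(0, pixel_size * sqrt(diff(bnd[, 1])^2 + diff(bnd[, 2])^2))
  gap_tol <- 3 * sqrt(2) * pixel_size
  is_gap <- step > gap_tol
  run <- cumsum(is_gap) + 1L
  ds <- step
  ds[is_gap | seq_len(n) == 1L] <- stats::median(step[!is_gap & step > 0]) %||%
    pixel_size
  if (!any(step > 0 & !is_gap)) ds[] <- pixel_size
  arc <- cumsum(ds)

  sampled <- if (sample_band > 0) {
    radial_band_sample(image, bnd, ctr, depth_px = sample_band)
  } else {
    image[cbind(bnd[, 1], bnd[, 2])]
  }
  out <- data.frame(arc_um = arc, angle_deg = ang,
                    intensity = sampled, ds_um = ds, run = run)
  structure(out,
            total_length_um = sum(ds),
            centroid = ctr, cell_id = cell_id, t = t, z = z,
            pixel_size = pixel_size,
            class = c("cortical_profile", "data.frame"))
}

#' Cortical enrichment
#'
#' The membrane-over-cytoplasm signal excess
#' `(Icortex - Icytoplasm) / Icytoplasm`.
#'
#' @param i_cortex mean cortical intensity.
#' @param i_cytoplasm mean intensity of the cytoplasmic control region; must
#'   be strictly positive.
#' @return dimensionless enrichment (0 means no membrane excess).
#' @export
#' @examples
#' cortical_enrichment(2, 1)   # 1
cortical_enrichment <- function(i_cortex, i_cytoplasm) {
  if (any(!is.finite(i_cytoplasm)) || any(i_cytoplasm <= 0))
    stopf("invalid measurement: Icytoplasm must be > 0")
  (i_cortex - i_cytoplasm) / i_cytoplasm
}

#' Smooth a cortical profile with a local polynomial fit
#'
#' Order-2 local polynomial moving fit of intensity over arc position
#' (Savitzky-Golay style), with endpoint handling by window shrinkage. Arc
#' positions are unchanged; profiles that are polynomials of order <= 2 are
#' reproduced exactly.
#'
#' @param profile a `cortical_profile` (or any data.frame with `arc_um` and
#'   `intensity`).
#' @param window window size in samples (default 20).
#' @param order polynomial order (default 2).
#' @return the profile with smoothed `intensity`.
#' @export
smooth_profile <- function(profile, window = 20L, order = 2L) {
  n <- nrow(profile)
  if (n < 3L) stopf("invalid input: profile needs at least 3 samples")
  if (window > n) stopf("invalid input: window (%d) exceeds samples (%d)",
                        window, n)
  h <- max(1L, floor(window / 2))
  x <- profile$arc_um
  y <- profile$intensity
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    xi <- x[lo:hi] - x[i]
    p <- min(order, length(xi) - 1L)
    X <- outer(xi, 0:p, `^`)
    beta <- tryCatch(qr.solve(X, y[lo:hi]), error = function(e) NULL)
    out[i] <- if (is.null(beta)) mean(y[lo:hi]) else beta[1]
  }
  profile$intensity <- out
  profile
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' `INTnucleus / INTcytoplasm`, with the cytoplasmic control region of equal
#' area, measured on the z-plane where the nucleus is largest.
#'
#' @param int_nucleus mean nuclear intensity.
#' @param int_cytoplasm mean intensity of the equal-area cytoplasmic region;
#'   must be strictly positive.
#' @return the ratio.
#' @export
nuclear_cytoplasmic_ratio <- function(int_nucleus, int_cytoplasm) {
  if (any(!is.finite(int_cytoplasm)) || any(int_cytoplasm <= 0))
    stopf("invalid measurement: INTcytoplasm must be > 0")
  int_nucleus / int_cytoplasm
}

#' Embryo-level EP : LP intensity ratio
#'
#' Per cell, the nuclear signal is normalized to the nuclear DAPI mean; the
#' normalized values are averaged within the early-polarizing (EP) and
#' late-polarizing (LP) groups, and the ratio mean(EP) / mean(LP) is returned
#' for the embryo.
#'
#' @param signal per-cell mean nuclear signal.
#' @param dapi per-cell mean nuclear DAPI (must be > 0).
#' @param class per-cell class labels, `"EP"` or `"LP"`.
#' @return the embryo-level ratio.
#' @export
ep_lp_intensity_ratio <- function(signal, dapi, class) {
  stopifnot(length(signal) == length(dapi), length(signal) == length(class))
  if (any(dapi <= 0)) stopf("invalid measurement: DAPI means must be > 0")
  is_ep <- class == "EP"
  is_lp <- class == "LP"
  if (!any(is_ep) || !any(is_lp))
    stopf("undefined ratio: embryo needs at least one EP and one LP cell")
  norm <- signal / dapi
  mean(norm[is_ep]) / mean(norm[is_lp])
}

#' CDX2 reporter ratio for an 8-cell-stage doublet
#'
#' Each nucleus's mean intensity is normalized per frame to the cytoplasmic
#' background; the reported ratio is cell 1 over cell 2 at the last frame
#' before the first 8-to-16-cell division. When an early-polarizing cell is
#' present it is placed in the numerator.
#'
#' @param nuc1,nuc2 per-frame mean nuclear intensities of the two cells.
#' @param background per-frame cytoplasmic background trace.
#' @param division_frame 1-based index of the frame at which the first
#'   division occurs; the ratio is evaluated at `division_frame - 1`.
#' @param ep_cell `1`, `2`, or `NA` (no EP cell; keep given order,
#'   e.g. left/right).
#' @return the normalized intensity ratio at the final 8-cell-stage frame.
#' @export
cdx2_doublet_ratio <- function(nuc1, nuc2, background,
                               division_frame, ep_cell = NA) {
  n <- length(nuc1)
  stopifnot(length(nuc2) == n, length(background) == n)
  if (is.na(division_frame) || division_frame < 2 || division_frame > n + 1)
    stopf("incomplete trace: division frame absent from trace")
  f <- division_frame - 1L
  r1 <- nuc1[f] / background[f]
  r2 <- nuc2[f] / background[f]
  if (!is.na(ep_cell) && ep_cell == 2L) return(r2 / r1)
  r1 / r2
}

#' Standard cytoplasmic control region
#'
#' A fixed region of cytoplasm eroded away from both the cortex and the
#' nucleus, used as the `Icytoplasm` / `INTcytoplasm` control. When
#' `area_px` is given, the region is trimmed to that many pixels (nearest the
#' nucleus centroid) so nucleus and control areas can be matched.
#'
#' @param cell_mask,nucleus_mask logical matrices.
#' @param pixel_size micrometres per pixel.
#' @param margin_um erosion margin from cortex and nucleus (default 2).
#' @param area_px optional target area in pixels.
#' @return a logical matrix.
#' @export
cytoplasm_region <- function(cell_mask, nucleus_mask = NULL, pixel_size = 1,
                             margin_um = 2, area_px = NULL) {
  n_it <- max(1L, ceiling(margin_um / pixel_size))
  reg <- cell_mask
  for (i in seq_len(n_it)) reg <- erode3(reg)
  if (!is.null(nucleus_mask) && any(nucleus_mask))
    reg <- reg & !dilate_n(nucleus_mask, n_it)
  if (!any(reg)) stopf("invalid measurement: cytoplasmic region is empty")
  if (!is.null(area_px) && sum(reg) > area_px) {
    ctr <- if (!is.null(nucleus_mask) && any(nucleus_mask))
      mask_centroid(nucleus_mask) else mask_centroid(cell_mask)
    idx <- which(reg, arr.ind = TRUE)
    d <- (idx[, 1] - ctr["y"])^2 + (idx[, 2] - ctr["x"])^2
    keep <- idx[order(d)[seq_len(area_px)], , drop = FALSE]
    reg[] <- FALSE
    reg[keep] <- TRUE
  }
  reg
}
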