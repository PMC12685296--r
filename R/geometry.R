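#' Inter-blastomere contact angle (IEA)
#'
#' The angle formed between the outer edges of two adjacent cells at the point
#' of contact. At each endpoint of the shared interface, the tangent to each
#' cell's contact-free boundary is estimated by a local line fit over a
#' configurable arc; the angle between the two away-pointing tangents is
#' reported, averaged over both interface endpoints. Flattened cells approach
#' 180 degrees; a point contact approaches 0.
#'
#' @param mask_a,mask_b logical matrices of the two cells (must share a
#'   contact interface).
#' @param pixel_size micrometres per pixel.
#' @param tangent_arc_um boundary arc length used for each tangent fit; the
#'   default (`Inf`) uses each cell's whole contiguous contact-free arc,
#'   which is the most stable choice for near-spherical blastomeres.
#' @param other_masks optional logical matrix (or list): cells other than the
#'   pair; their interfaces bound the contact-free stretch used for the
#'   tangent fits.
#' @return the angle in degrees, in `[0, 180]`.
#' @export
interblastomere_angle <- function(mask_a, mask_b, pixel_size = 1,
                                  tangent_arc_um = Inf, other_masks = NULL) {
  if (is.list(other_masks)) other_masks <- Reduce(`|`, other_masks)
  barrier <- if (is.null(other_masks)) NULL else dilate3(other_masks)
  near_b <- dilate3(mask_b)
  near_a <- dilate3(mask_a)
  ends_a <- contact_run_ends(mask_a, near_b, barrier)
  ends_b <- contact_run_ends(mask_b, near_a, barrier)
  if (is.null(ends_a) || is.null(ends_b))
    stopf("not adjacent: masks share no contact interface")

  angles <- numeric(0)
  for (ea in ends_a) {
    # match with the nearest endpoint of B's contact run; the junction is
    # taken at the midpoint, cancelling each mask's contact-band overshoot
    d2 <- vapply(ends_b, function(eb)
      sum((eb$point - ea$point)^2), numeric(1))
    eb <- ends_b[[which.min(d2)]]
    junction <- (ea$point + eb$point) / 2
    va <- tangent_direction(ea, junction, pixel_size, tangent_arc_um)
    vb <- tangent_direction(eb, junction, pixel_size, tangent_arc_um)
    if (is.null(va) || is.null(vb)) next
    cosang <- max(-1, min(1, sum(va * vb)))
    angles <- c(angles, rad2deg(acos(cosang)))
  }
  if (length(angles) == 0L)
    stopf("not adjacent: interface too short to fit tangents")
  mean(angles)
}

# Endpoints of the (single, possibly wrapped) contact run on a cell's ordered
# boundary. Each endpoint carries the free-side boundary points that follow
# it, for the tangent fit.
contact_run_ends <- function(mask, near_other, barrier = NULL) {
  bnd <- ordered_boundary(mask)
  n <- nrow(bnd)
  if (n < 8L) return(NULL)
  contact <- near_other[cbind(bnd[, 1], bnd[, 2])]
  blocked <- if (is.null(barrier)) rep(FALSE, n)
  else barrier[cbind(bnd[, 1], bnd[, 2])]
  if (!any(contact)) return(NULL)
  if (all(contact)) return(NULL)
  # close short free gaps so staircase fragmentation at the run ends does not
  # split the interface into spurious runs
  contact <- close_gaps(contact, min_gap = 5L)
  if (all(contact)) return(NULL)
  # rotate so the boundary starts inside a free stretch
  start <- which(!contact)[1]
  idx <- c(seq(start, n), seq_len(start - 1L))
  contact <- contact[idx]
  blocked <- blocked[idx]
  bnd <- bnd[idx, , drop = FALSE]
  runs <- rle(contact)
  ends <- list()
  pos <- cumsum(runs$lengths)
  # circular walk collecting free indices from `from` in direction `dir`,
  # stopping at contact with the partner or with any third cell
  walk_free <- function(from, dir) {
    out <- integer(0)
    i <- from
    for (k in seq_len(n)) {
      i <- ((i - 1L + dir) %% n) + 1L
      if (contact[i] || blocked[i]) break
      out <- c(out, i)
    }
    out
  }
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    first <- pos[k] - runs$lengths[k] + 1L
    last <- pos[k]
    ends <- c(ends,
              list(list(point = bnd[first, ],
                        free = bnd[walk_free(first, -1L), , drop = FALSE]),
                   list(point = bnd[last, ],
                        free = bnd[walk_free(last, 1L), , drop = FALSE])))
  }
  # keep the two endpoints of the longest contact run only
  if (length(ends) > 2L) {
    lens <- runs$lengths[runs$values]
    main <- which.max(lens)
    ends <- ends[c(2L * main - 1L, 2L * main)]
  }
  if (length(ends) == 0L) NULL else ends
}

# Unit tangent at an interface junction, pointing away from the interface
# along one cell's free boundary. The pixelated free boundary is first
# smoothed to subpixel positions (moving average along the contour), then a
# Taubin least-squares circle is fitted over the points nearest the junction
# and its tangent is evaluated at the junction; this avoids both staircase
# quantization and the curvature bias of a straight-line fit. The fit uses at
# least n_min points because the sagitta of a shorter pixelated arc is below
# the quantization noise. Near-straight boundaries (fit radius much larger
# than the fitted span) fall back to a principal-axis line fit.
tangent_direction <- function(end, junction, pixel_size, tangent_arc_um,
                              n_min = 14L) {
  free <- end$free
  if (nrow(free) < 4L) return(NULL)
  free <- smooth_polyline(free, w = 5L)
  steps <- pixel_size * sqrt(rowSums((free - matrix(end$point, nrow(free), 2,
                                                    byrow = TRUE))^2))
  use <- free[steps <= tangent_arc_um, , drop = FALSE]
  if (nrow(use) < n_min)
    use <- free[seq_len(min(n_min, nrow(free))), , drop = FALSE]
  away <- colMeans(use) - junction

  fit <- taubin_circle(use)
  m <- nrow(use)
  span <- sqrt(sum((use[m, ] - use[1, ])^2))
  circle_ok <- FALSE
  if (!is.null(fit) && is.finite(fit$radius) && fit$radius < 25 * span) {
    # accept the circle model only if it actually explains the boundary
    resid <- sqrt((use[, 1] - fit$center[1])^2 +
                    (use[, 2] - fit$center[2])^2) - fit$radius
    circle_ok <- sqrt(mean(resid^2)) <= 1.0
  }
  v <- if (circle_ok) {
    # tangent of the fitted arc at the junction
    radial <- junction - fit$center
    c(-radial[2], radial[1]) / sqrt(sum(radial^2))
  } else {
    # non-circular boundary: local principal-axis line fit at the junction
    loc <- use[seq_len(min(n_min, m)), , drop = FALSE]
    eigen(stats::cov(loc), symmetric = TRUE)$vectors[, 1]
  }
  names(v) <- NULL
  if (sum(v * away) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# close FALSE runs shorter than min_gap that sit between TRUE runs, treating
# the vector as circular
close_gaps <- function(x, min_gap = 5L) {
  n <- length(x)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(x)
  for (i in seq_len(k)) {
    if (!r$values[i] && r$lengths[i] < min_gap) {
      prev <- if (i == 1L) k else i - 1L
      nxt <- if (i == k) 1L else i + 1L
      if (r$values[prev] && r$values[nxt]) r$values[i] <- TRUE
    }
  }
  inverse.rle(r)
}

# Moving-average smoothing of an open polyline (rows = ordered points);
# window shrinks at the ends so endpoints stay anchored near their input
# positions.
smooth_polyline <- function(pts, w = 5L) {
  n <- nrow(pts)
  h <- w %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}

# Taubin algebraic circle fit; returns NULL for degenerate point sets.
taubin_circle <- function(pts) {
  y <- pts[, 1]; x <- pts[, 2]
  xm <- mean(x); ym <- mean(y)
  u <- x - xm; v <- y - ym
  z <- u^2 + v^2
  zm <- mean(z)
  if (zm <= 0) return(NULL)
  Z <- (z - zm) / (2 * sqrt(zm))
  sv <- tryCatch(svd(cbind(Z, u, v)), error = function(e) NULL)
  if (is.null(sv)) return(NULL)
  V <- sv$v[, 3]
  a <- V[1] / (2 * sqrt(zm))
  if (abs(a) < 1e-12) return(NULL)       # straight line
  b <- V[2]; cc <- V[3]
  d <- -zm * a
  r2 <- (b / (2 * a))^2 + (cc / (2 * a))^2 - d / a
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = c(-cc / (2 * a) + ym, -b / (2 * a) + xm),
       radius = sqrt(r2))
}

#' Compaction state of an embryo at one frame
#'
#' An embryo is compacted when every measured inter-blastomere angle has
#' reached the 120-degree threshold (halfway between the uncompacted 60 and
#' the fully compacted 180).
#'
#' @param angles inter-blastomere angles (degrees) for all adjacent pairs at
#'   one frame.
#' @param threshold compaction threshold in degrees (default 120).
#' @return logical flag.
#' @export
compaction_state <- function(angles, threshold = 120) {
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L)
    stopf("compaction state undefined: no measurable adjacent pairs")
  all(angles >= threshold)
}

#' 2D apex geometry of a blastomere
#'
#' Wedge-style shape metrics on the pre-division mid-plane: the apex is
#' anchored at the apical-domain midpoint (or, for unpolarized cells, the
#' middle of the contact-free arc); the basal corners are the two boundary
#' points farthest from the apex (at least 60 degrees apart about the
#' centroid). The apex angle is measured at the apex between the two
#' converging lines to the basal corners; the full length is the mean
#' converging-line length; the side length is the basal width; the length
#' ratio is side over full. Wide, flat cells have larger apex angles and
#' larger length ratios than tall, narrow cells.
#'
#' @param cell_mask logical matrix.
#' @param apex_deg apex anchor angle (degrees, 0 = outward axis; default 0).
#' @param pixel_size micrometres per pixel.
#' @param embryo_center `c(y, x)` reference axis origin; defaults to image
#'   centre.
#' @param min_area_px masks smaller than this are rejected as degenerate.
#' @return a list: `apex_angle_deg`, `side_length_um`, `full_length_um`,
#'   `length_ratio`.
#' @export
apex_geometry_2d <- function(cell_mask, apex_deg = 0, pixel_size = 1,
                             embryo_center = NULL, min_area_px = 25L) {
  if (sum(cell_mask) < min_area_px)
    stopf("invalid shape: mask area below %d pixels", min_area_px)
  if (is.null(embryo_center))
    embryo_center <- c(y = (nrow(cell_mask) + 1) / 2,
                       x = (ncol(cell_mask) + 1) / 2)
  bnd <- ordered_boundary(cell_mask)
  ctr <- mask_centroid(cell_mask)
  ref <- atan2(ctr["y"] - embryo_center["y"], ctr["x"] - embryo_center["x"])
  ang <- rad2deg(atan2(bnd[, 1] - ctr["y"], bnd[, 2] - ctr["x"]) - ref)
  apex <- bnd[which.min(ang_diff(ang, apex_deg)), ]

  d2 <- (bnd[, 1] - apex[1])^2 + (bnd[, 2] - apex[2])^2
  i1 <- which.max(d2)
  sep <- ang_diff(ang, ang[i1]) >= 60
  if (!any(sep)) stopf("invalid shape: no distinct basal corners")
  i2 <- which(sep)[which.max(d2[sep])]
  b1 <- bnd[i1, ]; b2 <- bnd[i2, ]

  v1 <- b1 - apex; v2 <- b2 - apex
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  list(apex_angle_deg = rad2deg(acos(max(-1, min(1, cosang)))),
       side_length_um = pixel_size * sqrt(sum((b1 - b2)^2)),
       full_length_um = pixel_size * mean(c(sqrt(sum(v1^2)), sqrt(sum(v2^2)))),
       length_ratio = sqrt(sum((b1 - b2)^2)) /
         mean(c(sqrt(sum(v1^2)), sqrt(sum(v2^2)))))
}

#' 3D aspect ratio from voxel moments
#'
#' Principal axis lengths from second-order spatial moments of the voxel mask
#' (anisotropy-corrected by the calibration); the aspect ratio is the longest
#' over the shortest axis. For a uniform ellipsoid the moment eigenvalues are
#' `semi_axis^2 / 5`, so axis ratios are recovered exactly in the continuum
#' limit.
#'
#' @param voxel_mask logical 3D array ordered `[z, y, x]`.
#' @param z_step,pixel_size calibration in micrometres.
#' @param min_voxels minimum voxel count (default 50).
#' @return a list: `long_um`, `short_um` (full axis lengths), `aspect_ratio`.
#' @export
aspect_ratio_3d <- function(voxel_mask, z_step = 1, pixel_size = 1,
                            min_voxels = 50L) {
  idx <- which(voxel_mask, arr.ind = TRUE)
  if (nrow(idx) < min_voxels)
    stopf("invalid shape: fewer than %d voxels", min_voxels)
  if (length(unique(idx[, 1])) < 2L)
    stopf("insufficient depth: mask spans fewer than 2 z-slices")
  pts <- cbind(idx[, 1] * z_step, idx[, 2] * pixel_size, idx[, 3] * pixel_size)
  # add the per-voxel second moment so thin shapes are not rank-deficient
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) +
    diag(c(z_step^2, pixel_size^2, pixel_size^2)) / 12
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(long_um = 2 * sqrt(5 * ev[1]),
       short_um = 2 * sqrt(5 * ev[3]),
       aspect_ratio = sqrt(ev[1] / ev[3]))
}

#' Embryo-normalized aspect ratios
#'
#' Divides each cell's aspect ratio by the embryo mean at the same frame, so
#' normalized values average exactly 1 per embryo.
#'
#' @param ratios per-cell aspect ratios for one embryo and frame.
#' @return normalized ratios.
#' @export
normalize_aspect_ratios <- function(ratios) {
  if (length(ratios) == 0L || any(!is.finite(ratios)))
    stopf("invalid input: ratios must be finite and non-empty")
  ratios / mean(ratios)
}

#' Measure inter-blastomere angles for all adjacent pairs at one frame
#'
#' @param stack an `embryo_stack`.
#' @param frame frame index.
#' @param z_index slice to measure on (default: mid-plane).
#' @return data.frame `cell_a`, `cell_b`, `angle_deg` (NA for pairs whose
#'   interface cannot be measured).
#' @export
measure_ieas <- function(stack, frame, z_index = NULL) {
  d <- dim(stack$labels)
  if (is.null(z_index)) z_index <- which.min(abs(stack$zoff))
  lab <- matrix(stack$labels[frame, z_index, , ], d[3], d[4])
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  px <- stack$calibration$pixel_size
  out <- list()
  k <- 1L
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    ma <- lab == ids[i]; mb <- lab == ids[j]
    if (!any(dilate_n(ma, 2L) & mb)) next
    others <- lab > 0L & lab != ids[i] & lab != ids[j]
    ang <- tryCatch(interblastomere_angle(ma, mb, pixel_size = px,
                                          other_masks = others),
                    error = function(e) NA_real_)
    out[[k]] <- data.frame(cell_a = ids[i], cell_b = ids[j], angle_deg = ang)
    k <- k + 1L
  }
  if (k == 1L) return(data.frame(cell_a = integer(0), cell_b = integer(0),
                                 angle_deg = numeric(0)))
  do.call(rbind, out)
}
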