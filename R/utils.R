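# Internal mask / geometry helpers shared across modules.
#
# Masks are plain logical (or integer label) matrices indexed [y, x];
# all morphology below works on logical matrices with a 3x3 structuring
# element implemented by shifts, which is all the pipeline needs.

shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  keep_y <- ys >= 1L & ys <= ny
  keep_x <- xs >= 1L & xs <= nx
  out[keep_y, keep_x] <- m[ys[keep_y], xs[keep_x]]
  out
}

erode3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & shift_mat(m, dy, dx)
  }
  out
}

dilate3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_mat(m, dy, dx)
  }
  out
}

dilate_n <- function(m, n) {
  for (i in seq_len(n)) m <- dilate3(m)
  m
}

# Boundary pixels: in the mask but not in its erosion. Pixels on the image
# edge count as boundary.
boundary_mask <- function(m) {
  inner <- erode3(m)
  edge <- m
  edge[2:(nrow(m) - 1), 2:(ncol(m) - 1)] <- FALSE
  (m & !inner) | (m & edge)
}

mask_centroid <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask", call. = FALSE)
  c(y = mean(idx[, 1]), x = mean(idx[, 2]))
}

# Ordered boundary coordinates (n x 2 matrix, columns y, x) sorted
# counterclockwise by polar angle about the mask centroid. Valid for the
# convex / star-shaped cell regions this pipeline works with.
ordered_boundary <- function(m) {
  b <- which(boundary_mask(m), arr.ind = TRUE)
  if (nrow(b) == 0L) return(b)
  ctr <- mask_centroid(m)
  ang <- atan2(b[, 1] - ctr["y"], b[, 2] - ctr["x"])
  b[order(ang), , drop = FALSE]
}

# Wrap angle (degrees) into [0, 360)
wrap360 <- function(a) ((a %% 360) + 360) %% 360

# Smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b))
  pmin(d, 360 - d)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Bilinear interpolation of a matrix at fractional (y, x) positions;
# positions outside the matrix are clamped to the border.
bilinear_at <- function(m, y, x) {
  ny <- nrow(m); nx <- ncol(m)
  y <- pmin(pmax(y, 1), ny)
  x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    m[cbind(y0 + 1, x0 + 1)] * fy * fx
}

# Cortical band sampling: for each boundary point, average the image along
# the inward radial direction (toward the centroid) over depth_px pixels.
# Emulates a line trace with thickness without tangential blurring.
radial_band_sample <- function(image, bnd, centroid, depth_px = 1.5) {
  dy <- centroid["y"] - bnd[, 1]
  dx <- centroid["x"] - bnd[, 2]
  nrm <- sqrt(dy^2 + dx^2)
  nrm[nrm == 0] <- 1
  uy <- dy / nrm; ux <- dx / nrm
  depths <- seq(0, depth_px, by = 0.75)
  vals <- vapply(depths, function(k)
    bilinear_at(image, bnd[, 1] + k * uy, bnd[, 2] + k * ux),
    numeric(nrow(bnd)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  rowMeans(vals)
}
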