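#' @title Calibrated image stacks
#' @description An `embryo_stack` bundles a T x Z x Y x X intensity array with
#'   per-cell label masks, optional nucleus masks, frame times, z-offsets and
#'   physical calibration. [render_embryo_movie()] produces one; [read_stack()]
#'   reconstructs one from disk.
#' @name embryo_stack
NULL

new_embryo_stack <- function(intensity, labels, nuclei, times, zoff,
                             pixel_size, z_step, frame_interval, center) {
  stopifnot(length(dim(intensity)) == 4L)
  structure(list(intensity = intensity, labels = labels, nuclei = nuclei,
                 times = times, zoff = zoff,
                 calibration = list(pixel_size = pixel_size, z_step = z_step,
                                    frame_interval = frame_interval),
                 center = center),
            class = "embryo_stack")
}

#' @export
print.embryo_stack <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("embryo_stack: %d frames x %d z x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  calibration: %.3g um/px, %.3g um/z, %g min/frame\n",
              x$calibration$pixel_size, x$calibration$z_step,
              x$calibration$frame_interval))
  n_cells <- max(x$labels)
  cat(sprintf("  %d labelled cell(s); t = %g..%g min\n",
              n_cells, min(x$times), max(x$times)))
  invisible(x)
}

#' Write an embryo stack to disk
#'
#' Writes `intensity.tif` (16-bit, pages ordered t-major then z), `labels.tif`
#' and `nuclei.tif` (8-bit label pages), and `stack.yaml` holding dimensions,
#' calibration and the intensity scale factor.
#'
#' @param stack an `embryo_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$intensity)
  scale <- max(stack$intensity, 1)
  pages <- vector("list", d[1] * d[2])
  lpages <- vector("list", d[1] * d[2])
  npages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) {
    pages[[k]] <- stack$intensity[ti, zi, , ] / scale
    lpages[[k]] <- stack$labels[ti, zi, , ] / 255
    npages[[k]] <- stack$nuclei[ti, zi, , ] / 255
    k <- k + 1L
  }
  tiff::writeTIFF(pages, file.path(dir, "intensity.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(lpages, file.path(dir, "labels.tif"), bits.per.sample = 8L)
  tiff::writeTIFF(npages, file.path(dir, "nuclei.tif"), bits.per.sample = 8L)
  yaml::write_yaml(list(n_t = d[1], n_z = d[2], ny = d[3], nx = d[4],
                        times = stack$times, zoff = stack$zoff,
                        scale = scale,
                        center = as.list(stack$center),
                        calibration = stack$calibration),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' Read a calibrated image stack
#'
#' Two input layouts are supported. A directory written by [write_stack()] is
#' reconstructed exactly (including labels and nuclei). Alternatively a bare
#' multi-page TIFF may be read by declaring its axis structure: pages must be
#' ordered t-major then z; a 3D stack (movie with a single optical section) is
#' declared with `n_z = 1` and a z-dimension of one is inserted. A plain 2D
#' image is rejected.
#'
#' @param path directory (with `stack.yaml`) or a TIFF file.
#' @param n_t,n_z frame and slice counts for a bare TIFF (ignored for
#'   directories).
#' @param pixel_size,z_step,frame_interval calibration for a bare TIFF.
#' @return an `embryo_stack`; for bare TIFFs the label and nucleus arrays are
#'   zero (masks must be supplied separately).
#' @export
read_stack <- function(path, n_t = NULL, n_z = NULL,
                       pixel_size = 1, z_step = 1, frame_interval = 1) {
  if (dir.exists(path)) return(read_stack_dir(path))
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  if (n_pages == 1L && is.null(n_t))
    stopf("format error: single 2D image; expected a T x Z x Y x X stack %s",
          "(declare n_t / n_z for multi-page TIFFs)")
  if (is.null(n_z)) n_z <- 1L
  if (is.null(n_t)) n_t <- n_pages %/% n_z
  if (n_t * n_z != n_pages)
    stopf("format error: %d pages cannot be arranged as t=%d x z=%d; %s",
          n_pages, n_t, n_z, "expected axes T x Z x Y x X, t-major")
  first <- pages[[1]]
  if (length(dim(first)) == 3L) {            # drop RGB channels if present
    pages <- lapply(pages, function(p) p[, , 1])
    first <- pages[[1]]
  }
  ny <- nrow(first); nx <- ncol(first)
  intensity <- array(0, c(n_t, n_z, ny, nx))
  k <- 1L
  for (ti in seq_len(n_t)) for (zi in seq_len(n_z)) {
    intensity[ti, zi, , ] <- pages[[k]]
    k <- k + 1L
  }
  new_embryo_stack(intensity,
                   labels = array(0L, dim(intensity)),
                   nuclei = array(0L, dim(intensity)),
                   times = (seq_len(n_t) - 1) * frame_interval,
                   zoff = (seq_len(n_z) - 1) * z_step,
                   pixel_size = pixel_size, z_step = z_step,
                   frame_interval = frame_interval,
                   center = c(y = (ny + 1) / 2, x = (nx + 1) / 2))
}

read_stack_dir <- function(dir) {
  meta_path <- file.path(dir, "stack.yaml")
  if (!file.exists(meta_path))
    stopf("format error: %s lacks stack.yaml", dir)
  meta <- yaml::read_yaml(meta_path)
  read_pages <- function(file, scale) {
    pages <- tiff::readTIFF(file.path(dir, file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, c(meta$n_t, meta$n_z, meta$ny, meta$nx))
    k <- 1L
    for (ti in seq_len(meta$n_t)) for (zi in seq_len(meta$n_z)) {
      arr[ti, zi, , ] <- pages[[k]] * scale
      k <- k + 1L
    }
    arr
  }
  intensity <- read_pages("intensity.tif", meta$scale)
  labels <- round(read_pages("labels.tif", 255))
  storage.mode(labels) <- "integer"
  nuclei <- round(read_pages("nuclei.tif", 255))
  storage.mode(nuclei) <- "integer"
  new_embryo_stack(intensity, labels, nuclei,
                   times = unlist(meta$times), zoff = unlist(meta$zoff),
                   pixel_size = meta$calibration$pixel_size,
                   z_step = meta$calibration$z_step,
                   frame_interval = meta$calibration$frame_interval,
                   center = c(y = meta$center$y, x = meta$center$x))
}
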