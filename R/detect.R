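#' Find the candidate apical-domain arc on one cortical profile
#'
#' Exhaustive search over all contiguous arcs whose length lies between the
#' configured fractions of the total contact-free length, returning the arc
#' that maximizes the length-weighted mean intensity (ties broken by longer
#' arc, then smaller start angle). Windows never span contact gaps; on a
#' fully contact-free (closed) boundary the search wraps around.
#'
#' @param profile a `cortical_profile` from [extract_contact_free_profile()].
#' @param config a [detection_config()].
#' @return a list: `start`/`end` sample indices, `start_deg`/`end_deg`,
#'   `mean_intensity`, `length_um`, `length_fraction`, `intensity_ratio`
#'   (arc mean over the mean of the remaining contact-free profile),
#'   `domain_size_deg`, `mid_deg`, `wraps`; or an error of class
#'   `blastopol_no_candidate` if no admissible window exists.
#' @export
find_candidate_domain <- function(profile, config = detection_config()) {
  n <- nrow(profile)
  if (n == 0L)
    stop(errorCondition("empty profile",
                        class = c("blastopol_no_candidate", "error",
                                  "condition")))
  total_len <- attr(profile, "total_length_um")
  circular <- length(unique(profile$run)) == 1L && is_closed_profile(profile)
  res <- best_window_cpp(profile$intensity, profile$ds_um,
                         as.integer(profile$run), total_len,
                         config$length_fraction_min,
                         config$length_fraction_max, circular,
                         config$candidate_tie_tol %||% 0.05)
  if (!isTRUE(res$found))
    stop(errorCondition("no admissible arc: profile shorter than the minimum length fraction",
                        class = c("blastopol_no_candidate", "error",
                                  "condition")))
  res <- trim_window_edges(res, profile, total_len,
                           config$length_fraction_min)
  i <- res$start; j <- res$end
  in_win <- if (!res$wraps && j >= i) seq(i, j) else c(seq(i, n), seq_len(j))
  win_sum <- res$mean * res$length_um
  rest_len <- total_len - res$length_um
  rest_sum <- sum(profile$intensity * profile$ds_um) - win_sum
  ratio <- if (rest_len > 0) res$mean / (rest_sum / rest_len) else NA_real_

  start_deg <- profile$angle_deg[i]
  end_deg <- profile$angle_deg[j]
  size_deg <- if (res$wraps || j < i) wrap360(end_deg - start_deg)
  else end_deg - start_deg
  mid_deg <- wrap360(start_deg + size_deg / 2)
  mid_deg <- ifelse(mid_deg > 180, mid_deg - 360, mid_deg)

  list(start = i, end = j, start_deg = start_deg, end_deg = end_deg,
       mean_intensity = res$mean, length_um = res$length_um,
       length_fraction = res$length_um / total_len,
       intensity_ratio = ratio, domain_size_deg = size_deg,
       mid_deg = mid_deg, wraps = isTRUE(res$wraps),
       total_length_um = total_len)
}

# The tie-tolerant search prefers the longest near-maximal window, which on
# a clean bright arc can absorb a few dim samples at the edges. Trim window
# ends whose intensity falls below the midpoint of the window and remaining
# means; on noisy-but-bright arcs edge samples stay above the midpoint and
# are kept.
trim_window_edges <- function(res, profile, total_len, fmin) {
  n <- nrow(profile)
  idx <- if (!res$wraps && res$end >= res$start) seq(res$start, res$end)
  else c(seq(res$start, n), seq_len(res$end))
  all_sum <- sum(profile$intensity * profile$ds_um)
  repeat {
    wlen <- sum(profile$ds_um[idx])
    if (length(idx) <= 2L || wlen <= fmin * total_len) break
    wsum <- sum(profile$intensity[idx] * profile$ds_um[idx])
    wmean <- wsum / wlen
    rest_len <- total_len - wlen
    rmean <- if (rest_len > 0) (all_sum - wsum) / rest_len else wmean
    thr <- (wmean + rmean) / 2
    first_i <- idx[1]; last_i <- idx[length(idx)]
    drop_first <- profile$intensity[first_i] < thr
    drop_last <- profile$intensity[last_i] < thr
    if (!drop_first && !drop_last) break
    # drop the dimmer end first, keeping the window admissible
    drop_head <- if (drop_first && drop_last)
      profile$intensity[first_i] <= profile$intensity[last_i] else drop_first
    cand <- if (drop_head) idx[-1] else idx[-length(idx)]
    if (sum(profile$ds_um[cand]) < fmin * total_len) break
    idx <- cand
  }
  wlen <- sum(profile$ds_um[idx])
  wsum <- sum(profile$intensity[idx] * profile$ds_um[idx])
  list(found = TRUE, start = idx[1], end = idx[length(idx)],
       wraps = idx[length(idx)] < idx[1], mean = wsum / wlen,
       length_um = wlen)
}

# closed boundary: the angular gap across the profile ends is no larger than
# the typical sample spacing
is_closed_profile <- function(profile) {
  ang <- sort(profile$angle_deg)
  gaps <- diff(c(ang, ang[1] + 360))
  max(gaps) <= 5 * stats::median(gaps)
}

#' Apply the three apical-domain criteria across z
#'
#' A cell is called polarized at one time point iff (a) some z-slice has a
#' candidate arc whose length fraction lies within the configured bounds, (b)
#' that arc's mean intensity strictly exceeds the threshold times the mean of
#' the remaining contact-free profile, and (c) slices passing (a) and (b),
#' with consecutive-slice angular overlap of at least the configured fraction,
#' form a contiguous run whose slab thickness (`n_slices * z_step`) reaches
#' the depth minimum. The reported arc is that of the passing slice with the
#' largest intensity ratio within the best run.
#'
#' @param candidates list of per-z-slice candidates from
#'   [find_candidate_domain()] (`NULL` entries for slices where the cell is
#'   absent or has no admissible arc).
#' @param config a [detection_config()].
#' @param z_step z-slice spacing in micrometres.
#' @return an `apical_domain_call`: list with `polarized`, and when polarized
#'   `arc_start_deg`, `arc_end_deg`, `domain_size_deg`, `mid_deg`,
#'   `length_fraction`, `intensity_ratio`, `z_extent_um`, `z_index`.
#' @export
apply_domain_criteria <- function(candidates, config = detection_config(),
                                  z_step = NULL) {
  if (is.null(z_step) || is.na(z_step) || z_step <= 0)
    stopf("configuration error: z_step calibration is required")
  nz <- length(candidates)
  pass <- vapply(candidates, function(cand) {
    !is.null(cand) &&
      cand$length_fraction >= config$length_fraction_min - 1e-9 &&
      cand$length_fraction <= config$length_fraction_max + 1e-9 &&
      is.finite(cand$intensity_ratio) &&
      cand$intensity_ratio > config$intensity_ratio_threshold
  }, logical(1))

  call <- list(polarized = FALSE)
  class(call) <- "apical_domain_call"
  if (!any(pass)) return(call)

  # contiguous runs of passing slices with sufficient mutual arc overlap
  best_run <- integer(0)
  cur <- integer(0)
  for (zi in seq_len(nz)) {
    if (!pass[zi]) { cur <- integer(0); next }
    if (length(cur) > 0L &&
        arc_overlap(candidates[[cur[length(cur)]]], candidates[[zi]]) >=
          config$z_overlap_min) {
      cur <- c(cur, zi)
    } else {
      cur <- zi
    }
    if (length(cur) > length(best_run)) best_run <- cur
  }
  z_extent <- length(best_run) * z_step
  if (z_extent < config$depth_min) return(call)

  ratios <- vapply(best_run, function(zi) candidates[[zi]]$intensity_ratio,
                   numeric(1))
  zi_best <- best_run[which.max(ratios)]
  cand <- candidates[[zi_best]]
  structure(list(polarized = TRUE,
                 arc_start_deg = cand$start_deg, arc_end_deg = cand$end_deg,
                 domain_size_deg = cand$domain_size_deg,
                 mid_deg = cand$mid_deg,
                 length_fraction = cand$length_fraction,
                 intensity_ratio = cand$intensity_ratio,
                 z_extent_um = z_extent, z_index = zi_best,
                 z_run = best_run),
            class = "apical_domain_call")
}

#' @export
print.apical_domain_call <- function(x, ...) {
  if (!x$polarized) {
    cat("apical domain call: not polarized\n")
  } else {
    cat(sprintf("apical domain call: polarized (%.0f deg arc, ratio %.2f, %.1f um depth)\n",
                x$domain_size_deg, x$intensity_ratio, x$z_extent_um))
  }
  invisible(x)
}

# Fractional angular overlap of two candidate arcs (relative to the smaller
# arc); 0.5-degree grid.
arc_overlap <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0)
  grid <- seq(-180, 179.5, by = 0.5)
  in_arc <- function(cand) {
    sz <- cand$domain_size_deg
    ang_diff(grid, cand$mid_deg) <= sz / 2
  }
  ia <- in_arc(a); ib <- in_arc(b)
  denom <- min(sum(ia), sum(ib))
  if (denom == 0) return(0)
  sum(ia & ib) / denom
}

#' Apical-domain size in degrees
#'
#' The angle subtended by the domain arc at the cell centroid, on the
#' mid-plane slice. Arc endpoints may be given as angles (degrees about the
#' centroid, counterclockwise) or taken from a polarized call.
#'
#' @param call an `apical_domain_call`, or `NULL` if angles given directly.
#' @param start_deg,end_deg arc endpoints (counterclockwise from start to
#'   end); equal endpoints denote a full circle.
#' @return degrees in (0, 360].
#' @export
domain_size_degrees <- function(call = NULL, start_deg = NULL, end_deg = NULL) {
  if (!is.null(call)) {
    if (!isTRUE(call$polarized))
      stopf("undefined measurement: cell is not polarized")
    return(call$domain_size_deg)
  }
  sz <- wrap360(end_deg - start_deg)
  ifelse(sz == 0, 360, sz)
}

#' Apical-surface-to-nucleus distance
#'
#' Perpendicular distance (micrometres) from the nucleus boundary point
#' nearest the apical-domain midpoint to the cortex at the domain midpoint,
#' on the mid-plane slice.
#'
#' @param nucleus_mask logical matrix of the nucleus on the same slice.
#' @param cell_mask logical matrix of the cell.
#' @param mid_deg apical-domain midpoint angle (degrees, 0 = outward axis),
#'   e.g. `call$mid_deg` from a polarized call.
#' @param pixel_size micrometres per pixel.
#' @param embryo_center `c(y, x)` reference for the outward axis; defaults to
#'   the image centre.
#' @return distance in micrometres.
#' @export
apical_nucleus_distance <- function(nucleus_mask, cell_mask, mid_deg,
                                    pixel_size = 1, embryo_center = NULL) {
  if (is.null(nucleus_mask) || !any(nucleus_mask))
    stopf("missing input: nucleus mask is empty")
  if (is.null(embryo_center))
    embryo_center <- c(y = (nrow(cell_mask) + 1) / 2,
                       x = (ncol(cell_mask) + 1) / 2)
  bnd <- ordered_boundary(cell_mask)
  ctr <- mask_centroid(cell_mask)
  ref <- atan2(ctr["y"] - embryo_center["y"], ctr["x"] - embryo_center["x"])
  ang <- rad2deg(atan2(bnd[, 1] - ctr["y"], bnd[, 2] - ctr["x"]) - ref)
  apex <- bnd[which.min(ang_diff(ang, mid_deg)), ]
  nb <- which(boundary_mask(nucleus_mask), arr.ind = TRUE)
  d2 <- (nb[, 1] - apex[1])^2 + (nb[, 2] - apex[2])^2
  pixel_size * sqrt(min(d2))
}

#' Run apical-domain detection over a stack
#'
#' For every requested cell and frame, extracts the contact-free cortical
#' profile on each z-slice, finds the candidate arc, and applies the
#' three-criterion rule.
#'
#' @param stack an `embryo_stack` with label masks.
#' @param config a [detection_config()].
#' @param cells,frames integer subsets (defaults: all labelled cells, all
#'   frames).
#' @param band_px contact-exclusion band in pixels.
#' @return a data.frame of per-cell, per-frame calls: `cell`, `frame`,
#'   `t_min`, `polarized`, `domain_size_deg`, `length_fraction`,
#'   `intensity_ratio`, `z_extent_um`, `mid_deg`.
#' @export
detect_stack <- function(stack, config = detection_config(),
                         cells = NULL, frames = NULL, band_px = 2L) {
  d <- dim(stack$intensity)
  if (is.null(frames)) frames <- seq_len(d[1])
  if (is.null(cells)) cells <- seq_len(max(stack$labels))
  z_step <- stack$calibration$z_step
  px <- stack$calibration$pixel_size
  rows <- vector("list", length(cells) * length(frames))
  k <- 1L
  for (ti in frames) {
    lab_t <- stack$labels[ti, , , , drop = FALSE]
    for (ci in cells) {
      cands <- vector("list", d[2])
      for (zi in seq_len(d[2])) {
        lab <- matrix(lab_t[1, zi, , ], d[3], d[4])
        cm <- lab == ci
        if (sum(cm) < 9L) next
        nm <- lab > 0L & lab != ci
        prof <- tryCatch(
          extract_contact_free_profile(
            matrix(stack$intensity[ti, zi, , ], d[3], d[4]),
            cm, if (any(nm)) nm else NULL,
            pixel_size = px, band_px = band_px,
            embryo_center = stack$center, cell_id = ci,
            t = stack$times[ti], z = zi),
          blastopol_empty_profile = function(e) NULL)
        if (is.null(prof)) next
        cands[[zi]] <- tryCatch(find_candidate_domain(prof, config),
                                blastopol_no_candidate = function(e) NULL)
      }
      call <- apply_domain_criteria(cands, config, z_step)
      rows[[k]] <- data.frame(
        cell = ci, frame = ti, t_min = stack$times[ti],
        polarized = call$polarized,
        domain_size_deg = call$domain_size_deg %||% NA_real_,
        length_fraction = call$length_fraction %||% NA_real_,
        intensity_ratio = call$intensity_ratio %||% NA_real_,
        z_extent_um = call$z_extent_um %||% NA_real_,
        mid_deg = call$mid_deg %||% NA_real_)
      k <- k + 1L
    }
  }
  do.call(rbind, rows[seq_len(k - 1L)])
}
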