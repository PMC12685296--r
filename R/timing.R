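#' Assemble a blastomere track
#'
#' One cell's time series of apical-domain calls and neighbour contact-angle
#' minima, anchored at its third-cleavage completion time.
#'
#' @param t_min frame times (minutes from movie start).
#' @param polarized per-frame apical-domain call flags.
#' @param min_iea per-frame minimum inter-blastomere angle over the cell's
#'   adjacent pairs (degrees; may be NA where unmeasured).
#' @param cleavage_min third-cleavage completion time (minutes).
#' @param embryo,cell identifiers.
#' @return a `blastomere_track` (data.frame with attributes).
#' @export
blastomere_track <- function(t_min, polarized, min_iea = NULL,
                             cleavage_min = 0, embryo = NA, cell = NA) {
  stopifnot(length(t_min) == length(polarized))
  if (is.null(min_iea)) min_iea <- rep(NA_real_, length(t_min))
  ord <- order(t_min)
  structure(data.frame(t_min = t_min[ord], polarized = polarized[ord],
                       min_iea = min_iea[ord]),
            cleavage_min = cleavage_min, embryo = embryo, cell = cell,
            class = c("blastomere_track", "data.frame"))
}

#' Polarization onset of a blastomere
#'
#' The first frame time, at or after cleavage completion, at which the
#' apical-domain call is positive and stays positive for `persistence`
#' consecutive frames. Single positive frames amid negatives are rejected
#' when `persistence >= 2`.
#'
#' @param track a [blastomere_track()].
#' @param persistence required run of consecutive positive frames (default 2).
#' @return a list: `onset_min` (absolute movie minutes; `NA` if the cell never
#'   polarizes within the track), `onset_rel_min` (minutes post-cleavage) and
#'   `censored` (`TRUE` when a trailing positive run was cut short by the end
#'   of imaging, so absence of an onset is not informative).
#' @export
polarization_onset <- function(track, persistence = 2L) {
  cleav <- attr(track, "cleavage_min")
  use <- track$t_min >= cleav
  if (!any(use))
    stopf("incomplete track: no frames at or after cleavage (%g min)", cleav)
  tt <- track$t_min[use]
  pol <- track$polarized[use]
  n <- length(pol)
  onset <- NA_real_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (pol[i]) run + 1L else 0L
    if (run >= persistence) { onset <- tt[i - persistence + 1L]; break }
  }
  censored <- FALSE
  if (is.na(onset)) {
    trailing <- 0L
    for (i in rev(seq_len(n))) {
      if (!pol[i]) break
      trailing <- trailing + 1L
    }
    censored <- trailing > 0L && trailing < persistence
  }
  list(onset_min = onset,
       onset_rel_min = if (is.na(onset)) NA_real_ else onset - cleav,
       censored = censored)
}

#' Classify a blastomere as early-polarizing, late-polarizing or unpolarized
#'
#' A cell is early-polarizing (EP) iff it forms the apical domain (1) within
#' the first hour after the reference event and (2) before its minimum
#' neighbour inter-blastomere angle reaches the compaction threshold of 120
#' degrees. Polarized cells failing either condition are late-polarizing
#' (LP); cells with no onset are unpolarized. In `live` mode the reference
#' event is the cell's own third cleavage; in `fixed` mode it is the last
#' third cleavage in the embryo (supply `reference_min`).
#'
#' @param track a [blastomere_track()].
#' @param mode `"live"` or `"fixed"`.
#' @param reference_min reference event time for `fixed` mode (minutes).
#' @param window_min EP window after the reference event (default 60,
#'   boundary inclusive).
#' @param iea_threshold compaction threshold in degrees (default 120).
#' @param persistence onset persistence, passed to [polarization_onset()].
#' @return a list: `class` (`"EP"`, `"LP"` or `"unpolarized"`), `onset_min`,
#'   `onset_rel_min`, `min_iea_at_onset`, `censored`.
#' @export
classify_polarity <- function(track, mode = c("live", "fixed"),
                              reference_min = NULL, window_min = 60,
                              iea_threshold = 120, persistence = 2L) {
  mode <- match.arg(mode)
  ons <- polarization_onset(track, persistence)
  ref <- switch(mode,
                live = attr(track, "cleavage_min"),
                fixed = reference_min %||%
                  stopf("fixed mode requires reference_min (last third cleavage)"))
  if (is.na(ons$onset_min)) {
    return(list(class = "unpolarized", onset_min = NA_real_,
                onset_rel_min = NA_real_, min_iea_at_onset = NA_real_,
                censored = ons$censored))
  }
  iea <- track$min_iea[match(ons$onset_min, track$t_min)]
  early_window <- (ons$onset_min - ref) <= window_min
  if (early_window && is.na(iea))
    stopf("unresolvable class: no inter-blastomere angle at the onset frame")
  cls <- if (early_window && !is.na(iea) && iea < iea_threshold) "EP" else "LP"
  list(class = cls, onset_min = ons$onset_min,
       onset_rel_min = ons$onset_min - attr(track, "cleavage_min"),
       min_iea_at_onset = iea, censored = FALSE)
}

#' Embryo-level early-polarization status
#'
#' An embryo is an EP embryo iff at least one of its blastomeres is
#' early-polarizing.
#'
#' @param classes character vector of per-cell classes (`"EP"`, `"LP"`,
#'   `"unpolarized"`).
#' @return a list: `ep_embryo` flag and `n_ep` count.
#' @export
embryo_ep_status <- function(classes) {
  n_ep <- sum(classes == "EP")
  list(ep_embryo = n_ep >= 1L, n_ep = n_ep)
}

#' Histogram of polarization onsets
#'
#' Bins onset times (minutes relative to each cell's cleavage) and reports
#' local maxima as peaks. No formal bimodality test is performed; the
#' histogram is descriptive.
#'
#' @param onsets_rel onset times relative to cleavage (minutes); `NA`s are
#'   dropped.
#' @param bin_width bin width in minutes (default 20).
#' @return an `onset_histogram`: list with `breaks`, `counts`, `mids`,
#'   `peaks` (bin midpoints of local maxima).
#' @export
onset_histogram <- function(onsets_rel, bin_width = 20) {
  onsets_rel <- onsets_rel[!is.na(onsets_rel)]
  if (length(onsets_rel) == 0L)
    stopf("empty histogram: no onsets supplied")
  breaks <- seq(0, bin_width * ceiling(max(onsets_rel) / bin_width + 1e-9),
                by = bin_width)
  if (length(breaks) < 2L) breaks <- c(0, bin_width)
  counts <- as.vector(table(cut(onsets_rel, breaks, right = TRUE,
                                include.lowest = TRUE)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # local maxima over run-length-encoded counts; plateaus count once, at
  # their first bin
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  prev <- c(-Inf, r$values[-nr])
  nxt <- c(r$values[-1], -Inf)
  peak_runs <- r$values > 0 & r$values > prev & r$values > nxt
  structure(list(breaks = breaks, counts = counts, mids = mids,
                 peaks = mids[starts[peak_runs]], n = length(onsets_rel)),
            class = "onset_histogram")
}

#' @export
print.onset_histogram <- function(x, ...) {
  cat(sprintf("onset histogram: %d onsets, %d bins of %g min\n",
              x$n, length(x$counts), diff(x$breaks[1:2])))
  cat("  peaks at", paste(x$peaks, collapse = ", "), "min post-cleavage\n")
  invisible(x)
}

#' @export
plot.onset_histogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$mids, space = 0,
                    xlab = "onset (min post-cleavage)", ylab = "cells", ...)
  invisible(x)
}
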