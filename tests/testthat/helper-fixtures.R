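# Shared fixtures and independent oracles, all built in code.

# filled disc mask
disc_mask <- function(cy, cx, r, n = 121) {
  m <- matrix(FALSE, n, n)
  for (y in seq_len(n)) m[y, ] <- (y - cy)^2 + (seq_len(n) - cx)^2 <= r^2
  m
}

# closed-form contact angle between two equal overlapping circles of radius r
# whose centres are d apart (exterior angle between the away tangents at an
# intersection point)
circle_contact_angle <- function(d, r) {
  180 - acos(1 - d^2 / (2 * r^2)) * 180 / pi
}

# Brute-force max-mean window oracle, mirroring the documented selection rule
# (windows within tie_tol of the maximal mean are tied; longest wins, then
# higher mean, then smaller start). Independent R implementation of the
# search contract.
brute_window <- function(intensity, ds, run, total_len, fmin, fmax,
                         tie_tol = 0.05, circular = FALSE) {
  n <- length(intensity)
  lo <- fmin * total_len; hi <- fmax * total_len
  wins <- list()
  for (i in seq_len(n)) {
    jmax <- if (circular) i + n - 1 else n
    wlen <- 0; wsum <- 0
    for (j in i:jmax) {
      jj <- ((j - 1) %% n) + 1
      if (!circular && run[jj] != run[i]) break
      wlen <- wlen + ds[jj]
      wsum <- wsum + intensity[jj] * ds[jj]
      if (wlen > hi + 1e-12) break
      if (wlen + 1e-12 < lo) next
      wins[[length(wins) + 1]] <- list(i = i, j = jj, len = wlen,
                                       mean = wsum / wlen)
    }
  }
  if (length(wins) == 0) return(NULL)
  means <- vapply(wins, `[[`, numeric(1), "mean")
  thresh <- max(means) - tie_tol * abs(max(means)) - 1e-12
  cand <- wins[means >= thresh]
  lens <- vapply(cand, `[[`, numeric(1), "len")
  cmeans <- vapply(cand, `[[`, numeric(1), "mean")
  starts <- vapply(cand, `[[`, numeric(1), "i")
  ord <- order(-lens, -cmeans, starts)
  best <- cand[[ord[1]]]
  brute_trim(best, intensity, ds, total_len, fmin)
}

# mirror of the documented edge-trim rule: drop window-end samples dimmer
# than the midpoint of the window mean and the remaining-profile mean
brute_trim <- function(win, intensity, ds, total_len, fmin) {
  n <- length(intensity)
  idx <- if (win$j >= win$i) win$i:win$j else c(win$i:n, 1:win$j)
  all_sum <- sum(intensity * ds)
  repeat {
    wlen <- sum(ds[idx])
    if (length(idx) <= 2 || wlen <= fmin * total_len) break
    wsum <- sum(intensity[idx] * ds[idx])
    wmean <- wsum / wlen
    rest_len <- total_len - wlen
    rmean <- if (rest_len > 0) (all_sum - wsum) / rest_len else wmean
    thr <- (wmean + rmean) / 2
    df <- intensity[idx[1]] < thr
    dl <- intensity[idx[length(idx)]] < thr
    if (!df && !dl) break
    drop_head <- if (df && dl)
      intensity[idx[1]] <= intensity[idx[length(idx)]] else df
    cand <- if (drop_head) idx[-1] else idx[-length(idx)]
    if (sum(ds[cand]) < fmin * total_len) break
    idx <- cand
  }
  wlen <- sum(ds[idx])
  list(i = idx[1], j = idx[length(idx)], len = wlen,
       mean = sum(intensity[idx] * ds[idx]) / wlen)
}

# exact two-tailed Fisher p by fixed-margin enumeration (probability-mass
# rule, same 1e-7 relative slack as the reference implementations)
fisher_enum <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small, fast simulation config for module tests
quick_sim_config <- function(seed, ...) {
  simulation_config(seed = seed, t_end = 160, lp_onset_mean = 120,
                    lp_onset_sd = 30, compaction_start = 60, ...)
}

# onset-recovery comparison for one rendered movie; returns per-cell truth
# and detected onsets for cells whose true onset is observable given the
# persistence rule
recover_onsets <- function(mov, det_cfg = detection_config()) {
  det <- detect_stack(mov$stack, det_cfg)
  t_end <- max(mov$stack$times)
  fi <- mov$stack$calibration$frame_interval
  horizon <- t_end - (det_cfg$persistence - 1) * fi
  out <- lapply(seq_len(nrow(mov$truth)), function(ci) {
    d <- det[det$cell == ci, ]
    tr <- blastomere_track(d$t_min, d$polarized,
                           cleavage_min = mov$truth$cleavage_min[ci],
                           cell = ci)
    on <- polarization_onset(tr, persistence = det_cfg$persistence)
    data.frame(cell = ci, true = mov$truth$onset_min[ci],
               detected = on$onset_min,
               observable = mov$truth$onset_min[ci] <= horizon)
  })
  do.call(rbind, out)
}

# angular width (degrees) of the arc from `start` counterclockwise to `end`
ang_diff_deg <- function(start, end) ((end - start) %% 360 + 360) %% 360
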