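#' Run the full polarization-analysis pipeline on one embryo movie
#'
#' Executes profile extraction and apical-domain detection for every cell and
#' frame, measures inter-blastomere angles, derives polarization onsets and
#' EP/LP classes, and (when a lineage table is present) computes the
#' division-symmetry and fate contingency statistics. Optionally writes
#' per-stage CSVs, a JSON report and a run log.
#'
#' @param movie a list as returned by [render_embryo_movie()]: `stack`
#'   (an `embryo_stack`), `truth` (per-cell table with `cell` and
#'   `cleavage_min`), optional `lineage`, optional `config`.
#' @param detect_cfg a [detection_config()].
#' @param mode timing mode, `"live"` (reference: each cell's own cleavage) or
#'   `"fixed"` (reference: the embryo's last cleavage).
#' @param out_dir if non-NULL, stage outputs are written here.
#' @return a list: `detection` (per cell/frame calls), `iea` (per pair/frame
#'   angles), `classification` (per cell: onset, min IEA at onset, class,
#'   censored flag), `embryo` (EP status), `stats` (contingency results, when
#'   lineage records are available).
#' @export
run_pipeline <- function(movie, detect_cfg = detection_config(),
                         mode = c("live", "fixed"), out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(movie$stack) || is.null(movie$truth))
    stopf("pre-flight validation: movie must carry 'stack' and 'truth' (cleavage times)")
  stack <- movie$stack
  truth <- movie$truth

  detection <- detect_stack(stack, detect_cfg)

  nt <- dim(stack$intensity)[1]
  iea <- do.call(rbind, lapply(seq_len(nt), function(ti) {
    tab <- measure_ieas(stack, ti)
    if (nrow(tab) == 0L) return(NULL)
    cbind(frame = ti, t_min = stack$times[ti], tab)
  }))

  cls <- classify_all(detection, iea, truth, stack, mode,
                      persistence = detect_cfg$persistence)
  emb <- embryo_ep_status(cls$class)

  stats_rep <- if (!is.null(movie$lineage)) lineage_stats(movie$lineage)

  res <- list(detection = detection, iea = iea, classification = cls,
              embryo = emb, stats = stats_rep)
  if (!is.null(out_dir)) write_pipeline_outputs(res, movie, out_dir, mode)
  res
}

classify_all <- function(detection, iea, truth, stack, mode,
                         persistence = 2L) {
  cells <- sort(unique(detection$cell))
  ref_fixed <- max(truth$cleavage_min)
  min_iea_frame <- function(ci, frames) {
    vapply(frames, function(fr) {
      sub <- iea[iea$frame == fr & (iea$cell_a == ci | iea$cell_b == ci), ]
      if (is.null(sub) || nrow(sub) == 0L || all(is.na(sub$angle_deg)))
        NA_real_ else min(sub$angle_deg, na.rm = TRUE)
    }, numeric(1))
  }
  rows <- lapply(cells, function(ci) {
    det <- detection[detection$cell == ci, ]
    det <- det[order(det$t_min), ]
    track <- blastomere_track(det$t_min, det$polarized,
                              min_iea = min_iea_frame(ci, det$frame),
                              cleavage_min = truth$cleavage_min[truth$cell == ci],
                              cell = ci)
    cl <- classify_polarity(track, mode = mode, reference_min = ref_fixed,
                            persistence = persistence)
    data.frame(cell = ci,
               cleavage_min = attr(track, "cleavage_min"),
               onset_min = cl$onset_min, onset_rel_min = cl$onset_rel_min,
               min_iea_at_onset = cl$min_iea_at_onset,
               class = cl$class, censored = cl$censored)
  })
  do.call(rbind, rows)
}

#' Contingency statistics for a lineage table
#'
#' From per-mother lineage records, computes the EP-vs-LP division-symmetry
#' table (anomalous divisions excluded but counted), the daughter-polarity
#' table, the trophectoderm-fate table, Fisher exact p-values for the
#' symmetry and fate associations, and the binomial independence test on
#' per-embryo EP counts.
#'
#' @param lineage a lineage data.frame from [generate_lineage_table()].
#' @param n_boot bootstrap replicates for the independence test.
#' @return a list of `proportion_table`s, test results and notes.
#' @export
lineage_stats <- function(lineage, n_boot = 2000L) {
  div <- division_symmetry(lineage$d1_polar, lineage$d2_polar)
  ok <- div != "anomalous"
  sym_tab <- proportion_table(lineage$class[ok], div[ok] == "symmetric")

  daughters <- data.frame(
    class = rep(lineage$class, 2L),
    polar = c(lineage$d1_polar, lineage$d2_polar),
    fate = c(te_assignment(lineage$d1_position, lineage$d1_marker),
             te_assignment(lineage$d2_position, lineage$d2_marker)))
  polar_tab <- proportion_table(daughters$class, daughters$polar)
  te_tab <- proportion_table(daughters$class, daughters$fate == "TE")

  to_mat <- function(tab) {
    m <- cbind(tab$successes, tab$n - tab$successes)
    rownames(m) <- tab$group
    m
  }
  fisher_sym <- fisher_exact(to_mat(sym_tab))
  fisher_te <- fisher_exact(to_mat(te_tab))

  ep_counts <- tapply(lineage$ep, lineage$embryo, sum)
  indep <- if (length(ep_counts) >= 10L)
    tryCatch(binomial_independence_test(as.integer(ep_counts),
                                        cells_per_embryo = max(lineage$cell),
                                        n_boot = n_boot),
             error = function(e) list(message = conditionMessage(e)))

  list(symmetry = sym_tab, daughter_polarity = polar_tab, te_fate = te_tab,
       fisher_symmetry = fisher_sym, fisher_te = fisher_te,
       n_anomalous = sum(!ok), independence = indep)
}

write_pipeline_outputs <- function(res, movie, out_dir, mode) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- movie$config
  seed <- if (!is.null(cfg)) cfg$seed else NA
  hash <- config_hash(cfg)
  stamp <- function(df) {
    df$config_hash <- hash
    df$seed <- seed
    df
  }
  utils::write.csv(stamp(res$detection),
                   file.path(out_dir, "detection.csv"), row.names = FALSE)
  if (!is.null(res$iea))
    utils::write.csv(stamp(res$iea), file.path(out_dir, "iea.csv"),
                     row.names = FALSE)
  utils::write.csv(stamp(res$classification),
                   file.path(out_dir, "classification.csv"), row.names = FALSE)
  report <- list(config_hash = hash, seed = seed, mode = mode,
                 embryo = res$embryo)
  if (!is.null(res$stats)) {
    report$stats <- list(
      symmetry = as.list(res$stats$symmetry),
      daughter_polarity = as.list(res$stats$daughter_polarity),
      te_fate = as.list(res$stats$te_fate),
      fisher_symmetry_p = res$stats$fisher_symmetry$p_value,
      fisher_te_p = res$stats$fisher_te$p_value,
      n_anomalous = res$stats$n_anomalous)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(sprintf("blastopol run (%s mode)", mode),
                 sprintf("seed: %s", seed),
                 sprintf("config hash: %s", hash),
                 if (!is.null(cfg)) utils::capture.output(print(cfg)))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

# Polynomial rolling hash (Horner, mod 2^31 - 1) of a serialized object;
# stable across runs for identical configs, dependency-free.
config_hash <- function(x) {
  if (is.null(x)) return("none")
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
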