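test_that("candidate search agrees with brute-force enumeration", {
  cfg <- detection_config()
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(20:120, 1)
    n_runs <- sample(1:3, 1)
    run <- sort(sample.int(n_runs, n, replace = TRUE))
    intensity <- runif(n, 50, 400)
    ds <- rep(1, n)
    prof <- structure(data.frame(arc_um = cumsum(ds), angle_deg = seq(-179, 180, length.out = n),
                                 intensity = intensity, ds_um = ds, run = run),
                      total_length_um = sum(ds),
                      class = c("cortical_profile", "data.frame"))
    circular <- n_runs == 1L
    oracle <- brute_window(intensity, ds, run, sum(ds),
                           cfg$length_fraction_min, cfg$length_fraction_max,
                           tie_tol = cfg$candidate_tie_tol,
                           circular = circular)
    got <- tryCatch(find_candidate_domain(prof, cfg),
                    blastopol_no_candidate = function(e) NULL)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$start, oracle$i)
      expect_equal(got$end, oracle$j)
      expect_equal(got$mean_intensity, oracle$mean, tolerance = 1e-9)
    }
  }
})

test_that("candidate search handles flat, saturated and short profiles", {
  cfg <- detection_config()
  flat <- structure(data.frame(arc_um = 1:100, angle_deg = seq(-179, 180, length.out = 100),
                               intensity = rep(10, 100), ds_um = rep(1, 100),
                               run = rep(1L, 100)),
                    total_length_um = 100,
                    class = c("cortical_profile", "data.frame"))
  cand <- find_candidate_domain(flat, cfg)
  expect_equal(cand$intensity_ratio, 1.0, tolerance = 1e-9)

  # bright arc covering 95% of the profile: candidate capped at 80%
  bright <- flat
  bright$intensity <- c(rep(500, 95), rep(10, 5))
  cand2 <- find_candidate_domain(bright, cfg)
  expect_equal(cand2$length_fraction, cfg$length_fraction_max,
               tolerance = 0.01)

  short <- flat[1:20, ]
  attr(short, "total_length_um") <- 100   # window min 33 > 20 available
  short$run <- rep(1L, 20)
  expect_error(find_candidate_domain(short, cfg),
               class = "blastopol_no_candidate")
})

test_that("the three-criterion rule enforces its length, intensity and depth bounds", {
  cfg <- detection_config()
  mk <- function(frac, ratio, mid = 0, size = 90) {
    # candidate with controllable fraction and ratio on a 100-um profile
    list(start = 1, end = 2, start_deg = mid - size / 2,
         end_deg = mid + size / 2, mean_intensity = ratio,
         length_um = frac * 100, length_fraction = frac,
         intensity_ratio = ratio, domain_size_deg = size, mid_deg = mid,
         wraps = FALSE, total_length_um = 100)
  }
  # ratio 2, fraction 0.5, z-extent 2 slices x 2 um = 4 um: polarized
  call <- apply_domain_criteria(list(mk(0.5, 2), mk(0.5, 2)), cfg, z_step = 2)
  expect_true(call$polarized)
  expect_equal(call$z_extent_um, 4)

  # ratio exactly at threshold: strictly-greater rule rejects
  call2 <- apply_domain_criteria(list(mk(0.5, 1.5), mk(0.5, 1.5)), cfg,
                                 z_step = 2)
  expect_false(call2$polarized)

  # fraction above the 80% cap rejects even at high ratio
  call3 <- apply_domain_criteria(list(mk(0.85, 2), mk(0.85, 2)), cfg,
                                 z_step = 2)
  expect_false(call3$polarized)

  # depth: single passing slice at z_step 2 um misses the 3 um minimum
  call4 <- apply_domain_criteria(list(mk(0.5, 2), NULL), cfg, z_step = 2)
  expect_false(call4$polarized)
  # ... but a single slice with z_step >= 3 um satisfies it (slab thickness)
  call5 <- apply_domain_criteria(list(mk(0.5, 2)), cfg, z_step = 3)
  expect_true(call5$polarized)

  # non-overlapping arcs across z do not form one domain
  call6 <- apply_domain_criteria(list(mk(0.5, 2, mid = -90),
                                      mk(0.5, 2, mid = 90)), cfg, z_step = 2)
  expect_false(call6$polarized)

  expect_error(apply_domain_criteria(list(mk(0.5, 2)), cfg, z_step = NULL),
               "z_step")
})

test_that("domain size in degrees matches arc geometry", {
  expect_equal(domain_size_degrees(start_deg = 10, end_deg = 10), 360)
  expect_equal(domain_size_degrees(start_deg = -90, end_deg = 90), 180)
  expect_equal(domain_size_degrees(start_deg = 170, end_deg = -170), 20)

  # rendered arc of known fraction on an isolated disc
  img <- matrix(100, 161, 161)
  m <- disc_mask(81, 81, 55, n = 161)
  b <- which(m & !disc_mask(81, 81, 53, n = 161), arr.ind = TRUE)
  ang <- atan2(b[, 1] - 81, b[, 2] - 81)
  f <- 0.4
  img[b[abs(ang) <= f * pi, , drop = FALSE]] <- 300
  p <- extract_contact_free_profile(img, m, NULL,
                                    embryo_center = c(y = 81, x = 1))
  cand <- find_candidate_domain(p)
  spacing <- 360 / nrow(p)
  expect_lt(abs(cand$domain_size_deg - f * 360), 2 * spacing + 1)

  unpol <- structure(list(polarized = FALSE), class = "apical_domain_call")
  expect_error(domain_size_degrees(unpol), "not polarized")
})

test_that("apical-nucleus distance recovers constructed offsets", {
  cell <- disc_mask(61, 61, 45)
  # nucleus tangent to the cortex at the domain midpoint (outward = +x)
  nuc_t <- disc_mask(61, 61 + 35, 10)
  d0 <- apical_nucleus_distance(nuc_t, cell, mid_deg = 0,
                                embryo_center = c(y = 61, x = 1))
  expect_lt(d0, 1.5)

  # nucleus placed 5 um short of the cortex
  nuc5 <- disc_mask(61, 61 + 30, 10)
  d5 <- apical_nucleus_distance(nuc5, cell, mid_deg = 0,
                                embryo_center = c(y = 61, x = 1))
  expect_equal(d5, 5, tolerance = 1.1)

  expect_error(apical_nucleus_distance(matrix(FALSE, 5, 5), cell, 0),
               "nucleus mask")
})

test_that("EP-offset nuclei sit closer to the apical surface than LP nuclei", {
  cfg <- quick_sim_config(seed = 13, ep_probability = 0.5,
                          nucleus_offset_ep = 6, nucleus_offset_lp = 0)
  mov <- render_embryo_movie(cfg)
  stk <- mov$stack
  d <- dim(stk$intensity)
  zmid <- which.min(abs(stk$zoff))
  ti <- 2L
  dists <- vapply(seq_len(8), function(ci) {
    lab <- matrix(stk$labels[ti, zmid, , ], d[3], d[4])
    nuc <- matrix(stk$nuclei[ti, zmid, , ], d[3], d[4]) == ci
    apical_nucleus_distance(nuc, lab == ci, mid_deg = 0,
                            pixel_size = stk$calibration$pixel_size,
                            embryo_center = stk$center)
  }, numeric(1))
  ep <- mov$truth$ep
  expect_true(sum(ep) > 0 && sum(!ep) > 0)   # seed fixed: both classes present
  expect_lt(mean(dists[ep]), mean(dists[!ep]))
})

test_that("calls are invariant to gain and 90-degree rotation", {
  cfg <- quick_sim_config(seed = 17, noise_sd = 0)
  mov <- render_embryo_movie(cfg)
  stk <- mov$stack
  d <- dim(stk$intensity)
  zmid <- which.min(abs(stk$zoff))
  ci <- 3L
  ti <- which(stk$times >= mov$truth$onset_min[ci])[1]
  lab <- matrix(stk$labels[ti, zmid, , ], d[3], d[4])
  img <- matrix(stk$intensity[ti, zmid, , ], d[3], d[4])
  base <- find_candidate_domain(extract_contact_free_profile(
    img, lab == ci, lab > 0 & lab != ci, embryo_center = stk$center))

  gain <- find_candidate_domain(extract_contact_free_profile(
    5 * img, lab == ci, lab > 0 & lab != ci, embryo_center = stk$center))
  expect_equal(gain$intensity_ratio, base$intensity_ratio, tolerance = 1e-9)
  expect_equal(gain$length_fraction, base$length_fraction, tolerance = 1e-9)

  rot90 <- function(m) t(m)[, nrow(m):1]
  ctr_rot <- c(y = stk$center[["x"]], x = d[3] + 1 - stk$center[["y"]])
  rot <- find_candidate_domain(extract_contact_free_profile(
    rot90(img), rot90(lab == ci), rot90(lab > 0 & lab != ci),
    embryo_center = ctr_rot))
  expect_equal(rot$intensity_ratio, base$intensity_ratio, tolerance = 0.02)
  expect_equal(rot$length_fraction, base$length_fraction, tolerance = 0.02)
})

test_that("raising rendered enrichment never flips a polarized call off", {
  cfgs <- lapply(c(1.8, 2.5, 4), function(e)
    quick_sim_config(seed = 23, noise_sd = 0, domain_enrichment = e))
  polarized <- vapply(cfgs, function(cfg) {
    mov <- render_embryo_movie(cfg)
    ti <- which(mov$stack$times >= mov$truth$onset_min[1])[1]
    det <- detect_stack(mov$stack, cells = 1L, frames = ti)
    det$polarized[1]
  }, logical(1))
  expect_false(any(diff(polarized) < 0))
  expect_true(all(polarized))
})
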