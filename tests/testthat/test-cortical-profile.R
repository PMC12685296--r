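test_that("cortical enrichment follows (Icortex - Icyto) / Icyto", {
  expect_equal(cortical_enrichment(2.0, 1.0), 1.0)
  expect_equal(cortical_enrichment(1.0, 1.0), 0.0)
  expect_equal(cortical_enrichment(0.5, 1.0), -0.5)
  expect_error(cortical_enrichment(1, 0), "Icytoplasm")
  expect_error(cortical_enrichment(1, -2), "Icytoplasm")
})

test_that("profiles of isolated and touching discs have the right extent", {
  img <- matrix(50, 121, 121)
  m <- disc_mask(61, 61, 40)
  p <- extract_contact_free_profile(img, m, NULL)
  expect_gt(diff(range(p$angle_deg)), 350)          # full 360 degrees
  # arc length close to the analytic circumference
  circ <- 2 * pi * 40
  expect_lt(abs(attr(p, "total_length_um") - circ), nrow(p) * sqrt(2) / 4)

  mb <- disc_mask(61, 61 + 70, 40, n = 181)
  ma <- disc_mask(61, 61, 40, n = 181)
  img2 <- matrix(50, 181, 181)
  p2 <- extract_contact_free_profile(img2, ma, mb)
  gaps <- diff(sort(p2$angle_deg))
  expect_gt(max(gaps), 10)                          # contact removed
  expect_lt(attr(p2, "total_length_um"), attr(p, "total_length_um"))

  # fully enclosed cell: no contact-free boundary
  ring <- disc_mask(61, 61, 50) & !disc_mask(61, 61, 35)
  core <- disc_mask(61, 61, 34)
  expect_error(extract_contact_free_profile(img, core, ring, band_px = 3),
               class = "blastopol_empty_profile")
})

test_that("a rendered half-arc domain shows the configured enrichment", {
  # isolated synthetic cell with a bright arc over exactly half the cortex
  img <- matrix(100, 121, 121)
  m <- disc_mask(61, 61, 45)
  ring <- m & !disc_mask(61, 61, 43)
  b <- which(ring, arr.ind = TRUE)
  ang <- atan2(b[, 1] - 61, b[, 2] - 61)
  img[ring] <- 300
  img[b[abs(ang) <= pi / 2, , drop = FALSE]] <- 600
  p <- extract_contact_free_profile(img, m, NULL,
                                    embryo_center = c(y = 61, x = 1))
  ord <- order(abs(p$angle_deg))
  half <- rep(FALSE, nrow(p))
  half[ord[seq_len(floor(nrow(p) / 2))]] <- TRUE
  ratio <- mean(p$intensity[half]) / mean(p$intensity[!half])
  expect_equal(ratio, 2.0, tolerance = 0.05)

  # full renderer: samples inside the recorded ground-truth arc carry the
  # configured enrichment over the rest of the contact-free cortex
  cfg <- quick_sim_config(seed = 21, noise_sd = 0, domain_enrichment = 2.0,
                          ep_probability = 1)
  mov <- render_embryo_movie(cfg)
  stk <- mov$stack
  d <- dim(stk$intensity)
  zmid <- which.min(abs(stk$zoff))
  ci <- 2L
  ti <- which(stk$times >= mov$truth$onset_min[ci])[1]
  lab <- matrix(stk$labels[ti, zmid, , ], d[3], d[4])
  img2 <- matrix(stk$intensity[ti, zmid, , ], d[3], d[4])
  p2 <- extract_contact_free_profile(img2, lab == ci, lab > 0 & lab != ci,
                                     embryo_center = stk$center)
  gt_half_width <- ang_diff_deg(mov$truth$domain_start_deg[ci],
                                mov$truth$domain_end_deg[ci]) / 2
  # angles are cell-relative (0 = outward), matching the rendered arc centre
  in_dom <- abs(p2$angle_deg) <= gt_half_width - 3
  out_dom <- abs(p2$angle_deg) >= gt_half_width + 8
  ratio2 <- mean(p2$intensity[in_dom]) / mean(p2$intensity[out_dom])
  expect_equal(ratio2, 2.0, tolerance = 0.05)
})

test_that("local polynomial smoothing preserves quadratics and shrinks noise", {
  arc <- seq(0, 50, by = 0.5)
  const <- data.frame(arc_um = arc, intensity = rep(7, length(arc)))
  expect_equal(smooth_profile(const)$intensity, const$intensity)

  quad <- data.frame(arc_um = arc,
                     intensity = 3 + 0.5 * arc - 0.02 * arc^2)
  sm <- smooth_profile(quad)
  expect_equal(sm$intensity, quad$intensity, tolerance = 1e-8)
  # idempotent on polynomials of order <= 2
  expect_equal(smooth_profile(sm)$intensity, sm$intensity, tolerance = 1e-8)

  set.seed(42)
  noise <- data.frame(arc_um = arc, intensity = rnorm(length(arc)))
  expect_lt(var(smooth_profile(noise)$intensity), var(noise$intensity))

  expect_error(smooth_profile(noise[1:2, ]), "at least 3")
  expect_error(smooth_profile(noise[1:10, ], window = 50), "window")
})

test_that("nuclear-cytoplasmic and EP:LP ratios follow their definitions", {
  expect_equal(nuclear_cytoplasmic_ratio(4, 2), 2)
  expect_equal(nuclear_cytoplasmic_ratio(3, 3), 1)
  expect_error(nuclear_cytoplasmic_ratio(1, 0), "INTcytoplasm")

  # rendered nucleus at 3x cytoplasm recovers 3.0
  img <- matrix(100, 121, 121)
  cell <- disc_mask(61, 61, 45)
  nuc <- disc_mask(61, 61, 12)
  img[nuc] <- 300
  ctrl <- cytoplasm_region(cell, nuc, margin_um = 3, area_px = sum(nuc))
  expect_equal(sum(ctrl), sum(nuc))
  expect_equal(nuclear_cytoplasmic_ratio(mean(img[nuc]), mean(img[ctrl])),
               3.0, tolerance = 0.01)

  expect_equal(ep_lp_intensity_ratio(c(1, 1, 1), c(1, 1, 1),
                                     c("EP", "LP", "LP")), 1.0)
  expect_equal(ep_lp_intensity_ratio(c(4, 2, 2), c(1, 1, 1),
                                     c("EP", "LP", "LP")), 2.0)
  expect_error(ep_lp_intensity_ratio(1:3, rep(1, 3), rep("LP", 3)),
               "undefined ratio")

  # random labels on homogeneous cells: mean ratio centres on 1
  set.seed(7)
  ratios <- replicate(2000, {
    cls <- sample(c("EP", rep("LP", 7)))
    ep_lp_intensity_ratio(rep(5, 8), rep(2, 8), cls)
  })
  expect_equal(mean(ratios), 1.0, tolerance = 1e-12)
})

test_that("doublet reporter ratios cancel shared background", {
  t10 <- rep(10, 10)
  expect_equal(cdx2_doublet_ratio(t10, t10, rep(2, 10), division_frame = 10),
               1.0)
  n1 <- seq(2, 4, length.out = 10); n2 <- seq(2, 3.5, length.out = 10)
  bg <- rep(1.5, 10)
  r <- cdx2_doublet_ratio(n1, n2, bg, division_frame = 10)
  expect_equal(cdx2_doublet_ratio(n1, n2, 2 * bg, division_frame = 10), r)
  expect_equal(cdx2_doublet_ratio(n1, n2, bg, division_frame = 10,
                                  ep_cell = 2), 1 / r)
  expect_error(cdx2_doublet_ratio(n1, n2, bg, division_frame = NA),
               "incomplete trace")
  expect_error(cdx2_doublet_ratio(n1, n2, bg, division_frame = 12),
               "incomplete trace")
})

test_that("intensity ratios are invariant to multiplicative gain", {
  img <- matrix(60, 121, 121)
  m <- disc_mask(61, 61, 40)
  b <- which(m & !disc_mask(61, 61, 38), arr.ind = TRUE)
  ang <- atan2(b[, 1] - 61, b[, 2] - 61)
  img[b[abs(ang) < pi * 0.4, , drop = FALSE]] <- 200
  for (gain in c(1, 3.7)) {
    p <- extract_contact_free_profile(gain * img, m, NULL,
                                      embryo_center = c(y = 61, x = 1))
    cand <- find_candidate_domain(p)
    if (gain == 1) ref <- cand$intensity_ratio
    expect_equal(cand$intensity_ratio, ref, tolerance = 1e-9)
  }
  expect_equal(cortical_enrichment(2 * 3, 2 * 1.5),
               cortical_enrichment(3, 1.5))
  expect_equal(nuclear_cytoplasmic_ratio(5 * 4, 5 * 2),
               nuclear_cytoplasmic_ratio(4, 2))
})
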