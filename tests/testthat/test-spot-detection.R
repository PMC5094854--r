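# Plane-level fixtures: constant background 100 with analytic Gaussian
# spots, flat outline mask.

make_plane <- function(nx = 80, ny = 80, bg = 100) matrix(bg, nx, ny)

add_disc <- function(m, cx, cy, r, value) {
  idx <- gonadFISH:::disc_indices(cx, cy, r, nrow(m), ncol(m))
  m[idx] <- value
  m
}

add_gauss <- function(m, cx, cy, amp, sigma = 1.385) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    m[i, j] <- m[i, j] + amp * exp(-((i - cx)^2 + (j - cy)^2) / (2 * sigma^2))
  m
}

test_that("segmentation applies the 1.5x candidate threshold", {
  mask <- matrix(TRUE, 80, 80)
  pp <- probe_params()
  # disc at 2.0x background -> candidate
  m <- add_disc(make_plane(), 40, 40, 3, 200)
  seg <- segment_spot_candidates(m, mask, 100, pp)
  expect_equal(nrow(seg$candidates), 1L)
  # disc at 1.2x background -> below the 1.5x rule, no candidate
  m2 <- add_disc(make_plane(), 40, 40, 3, 120)
  expect_equal(nrow(segment_spot_candidates(m2, mask, 100, pp)$candidates), 0L)
  # blank plane -> empty
  expect_equal(nrow(segment_spot_candidates(make_plane(), mask, 100,
                                            pp)$candidates), 0L)
})

test_that("local peak detection finds isolated PSF centers and no ramps", {
  mask <- matrix(TRUE, 80, 80)
  pp <- probe_params()
  m <- add_gauss(make_plane(), 30.2, 41.7, 300)
  pk <- detect_local_peaks(m, mask, 100, pp)
  expect_equal(nrow(pk), 1L)
  expect_lt(sqrt((pk$cx - 30.2)^2 + (pk$cy - 41.7)^2), 1.5)
  # two spots 10 px apart -> two peaks
  m2 <- add_gauss(m, 40.2, 41.7, 300)
  pk2 <- detect_local_peaks(m2, mask, 100, pp)
  expect_equal(nrow(pk2), 2L)
  # monotone ramp -> no local maxima
  ramp <- matrix(rep(seq(100, 400, length.out = 80), each = 80), 80, 80)
  expect_equal(nrow(detect_local_peaks(ramp, mask, 100, pp)), 0L)
})

test_that("only candidates found by both methods survive", {
  mask <- matrix(TRUE, 80, 80)
  pp <- probe_params()
  m <- add_gauss(make_plane(), 30, 30, 300)
  m <- add_disc(m, 60, 60, 3, 250)
  seg <- segment_spot_candidates(m, mask, 100, pp)
  expect_equal(nrow(seg$candidates), 2L)
  # a peak list holding only the Gaussian spot: the disc candidate (found
  # by segmentation alone) must be dropped
  pk <- detect_local_peaks(m, mask, 100, pp)
  pk1 <- pk[(pk$cx - 30)^2 + (pk$cy - 30)^2 < 9, , drop = FALSE]
  both <- intersect_candidates(seg, pk1, pp$match_radius_px)
  expect_equal(nrow(both), 1L)
  expect_lt(sqrt((both$cx - 30)^2 + (both$cy - 30)^2), 1.5)
  expect_true(all(both$found_by_segmentation) && all(both$found_by_peak))
  # with both peaks present, both candidates are retained
  expect_equal(nrow(intersect_candidates(seg, pk, pp$match_radius_px)), 2L)
  # empty inputs
  blank_seg <- segment_spot_candidates(make_plane(), mask, 100, pp)
  expect_equal(nrow(intersect_candidates(blank_seg, pk, 2)), 0L)
  expect_equal(nrow(intersect_candidates(seg, pk[0, ], 2)), 0L)
})

test_that("the threshold cascade passes good spots and names failures", {
  mask <- matrix(TRUE, 80, 80)
  pp <- probe_params("sygl-1")
  m <- add_gauss(make_plane(), 40, 40, 280)
  seg <- segment_spot_candidates(m, mask, 100, pp)
  cand <- seg$candidates[1, ]
  f <- filter_candidate(cand, seg, m, mask, 100, 100, pp)
  expect_true(f$pass)
  expect_lt(f$p_value, 9e-10)
  # same geometry, peak below the 1.9x local ratio -> local_bg_ratio failure
  m2 <- add_gauss(make_plane(), 40, 40, 85)
  seg2 <- segment_spot_candidates(m2, mask, 100, pp)
  f2 <- filter_candidate(seg2$candidates[1, ], seg2, m2, mask, 100, 100, pp)
  expect_false(f2$pass)
  expect_true("local_bg_ratio" %in% f2$reasons)
  # an elongated bar fails circularity
  m3 <- make_plane()
  m3[38:42, 20:60] <- 300
  seg3 <- segment_spot_candidates(m3, mask, 100, pp)
  f3 <- filter_candidate(seg3$candidates[1, ], seg3, m3, mask, 100, 100, pp)
  expect_true("circularity" %in% f3$reasons)
  # a small 2x2 blob fails the size criterion
  m4 <- make_plane(); m4[40:41, 40:41] <- 500
  seg4 <- segment_spot_candidates(m4, mask, 100, pp)
  f4 <- filter_candidate(seg4$candidates[1, ], seg4, m4, mask, 100, 100, pp)
  expect_true("size" %in% f4$reasons)
  # footprint identical to annulus -> t-test p ~ 1 -> fail
  m5 <- make_plane()
  seg5 <- list(candidates = data.frame(label = 1, area = 16, cx = 40, cy = 40,
                                       peak = 100, mean = 100, sum = 1600,
                                       perimeter = 16, circularity = 1),
               lab = structure(matrix(0L, 80, 80), n = 1L), threshold = 150)
  seg5$lab[38:41, 38:41] <- 1L
  f5 <- filter_candidate(seg5$candidates[1, ], seg5, m5, mask, 100, 100, pp)
  expect_false(f5$pass)
  expect_true("ttest" %in% f5$reasons)
})

test_that("circularity decision is invariant under 90-degree rotation", {
  mask <- matrix(TRUE, 80, 80)
  pp <- probe_params()
  m <- add_gauss(make_plane(), 40, 35, 300)
  m <- add_disc(m, 20, 60, 2.2, 260)
  rot <- t(m[nrow(m):1, ])
  for (plane in list(m, rot)) {
    seg <- segment_spot_candidates(plane, mask, 100, pp)
    expect_equal(sort(round(seg$candidates$circularity, 6)),
                 sort(round(segment_spot_candidates(m, mask, 100,
                                                    pp)$candidates$circularity,
                            6)))
  }
})

test_that("3-D merging links chains and sums intensities", {
  pp <- probe_params()
  cand <- function(cx, cy, int) data.frame(cx = cx, cy = cy, area = 16,
                                           intensity_bg = int)
  # one spot across 5 consecutive planes
  by_plane <- list(cand(40, 40, 5), cand(40.3, 40.1, 10), cand(40, 40, 20),
                   cand(40.2, 39.9, 10), cand(40, 40, 5))
  sp <- merge_spots_3d(by_plane, 0.065, 0.3, pp)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$n_planes, 5L)
  expect_equal(sp$intensity_bg, 50)   # sum of constituents
  # two spots far apart in XY stay separate
  two <- list(rbind(cand(20, 20, 5), cand(60, 60, 7)),
              rbind(cand(20, 20, 5), cand(60, 60, 7)))
  sp2 <- merge_spots_3d(two, 0.065, 0.3, pp)
  expect_equal(nrow(sp2), 2L)
  expect_equal(sort(sp2$intensity_bg), c(10, 14))
  # a gap in planes breaks the chain
  gap <- list(cand(40, 40, 5), NULL, cand(40, 40, 5))
  expect_equal(nrow(merge_spots_3d(gap, 0.065, 0.3, pp)), 2L)
})

test_that("ATS classification follows the three confirmation criteria", {
  pp <- probe_params()
  nuclei <- data.frame(id = 1:2, x = c(5, 12), y = c(5, 5), z = c(3, 3),
                       radius = 2, summed_dapi = 1,
                       distal_distance = c(5, 12), is_dtc = FALSE,
                       n_planes = 9L)
  spot <- function(x, y, z, photo, n_planes = 4, int = 100)
    data.frame(x = x, y = y, z = z, plane_min = 5, plane_max = 5 + n_planes - 1,
               n_planes = n_planes, intensity_bg = int, max_area = 20,
               photometry_bg = photo, channel = "x")
  ref <- 90
  # colocalized nuclear exon+intron, both bright -> ATS
  ats <- classify_ats(spot(5, 5, 3, 1500), spot(5.05, 5, 3.1, 1400),
                      nuclei, pp, ref)
  expect_equal(nrow(ats), 1L)
  expect_equal(ats$nucleus_id, 1L)
  expect_equal(ats$exon_intensity_au, 1500 / ref * 10)
  # intron spot in the cytoplasm -> not ATS
  expect_equal(nrow(classify_ats(spot(5, 5, 3, 1500), spot(8.5, 5, 3, 1400),
                                 nuclei, pp, ref)), 0L)
  # nuclear exon spot with no colocalized intron partner -> not ATS
  expect_equal(nrow(classify_ats(spot(5, 5, 3, 1500),
                                 spot(12, 5, 3, 1400), nuclei, pp, ref)), 0L)
  # dimmer than a single mRNA -> rejected by criterion (3)
  expect_equal(nrow(classify_ats(spot(5, 5, 3, 50), spot(5, 5, 3.1, 1400),
                                 nuclei, pp, ref)), 0L)
  # below the 10x integrated gate -> not even a potential ATS
  expect_equal(nrow(classify_ats(spot(5, 5, 3, 1500, int = 8),
                                 spot(5, 5, 3.1, 1400), nuclei, pp, ref)), 0L)
  # too few planes (< 3) -> not a potential ATS
  expect_equal(nrow(classify_ats(spot(5, 5, 3, 1500, n_planes = 2),
                                 spot(5, 5, 3.1, 1400), nuclei, pp, ref)), 0L)
})

test_that("mRNA calling removes nuclear spots and applies the 20%/2x rules", {
  pp <- probe_params()
  nuclei <- data.frame(id = 1L, x = 5, y = 5, z = 3, radius = 2,
                       summed_dapi = 1, distal_distance = 5, is_dtc = FALSE,
                       n_planes = 9L)
  base <- data.frame(x = seq(10, 19), y = 5, z = 3, plane_min = 5,
                     plane_max = 7, n_planes = 3, intensity_bg = 50,
                     max_area = 20, photometry_bg = 100, channel = "exon")
  # nuclear spot removed
  nuc_spot <- base[1, ]; nuc_spot$x <- 5
  out <- call_mrnas(rbind(base, nuc_spot), nuclei, pp)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$x >= 10))
  # multi-mRNA: >= 2x brighter AND larger
  multi <- base[1, ]; multi$x <- 25
  multi$photometry_bg <- 250; multi$max_area <- 48
  out2 <- call_mrnas(rbind(base, multi), nuclei, pp)
  expect_equal(out2$copy_count[out2$x == 25], 2L)
  expect_true(all(out2$copy_count[out2$x != 25] == 1L))
  # 15% intensity and 15% size -> removed
  dim_small <- base[1, ]; dim_small$x <- 30
  dim_small$photometry_bg <- 15; dim_small$max_area <- 3
  out3 <- call_mrnas(rbind(base, dim_small), nuclei, pp)
  expect_false(30 %in% out3$x)
  # 15% intensity but 150% size -> retained (conjunctive rule)
  dim_big <- base[1, ]; dim_big$x <- 31
  dim_big$photometry_bg <- 15; dim_big$max_area <- 30
  out4 <- call_mrnas(rbind(base, dim_big), nuclei, pp)
  expect_true(31 %in% out4$x)
  # spots spanning one plane are not mRNA candidates
  single <- base; single$n_planes <- 1
  expect_equal(nrow(call_mrnas(single, nuclei, pp)), 0L)
})

test_that("detector meets precision/recall contracts on a tiny stack", {
  sim <- get_tiny_sim()
  res <- get_tiny_result()
  m <- match_spots(res$mrna, sim$truth$mrna, 0.5)
  a <- match_spots(res$ats, sim$truth$ats, 0.5)
  expect_gte(m$precision, 0.90)
  expect_gte(m$recall, 0.88)   # cohort-level >= 0.90 is asserted in acceptance
  expect_gte(a$precision, 0.95)
  expect_gte(a$recall, 0.95)
  # position invariants: ATS inside owner nucleus (+ margin), mRNA outside all
  pp <- probe_params()
  nuc <- res$nuclei
  j <- match(res$ats$nucleus_id, nuc$id)
  d <- sqrt((res$ats$x - nuc$x[j])^2 + (res$ats$y - nuc$y[j])^2 +
              (res$ats$z - nuc$z[j])^2)
  expect_true(all(d <= nuc$radius[j] + pp$ats_nucleus_margin_um + 1e-9))
  own <- gonadFISH:::owning_nucleus(res$mrna$x, res$mrna$y, res$mrna$z, nuc)
  expect_true(all(own == 0L))
})
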