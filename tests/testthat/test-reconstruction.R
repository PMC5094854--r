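test_that("gonad boundary is recovered with IoU >= 0.9 and oriented", {
  sim <- get_tiny_sim()
  spec <- tiny_spec()
  outline <- detect_gonad_boundary(sim$stack)
  expect_s3_class(outline, "gonad_outline")
  expect_equal(outline$distal_end, "left")
  # voxel-wise IoU against the generator's analytic outline
  px <- outline$pixel_xy_um
  d <- dim(outline$mask2d)
  xs <- (seq_len(d[1]) - 0.5) * px
  ys <- (seq_len(d[2]) - 0.5) * px
  hw <- gonad_halfwidth(spec, xs)
  truth2d <- abs(outer(rep(1, d[1]), ys - (spec$radius_max_um + 2))) <=
    outer(hw, rep(1, d[2]))
  iou <- sum(outline$mask2d & truth2d) / sum(outline$mask2d | truth2d)
  expect_gte(iou, 0.9)
})

test_that("a right-rendered stack is reoriented distal-left", {
  sim <- get_tiny_sim()
  flipped <- flip_stack_x(sim$stack)
  outline <- detect_gonad_boundary(flipped)
  expect_equal(outline$distal_end, "right")
  o <- orient_distal_left(flipped, outline)
  expect_equal(o$outline$distal_end, "left")
  expect_equal(o$stack$channels$dapi, sim$stack$channels$dapi)
})

test_that("a blank stack has no detectable boundary", {
  set.seed(4)
  blank <- sim_stack(list(dic = array(rnorm(40 * 30 * 4, 100, 5),
                                      c(40, 30, 4)),
                          dapi = array(50, c(40, 30, 4))),
                     optics_params())
  expect_error(detect_gonad_boundary(blank), "boundary")
})

test_that("plane background estimation matches its contract", {
  m <- matrix(7.5, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  expect_equal(estimate_plane_background(m, mask), 7.5)
  # bright disc excluded automatically
  m2 <- m
  m2[15:20, 15:20] <- 100
  expect_equal(estimate_plane_background(m2, mask), 7.5)
  # explicit exclusion mask
  excl <- matrix(FALSE, 40, 40); excl[15:20, 15:20] <- TRUE
  expect_equal(estimate_plane_background(m2, mask, exclude = excl), 7.5)
  expect_error(estimate_plane_background(m, matrix(FALSE, 40, 40)),
               "background")
})

test_that("signal outside the outline is replaced by plane background", {
  sim <- get_tiny_sim()
  outline <- detect_gonad_boundary(sim$stack)
  st <- sim$stack
  # plant a bright blob outside the mask
  out_col <- which(!outline$mask2d[, 2])[1]
  st$channels$exon[out_col, 2, 3] <- 1e5
  masked <- mask_outside_signal(st, outline)
  expect_equal(masked$channels$exon[out_col, 2, 3],
               masked$plane_bg$exon[3])
  # inside voxels untouched
  ins <- which(outline$mask2d)[100]
  ij <- arrayInd(ins, dim(outline$mask2d))
  expect_equal(masked$channels$exon[ij[1], ij[2], 3],
               st$channels$exon[ij[1], ij[2], 3])
})

test_that("nucleus circles recover a rendered sphere cross-section", {
  spec <- tiny_spec()
  truth <- structure(list(
    spec = spec,
    nuclei = data.frame(id = 1L, x = 10, y = 8, z = 4.5, radius = 2,
                        cycle_stage = "G2", locus_count = 4L, dna_content = 4,
                        is_dtc = FALSE),
    ats = data.frame(kind = character(), x = numeric(), y = numeric(),
                     z = numeric(), owner_id = integer(), load = numeric()),
    mrna = data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), owner_id = integer(), load = numeric())),
    class = "gonad_truth")
  set.seed(2)
  st <- render_stack(truth, optics_params())
  outline <- detect_gonad_boundary(st)
  k <- 15  # central plane (z = 4.35)
  circ <- detect_nucleus_circles(st$channels$dapi[, , k], outline$mask2d,
                                 nucleus_detection_params(),
                                 st$pixel_xy_um)
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$r_um, 2, tolerance = 0.1)
  expect_equal(circ$cx_um, 10, tolerance = 0.1)
  expect_equal(circ$cy_um, 8, tolerance = 0.1)
  # below-threshold plane -> no circles
  flat <- matrix(rnorm(prod(dim(outline$mask2d)), 50, 3),
                 nrow(outline$mask2d))
  expect_equal(nrow(detect_nucleus_circles(flat, outline$mask2d,
                                           nucleus_detection_params(),
                                           st$pixel_xy_um, bg = 50)), 0L)
})

test_that("sphere fitting honors the consecutive-plane and jitter rules", {
  params <- nucleus_detection_params()
  z_step <- 0.3
  # noiseless sphere R = 2 centered at z = 4.5: exact recovery
  planes <- 1:30
  zc <- (planes - 0.5) * z_step
  r2 <- 4 - (zc - 4.5)^2
  sel <- which(r2 > params$radius_range_um[1]^2)
  circles <- rep(list(NULL), 30)
  for (k in sel)
    circles[[k]] <- data.frame(cx_um = 5, cy_um = 5, r_um = sqrt(r2[k]),
                               interior_bg = 9)
  nuc <- reconstruct_nuclei(circles, params, z_step)
  expect_equal(nrow(nuc), 1L)
  expect_equal(nuc$radius, 2, tolerance = 1e-6)
  expect_equal(nuc$x, 5); expect_equal(nuc$y, 5)
  expect_equal(nuc$z, 4.5, tolerance = 1e-6)

  # only 3 consecutive planes -> rejected (needs >= 4)
  circles3 <- rep(list(NULL), 30)
  for (k in 14:16)
    circles3[[k]] <- data.frame(cx_um = 5, cy_um = 5, r_um = 1.8,
                                interior_bg = 9)
  expect_equal(nrow(reconstruct_nuclei(circles3, params, z_step)), 0L)

  # center variation of 0.6 um -> rejected (< 0.5 um required); excessive
  # jitter fragments the chain below the consecutive-plane minimum
  set.seed(9)
  circles_j <- rep(list(NULL), 30)
  for (k in sel) {
    ang <- runif(1, 0, 2 * pi)
    circles_j[[k]] <- data.frame(cx_um = 5 + 0.6 * cos(ang),
                                 cy_um = 5 + 0.6 * sin(ang),
                                 r_um = sqrt(r2[k]), interior_bg = 9)
  }
  expect_equal(nrow(reconstruct_nuclei(circles_j, params, z_step)), 0L)
})

test_that("nuclei are recovered from a rendered tiny gonad", {
  sim <- get_tiny_sim()
  res <- get_tiny_result()
  truth <- sim$truth$nuclei
  det <- res$nuclei
  # >= 95% recovered with center error < 0.5 um, radius error < 20%
  d2 <- outer(det$x, truth$x, "-")^2 + outer(det$y, truth$y, "-")^2 +
    outer(det$z, truth$z, "-")^2
  j <- max.col(-d2)
  err <- sqrt(d2[cbind(seq_len(nrow(det)), j)])
  matched <- err < 0.5
  expect_gte(sum(matched) / nrow(truth), 0.95)
  expect_true(all(abs(det$radius[matched] - truth$radius[j[matched]]) /
                    truth$radius[j[matched]] < 0.2))
  # DNA-content proxy: summed DAPI correlates with truth dna_content
  expect_gt(cor(det$summed_dapi[matched], truth$dna_content[j[matched]]), 0.8)
  # and with the recovered radius
  expect_gt(cor(det$summed_dapi, det$radius), 0.5)
  # all centers inside the gonad mask
  expect_true(all(gonadFISH:::in_outline(res$outline, det$x, det$y)))
})

test_that("detection is deterministic for a fixed stack", {
  sim <- get_tiny_sim()
  cfg <- run_config(spec = tiny_spec())
  outline <- detect_gonad_boundary(sim$stack)
  st <- mask_outside_signal(sim$stack, outline)
  bg <- st$plane_bg$dapi
  c1 <- detect_nucleus_circles(st$channels$dapi[, , 10], outline$mask2d,
                               cfg$nucleus, st$pixel_xy_um, bg = bg[10])
  c2 <- detect_nucleus_circles(st$channels$dapi[, , 10], outline$mask2d,
                               cfg$nucleus, st$pixel_xy_um, bg = bg[10])
  expect_identical(c1, c2)
})

test_that("the DTC nucleus is flagged via GFP overlap and by fallback", {
  # GFP route on a small rendered gonad with a DTC
  d <- get_dtc_sim()
  sim <- d$sim
  res <- get_dtc_result()
  expect_equal(sum(res$nuclei$is_dtc), 1L)
  flagged <- res$nuclei[res$nuclei$is_dtc, ]
  truth_dtc <- sim$truth$nuclei[sim$truth$nuclei$is_dtc, ]
  expect_lt(sqrt(sum((flagged[, c("x", "y", "z")] -
                        truth_dtc[, c("x", "y", "z")])^2)), 1.5)
  # germ nuclei retained
  expect_gte(sum(!res$nuclei$is_dtc),
             0.9 * sum(!sim$truth$nuclei$is_dtc))

  # no GFP channel, no fallback requested -> pass-through
  nuc <- data.frame(id = 1:2, x = c(1, 10), y = c(5, 5), z = c(4, 4),
                    radius = 2, summed_dapi = 1, distal_distance = c(1, 10),
                    is_dtc = FALSE, n_planes = 8L)
  expect_identical(exclude_dtc(nuc), nuc)
  # fallback flags the distal-most nucleus near the cap
  nb <- exclude_dtc(nuc, outline = NULL, fallback = TRUE)
  expect_true(nb$is_dtc[1] && !nb$is_dtc[2])
})
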