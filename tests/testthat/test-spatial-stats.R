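test_that("micron-to-gcd conversion rounds half-up for labels", {
  expect_equal(micron_to_gcd(0)$gcd, 0)
  expect_equal(micron_to_gcd(0)$gcd_label, 0)
  g60 <- micron_to_gcd(60, 4.55)
  expect_equal(g60$gcd, 60 / 4.55)
  expect_equal(g60$gcd_label, 13)     # "roughly 60 um or 13 gcd"
  g30 <- micron_to_gcd(30, 4.55)
  expect_equal(g30$gcd_label, 7)      # "1-30 um (~1-7 gcd)"
  expect_equal(micron_to_gcd(c(20, 45), 4.55)$gcd_label, c(4, 10))
})

test_that("gcd estimation equals the brute-force nearest-neighbor mean", {
  # regular lattice: exact spacing
  g <- expand.grid(x = seq(0, 8, 2), y = seq(0, 8, 2), z = c(0, 2))
  nuc <- data.frame(id = seq_len(nrow(g)), g, is_dtc = FALSE)
  expect_equal(estimate_gcd(nuc)$gcd_um, 2)
  # two nuclei at distance 5
  nuc2 <- data.frame(id = 1:2, x = c(0, 3), y = c(0, 4), z = 0, is_dtc = FALSE)
  expect_equal(estimate_gcd(nuc2)$gcd_um, 5)
  expect_error(estimate_gcd(nuc2[1, ]), ">= 2")
  # random packing vs O(n^2) oracle
  set.seed(12)
  nr <- data.frame(id = 1:40, x = runif(40, 0, 20), y = runif(40, 0, 10),
                   z = runif(40, 0, 10), is_dtc = FALSE)
  oracle <- mean(vapply(1:40, function(i) {
    min(sqrt((nr$x[-i] - nr$x[i])^2 + (nr$y[-i] - nr$y[i])^2 +
               (nr$z[-i] - nr$z[i])^2))
  }, numeric(1)))
  expect_equal(estimate_gcd(nr)$gcd_um, oracle)
  # DTC excluded
  nr$is_dtc[1] <- TRUE
  expect_false(isTRUE(all.equal(estimate_gcd(nr)$gcd_um, oracle)))
})

test_that("gradient profiles average per gonad with cross-gonad SEM", {
  # one gonad, 7 of 10 positive in one bin -> 70%, SEM undefined
  d1 <- data.frame(gonad = 1, distal_distance = rep(2.5, 10))
  p1 <- gradient_profile(d1, c(rep(TRUE, 7), rep(FALSE, 3)), 5, 60)
  expect_equal(p1$value[1], 70)
  expect_true(is.na(p1$sem[1]))
  # two gonads at 60% and 80% -> mean 70, SEM 10
  d2 <- data.frame(gonad = rep(1:2, each = 10), distal_distance = 2.5)
  v2 <- c(rep(TRUE, 6), rep(FALSE, 4), rep(TRUE, 8), rep(FALSE, 2))
  p2 <- gradient_profile(d2, v2, 5, 60)
  expect_equal(p2$value[1], 70)
  expect_equal(p2$sem[1], 10)
  expect_equal(p2$n_gonads[1], 2L)
  # numeric values -> profile of means
  p3 <- gradient_profile(d2, rep(c(2, 4), each = 10), 5, 60)
  expect_equal(p3$value[1], 3)
  # empty bins reported missing
  expect_true(all(is.na(p2$value[-1])))
})

test_that("profiles agree bin-for-bin with an independent recount", {
  set.seed(19)
  n <- 400
  d <- data.frame(gonad = sample(1:4, n, replace = TRUE),
                  distal_distance = runif(n, 0, 60))
  v <- runif(n) < 0.4
  p <- gradient_profile(d, v, 5, 60)
  for (b in seq_len(12)) {
    lo <- (b - 1) * 5; hi <- b * 5
    per_gonad <- vapply(1:4, function(g) {
      sel <- d$gonad == g & d$distal_distance >= lo & d$distal_distance < hi
      if (!any(sel)) NA_real_ else 100 * mean(v[sel])
    }, numeric(1))
    expect_equal(p$value[b], mean(per_gonad, na.rm = TRUE))
  }
})

test_that("region boundary follows the sustained-below-threshold rule", {
  prof <- function(v) data.frame(bin_start = seq(0, by = 5,
                                                 length.out = length(v)),
                                 value = v)
  expect_equal(region_boundary(prof(c(70, 50, 30, 10, 4, 2, 1)))$boundary_um,
               20)
  z <- region_boundary(prof(rep(0, 12)))
  expect_equal(z$boundary_um, 0)
  nv <- region_boundary(prof(rep(50, 12)))
  expect_equal(nv$boundary_um, 60)
  expect_true(nv$flagged)
  # a dip followed by recovery does not end the region
  expect_equal(region_boundary(prof(c(70, 3, 30, 10, 4, 2, 1)))$boundary_um,
               20)
  # monotone non-increasing in the threshold
  v <- c(70, 40, 22, 12, 6, 3, 1.5, 0.5)
  b <- vapply(c(2, 5, 10, 25, 50),
              function(th) region_boundary(prof(v), th)$boundary_um,
              numeric(1))
  expect_true(all(diff(b) <= 0))
})

test_that("contingency test flags association and accepts independence", {
  mk <- function(tab) {
    contacts <- data.frame(nucleus_id = 1:sum(tab),
                           contact_voxels = 0,
                           contact = rep(c(FALSE, FALSE, TRUE, TRUE),
                                         as.integer(tab)))
    quant <- data.frame(id = 1:sum(tab),
                        ats_count = rep(c(0L, 1L, 0L, 1L), as.integer(tab)),
                        distal_distance = 10)
    contact_ats_contingency(contacts, quant)
  }
  perfect <- mk(c(50, 0, 0, 50))
  expect_lt(perfect$p, 0.001)
  indep <- mk(c(25, 25, 25, 25))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p, 1)
  expect_error(mk(c(50, 50, 0, 0)), "empty margin")
})

test_that("Levene and Anderson-Darling match the reference implementations", {
  # frozen oracle values from scipy.stats.levene(center="mean") and
  # statsmodels normal_ad on these exact vectors
  g1 <- c(5.743, 5.543, 4.334, 5.232, 5.117, 5.219, 5.871, 5.224, 5.679,
          5.068, 5.289, 5.631)
  g2 <- c(0.629, 4.041, 3.589, 3.083, 4.175, 9.485, 2.403, 7.905, -0.049,
          3.995, 5.488, 6.759)
  lev <- levene_test(c(g1, g2), rep(1:2, each = 12))
  expect_equal(lev$statistic, 12.079572, tolerance = 1e-6)
  expect_equal(lev$p, 0.00214621, tolerance = 1e-5)

  x1 <- c(10.609, 7.92, 11.501, 11.881, 6.098, 7.396, 10.256, 9.368, 9.966,
          8.294, 11.759, 11.556, 10.132, 12.254, 10.935, 8.281, 10.738,
          8.082, 11.757, 9.9)
  a1 <- ad_test(x1)
  expect_equal(a1$statistic, 0.4901728, tolerance = 1e-5)
  expect_equal(a1$p, 0.1957360, tolerance = 1e-4)
  x2 <- c(2.495, 0.447, 3.676, 2.454, 1.312, 0.834, 0.907, 0.154, 0.359,
          1.371, 0.777, 2.528, 1.417, 0.476, 0.922, 1.283, 0.688, 0.644,
          1.758, 0.594)
  a2 <- ad_test(x2)
  expect_equal(a2$statistic, 0.9012762, tolerance = 1e-5)
  expect_equal(a2$p, 0.01729842, tolerance = 1e-4)
})

test_that("dispatch_test gates on Levene + AD and picks the right test", {
  set.seed(23)
  a <- rnorm(40, 10, 2); b <- rnorm(40, 11, 2)
  r1 <- dispatch_test(list(a = a, b = b))
  expect_equal(r1$test, "t")
  expect_gte(r1$gates$levene_p, 0.05)
  # heavy-tailed group -> nonparametric KS
  h <- rexp(40, 0.2)
  r2 <- dispatch_test(list(a = a, h = h))
  expect_equal(r2$test, "KS")
  expect_true(any(r2$gates$ad_p < 0.05, na.rm = TRUE) ||
                r2$gates$levene_p < 0.05)
  # three well-behaved groups -> ANOVA
  r3 <- dispatch_test(list(a = a, b = b, c = rnorm(40, 10.5, 2)))
  expect_equal(r3$test, "ANOVA")
  # three groups failing gates -> Kruskal-Wallis
  r4 <- dispatch_test(list(a = a, b = b, h = h))
  expect_equal(r4$test, "Kruskal-Wallis")
  expect_error(dispatch_test(list(a = a, b = b[1:2])), "n >= 3")
})

test_that("pairwise ATS correlation symmetrizes and detects independence", {
  ats <- function(ids, vals) data.frame(nucleus_id = ids, x = 0, y = 0, z = 0,
                                        distal_distance = 0,
                                        exon_intensity_au = vals,
                                        intron_intensity_bg = 1,
                                        gene = "sygl-1")
  # identical intensities within each pair -> r = 1
  r1 <- pairwise_ats_correlation(ats(c(1, 1, 2, 2), c(30, 30, 90, 90)))
  expect_equal(r1$statistic, 1)
  # the symmetrized pairs (1,2) and (2,1) -> r = -1
  r2 <- pairwise_ats_correlation(ats(c(1, 1), c(1, 2)))
  expect_equal(r2$statistic, -1)
  expect_equal(nrow(r2$pairs), 2L)
  # independently drawn loads -> |r| < 0.1 at n >= 500
  set.seed(33)
  n <- 600
  big <- ats(rep(seq_len(n), each = 2),
             gonadFISH:::rlnorm_load(2 * n, 17.2, 0.8) * 10)
  r3 <- pairwise_ats_correlation(big)
  expect_gte(r3$n_pairs, 500)
  expect_lt(abs(r3$statistic), 0.1)
  expect_error(pairwise_ats_correlation(ats(1:3, c(1, 2, 3))), ">= 2 ATS")
})

test_that("cv is the sample sd over the mean", {
  expect_equal(cv(rep(4, 10)), 0)
  expect_equal(cv(c(5, 15)), sd(c(5, 15)) / 10)
  expect_equal(round(cv(c(5, 15)), 3), 0.707)
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("half-life fitting recovers exact and simulated decays", {
  f <- fit_halflife(c(0, 60, 120), c(100, 50, 25))
  expect_equal(f$halflife_min, 60, tolerance = 1e-6)
  expect_false(f$flagged)
  # constant counts -> flagged
  expect_true(fit_halflife(c(0, 30, 60), c(80, 80, 80))$flagged)
  # parameter recovery from Bernoulli-thinned counts, half-life 60
  set.seed(41)
  t <- c(0, 15, 30, 60, 120, 180)
  n0 <- 4000
  y <- rbinom(length(t), n0, 2^(-t / 60))
  fr <- fit_halflife(t, y)
  expect_equal(fr$halflife_min, 60, tolerance = 0.1 * 60)
})

test_that("DTC contacts use the strict >10 adjacent-voxel rule", {
  res <- get_dtc_result()
  expect_false(is.null(res$contacts))
  # strict threshold: contact iff contact_voxels > 10
  expect_equal(res$contacts$contact, res$contacts$contact_voxels > 10)
  # distal cells contact the DTC body; distal contact fraction high
  m <- merge(res$contacts, res$nuclei[, c("id", "distal_distance")],
             by.x = "nucleus_id", by.y = "id")
  distal <- m$contact[m$distal_distance < 5]
  expect_gt(mean(distal), 0.6)
  # contact x ATS contingency runs end to end
  ct <- contact_ats_contingency(res$contacts, res$quant$per_nucleus)
  expect_true(is.finite(ct$p))
})
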