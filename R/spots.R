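#' Segment spot candidates in one plane
#'
#' Connected components of pixels above
#' `intron_candidate_bg_ratio_min x background` (the published candidate
#' rule, applied to both probe channels), holes not filled (spots are
#' compact). Components smaller than 2 px are noise and dropped here;
#' the size criterion proper is applied by [filter_candidate()].
#'
#' @param plane Numeric matrix.
#' @param mask2d In-gonad logical mask.
#' @param bg Plane background level.
#' @param params A [probe_params()].
#' @return List with `candidates` (data.frame: label, area, cx, cy, peak,
#'   mean, sum, circularity, found_by_segmentation, found_by_peak) and
#'   `lab` (the label matrix, for footprint lookup).
#' @export
segment_spot_candidates <- function(plane, mask2d, bg, params = probe_params()) {
  thr <- params$intron_candidate_bg_ratio_min * bg
  bw <- plane > thr & mask2d
  lab <- .cc_label(bw)
  st <- component_stats(lab, plane)
  st <- st[st$area >= 2, , drop = FALSE]
  if (nrow(st)) {
    st$found_by_segmentation <- TRUE
    st$found_by_peak <- FALSE
  } else {
    st$found_by_segmentation <- logical(0)
    st$found_by_peak <- logical(0)
  }
  list(candidates = st, lab = lab, threshold = thr)
}

#' Detect spot candidates as smoothed local intensity peaks
#'
#' Gaussian local peak detection: the plane is lightly smoothed
#' (sigma = 1.2 px) and strict 8-neighbor local maxima above the candidate
#' threshold are returned; each peak's footprint is grown to the
#' surrounding super-threshold region.
#'
#' @inheritParams segment_spot_candidates
#' @param seg Optional [segment_spot_candidates()] result; when supplied,
#'   smoothing and maxima search run on padded crops around the
#'   super-threshold components only (identical peaks, much cheaper than a
#'   full-plane convolution, since a smoothed maximum above threshold
#'   cannot occur away from super-threshold pixels).
#' @return Data.frame of peak candidates: `cx, cy, peak,
#'   found_by_segmentation (FALSE), found_by_peak (TRUE)`.
#' @export
detect_local_peaks <- function(plane, mask2d, bg, params = probe_params(),
                               seg = NULL) {
  thr <- params$intron_candidate_bg_ratio_min * bg
  nr <- nrow(plane); nc <- ncol(plane)
  empty <- data.frame(cx = numeric(), cy = numeric(), peak = numeric(),
                      found_by_segmentation = logical(),
                      found_by_peak = logical())
  if (is.null(seg)) {
    sm <- gauss_blur2d(plane, 1.2)
    pk <- local_maxima2d(sm) & sm > thr & mask2d
    idx <- which(pk)
    if (!length(idx)) return(empty)
    return(data.frame(cx = ((idx - 1) %% nr) + 1, cy = ((idx - 1) %/% nr) + 1,
                      peak = plane[idx], found_by_segmentation = FALSE,
                      found_by_peak = TRUE))
  }
  st <- seg$candidates
  if (!nrow(st)) return(empty)
  pad <- 6L
  res <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    r <- ceiling(sqrt(st$area[i] / pi)) + pad
    i0 <- max(1L, floor(st$cx[i] - r)); i1 <- min(nr, ceiling(st$cx[i] + r))
    j0 <- max(1L, floor(st$cy[i] - r)); j1 <- min(nc, ceiling(st$cy[i] + r))
    crop <- plane[i0:i1, j0:j1]
    sm <- gauss_blur2d(crop, 1.2)
    pk <- local_maxima2d(sm) & sm > thr & mask2d[i0:i1, j0:j1]
    # exclude the pad ring so border artifacts of the crop are ignored
    keep <- matrix(FALSE, nrow(pk), ncol(pk))
    bi <- which(i0:i1 >= i0 + (i0 > 1) * 3 & i0:i1 <= i1 - (i1 < nr) * 3)
    bj <- which(j0:j1 >= j0 + (j0 > 1) * 3 & j0:j1 <= j1 - (j1 < nc) * 3)
    keep[bi, bj] <- TRUE
    idx <- which(pk & keep)
    if (!length(idx)) next
    ii <- ((idx - 1) %% nrow(pk)) + i0
    jj <- ((idx - 1) %/% nrow(pk)) + j0
    res[[i]] <- data.frame(cx = ii, cy = jj, peak = plane[cbind(ii, jj)],
                           found_by_segmentation = FALSE, found_by_peak = TRUE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[!duplicated(out[, c("cx", "cy")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect segmentation and peak candidates
#'
#' Only spots identified by both detection methods survive. A segmentation
#' candidate and a peak match when their centroids lie within
#' `radius_px`, or when either centroid falls inside the other's
#' super-threshold footprint (which keeps closely spaced spots whose
#' joint component centroid sits between two peaks). The rule is symmetric
#' in its two inputs.
#'
#' @param seg Result of [segment_spot_candidates()].
#' @param peaks Result of [detect_local_peaks()].
#' @param radius_px Centroid matching radius (px).
#' @return The segmentation candidates found by both methods, with both
#'   provenance flags set.
#' @export
intersect_candidates <- function(seg, peaks, radius_px = 2) {
  st <- seg$candidates
  if (!nrow(st) || !nrow(peaks)) return(st[0, , drop = FALSE])
  lab <- seg$lab
  nr <- nrow(lab)
  peak_lab <- lab[cbind(round(peaks$cx), round(peaks$cy))]
  keep <- vapply(seq_len(nrow(st)), function(i) {
    d <- sqrt((peaks$cx - st$cx[i])^2 + (peaks$cy - st$cy[i])^2)
    any(d <= radius_px) || any(peak_lab == st$label[i])
  }, logical(1))
  out <- st[keep, , drop = FALSE]
  if (nrow(out)) {
    out$found_by_segmentation <- TRUE
    out$found_by_peak <- TRUE
  }
  out
}

# Pooled-variance (Student) two-sample two-sided t-test p-value. The
# pooled test is deliberate: a Gaussian-profile footprint has internal
# variance comparable to its contrast, so a Welch test saturates at
# t ~ sqrt(footprint area) and p < 9e-10 would be unreachable for any
# spot at this PSF size; the pooled test (the MATLAB ttest2 default in
# the original workflow) borrows the annulus' degrees of freedom and
# behaves as the printed threshold requires.
pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(1)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(t), nx + ny - 2)
}

#' Apply the fixed threshold cascade to one plane candidate
#'
#' A candidate passes iff (1) peak / overall background >
#' `overall_bg_ratio_min`; (2) peak / local background >
#' `local_bg_ratio_min`, the local background being the mean of pixels
#' within `local_bg_annulus_factor` x the spot radius of the center
#' (super-threshold pixels and out-of-gonad pixels excluded); (3) a
#' pooled-variance Student t-test of footprint pixels against those
#' local-background pixels gives
#' p < `pixel_ttest_p_max`; (4) the footprint holds at least `min_size_px`
#' pixels; and (5) circularity >= `circularity_min`. All failure reasons
#' are reported.
#'
#' @param cand One-row candidate (from [intersect_candidates()]).
#' @param seg The owning [segment_spot_candidates()] result (for footprint
#'   pixels and the threshold).
#' @param plane,mask2d The plane and in-gonad mask.
#' @param bg Plane background.
#' @param overall_bg Mean background across planes of this channel.
#' @param params A [probe_params()].
#' @return List with `pass` (logical), `reasons` (character vector of
#'   failed criteria), `local_bg`, `p_value`, and `edge_flag` (TRUE when
#'   the annulus was truncated by the image edge).
#' @export
filter_candidate <- function(cand, seg, plane, mask2d, bg, overall_bg,
                             params = probe_params()) {
  lab <- seg$lab
  nr <- nrow(lab); nc <- ncol(lab)
  fp <- plane[lab == cand$label]
  r_spot <- sqrt(cand$area / pi)
  r_ann <- max(4, params$local_bg_annulus_factor * r_spot)
  i0 <- max(1L, floor(cand$cx - r_ann)); i1 <- min(nr, ceiling(cand$cx + r_ann))
  j0 <- max(1L, floor(cand$cy - r_ann)); j1 <- min(nc, ceiling(cand$cy + r_ann))
  edge_flag <- (cand$cx - r_ann < 1) || (cand$cx + r_ann > nr) ||
    (cand$cy - r_ann < 1) || (cand$cy + r_ann > nc)
  box <- plane[i0:i1, j0:j1]
  ann_sel <- mask2d[i0:i1, j0:j1] & box <= seg$threshold
  ann <- box[ann_sel]
  if (length(ann) < 5) {          # degenerate annulus: take what is there
    ann <- box[mask2d[i0:i1, j0:j1]]
    edge_flag <- TRUE
  }
  chk <- check_candidate(fp, ann, cand$peak, cand$area, cand$circularity,
                         overall_bg, params)
  chk$edge_flag <- edge_flag
  chk
}

# Split segmentation components containing two or more detected peaks:
# pixels are reassigned to the nearest peak and per-component statistics
# are rebuilt. Closely spaced spots (a cytoplasmic mRNA against the tail
# of a bright ATS, or two mRNAs in one packet) otherwise fuse into one
# irregular component that the circularity criterion rejects wholesale.
# Peaks closer than `min_sep_px` are counted as one (brightest wins).
split_multi_peak <- function(seg, peaks, plane, min_sep_px = 2) {
  st <- seg$candidates
  if (!nrow(st) || nrow(peaks) < 2) return(seg)
  o <- order(-peaks$peak)
  keep <- logical(nrow(peaks))
  for (i in o) {
    if (!any(keep & (peaks$cx - peaks$cx[i])^2 +
             (peaks$cy - peaks$cy[i])^2 < min_sep_px^2))
      keep[i] <- TRUE
  }
  peaks <- peaks[keep, , drop = FALSE]
  lab <- seg$lab
  plab <- lab[cbind(round(peaks$cx), round(peaks$cy))]
  multi <- as.integer(names(which(table(plab[plab > 0]) >= 2)))
  if (!length(multi)) return(seg)
  nr <- nrow(lab)
  nlab <- attr(lab, "n")
  for (l in multi) {
    idx <- which(lab == l)
    ii <- ((idx - 1) %% nr) + 1
    jj <- ((idx - 1) %/% nr) + 1
    pk <- which(plab == l)
    d2 <- outer(ii, peaks$cx[pk], "-")^2 + outer(jj, peaks$cy[pk], "-")^2
    owner <- max.col(-d2, ties.method = "first")
    newlab <- c(l, nlab + seq_len(length(pk) - 1L))
    nlab <- nlab + length(pk) - 1L
    lab[idx] <- newlab[owner]
  }
  attr(lab, "n") <- nlab
  seg$lab <- lab
  st2 <- component_stats(lab, plane)
  st2 <- st2[st2$area >= 2, , drop = FALSE]
  st2$found_by_segmentation <- rep(TRUE, nrow(st2))
  st2$found_by_peak <- rep(FALSE, nrow(st2))
  seg$candidates <- st2
  seg
}

# shared criterion check for one candidate given its pixel populations;
# the single source of truth for the cascade logic
check_candidate <- function(fp, ann, peak, area, circularity, overall_bg,
                            params) {
  local_bg <- mean(ann)
  p <- pooled_t_p(fp, ann)
  reasons <- character()
  if (!(peak / overall_bg > params$overall_bg_ratio_min))
    reasons <- c(reasons, "overall_bg_ratio")
  if (!(peak / local_bg > params$local_bg_ratio_min))
    reasons <- c(reasons, "local_bg_ratio")
  if (!(is.finite(p) && p < params$pixel_ttest_p_max))
    reasons <- c(reasons, "ttest")
  if (!(area >= params$min_size_px))
    reasons <- c(reasons, "size")
  if (!(circularity >= params$circularity_min))
    reasons <- c(reasons, "circularity")
  list(pass = length(reasons) == 0, reasons = reasons, local_bg = local_bg,
       p_value = p)
}

# full dual-method detection + cascade for one plane; returns passing
# candidates with normalized intensity (background units). Footprint pixel
# lists are materialized once per plane and the local-background window is
# a square box, keeping the per-candidate cost flat.
detect_plane_candidates <- function(plane, mask2d, bg, overall_bg, params) {
  seg <- segment_spot_candidates(plane, mask2d, bg, params)
  if (!nrow(seg$candidates)) return(NULL)
  peaks <- detect_local_peaks(plane, mask2d, bg, params, seg = seg)
  seg <- split_multi_peak(seg, peaks, plane)
  both <- intersect_candidates(seg, peaks, params$match_radius_px)
  if (!nrow(both)) return(NULL)
  lab <- seg$lab
  nr <- nrow(lab); nc <- ncol(lab)
  pos <- which(lab > 0)
  fp_by_label <- split(plane[pos], lab[pos])
  below <- plane <= seg$threshold & mask2d
  cx <- both$cx; cy <- both$cy; area <- both$area
  keep <- logical(nrow(both))
  local_bg <- p_value <- numeric(nrow(both))
  for (i in seq_len(nrow(both))) {
    r_ann <- max(4, params$local_bg_annulus_factor * sqrt(area[i] / pi))
    i0 <- max(1L, floor(cx[i] - r_ann)); i1 <- min(nr, ceiling(cx[i] + r_ann))
    j0 <- max(1L, floor(cy[i] - r_ann)); j1 <- min(nc, ceiling(cy[i] + r_ann))
    box_b <- below[i0:i1, j0:j1]
    ann <- plane[i0:i1, j0:j1][box_b]
    if (length(ann) < 5) ann <- plane[i0:i1, j0:j1][mask2d[i0:i1, j0:j1]]
    chk <- check_candidate(fp_by_label[[as.character(both$label[i])]], ann,
                           both$peak[i], area[i], both$circularity[i],
                           overall_bg, params)
    keep[i] <- chk$pass
    local_bg[i] <- chk$local_bg
    p_value[i] <- chk$p_value
  }
  if (!any(keep)) return(NULL)
  out <- both[keep, c("cx", "cy", "area", "peak", "mean", "sum",
                      "circularity"), drop = FALSE]
  out$local_bg <- local_bg[keep]
  out$p_value <- p_value[keep]
  out$intensity_bg <- (out$sum - out$area * bg) / bg
  out
}

#' Link filtered plane candidates into 3-D spots
#'
#' Candidates on adjacent planes are chained when their XY centroids lie
#' within one spot radius (at least `match_radius_px`). The integrated
#' intensity of a 3-D spot is the sum of its constituent per-plane
#' background-normalized intensities; its centroid is the
#' intensity-weighted mean.
#'
#' @param cands_by_plane List over z of per-plane candidate data.frames
#'   (with `cx, cy, area, intensity_bg`), e.g. from the plane cascade.
#' @param pixel_um XY pixel size, `z_step_um` z spacing (um).
#' @param z_step_um Z-step (um).
#' @param params A [probe_params()].
#' @return Data.frame of 3-D spots: `x, y, z` (um), `plane_min, plane_max,
#'   n_planes, intensity_bg, max_area`.
#' @export
merge_spots_3d <- function(cands_by_plane, pixel_um, z_step_um,
                           params = probe_params()) {
  keep <- !vapply(cands_by_plane, is.null, logical(1))
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      plane_min = integer(), plane_max = integer(),
                      n_planes = integer(), intensity_bg = numeric(),
                      max_area = numeric())
  if (!any(keep)) return(empty)
  all <- do.call(rbind, lapply(which(keep), function(p)
    cbind(plane = p, cands_by_plane[[p]][, c("cx", "cy", "area",
                                             "intensity_bg")])))
  open <- list(); chains <- list()
  for (p in sort(unique(all$plane))) {
    rows <- which(all$plane == p)
    live <- vapply(open, function(ch) ch$last_plane == p - 1L, logical(1))
    if (length(open)) {
      chains <- c(chains, open[!live])
      open <- open[live]
    }
    assigned <- rep(NA_integer_, length(rows))
    if (length(open)) {
      ocx <- vapply(open, `[[`, numeric(1), "cx")
      ocy <- vapply(open, `[[`, numeric(1), "cy")
      orad <- vapply(open, `[[`, numeric(1), "rad")
      dmat <- sqrt(outer(all$cx[rows], ocx, "-")^2 +
                     outer(all$cy[rows], ocy, "-")^2)
      lim <- pmax(params$match_radius_px,
                  outer(sqrt(all$area[rows] / pi), orad, pmax))
      dmat[dmat > lim] <- Inf
      dmat <- matrix(dmat, nrow = length(rows))
      repeat {
        if (all(!is.finite(dmat))) break
        m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = TRUE]
        assigned[m[1]] <- m[2]
        dmat[m[1], ] <- Inf
        dmat[, m[2]] <- Inf
      }
    }
    for (i in seq_along(rows)) {
      r <- rows[i]
      j <- assigned[i]
      if (!is.na(j)) {
        ch <- open[[j]]
        ch$idx <- c(ch$idx, r)
        ch$cx <- all$cx[r]; ch$cy <- all$cy[r]
        ch$rad <- sqrt(all$area[r] / pi)
        ch$last_plane <- p
        open[[j]] <- ch
      } else {
        open[[length(open) + 1L]] <-
          list(last_plane = p, cx = all$cx[r], cy = all$cy[r],
               rad = sqrt(all$area[r] / pi), idx = r)
      }
    }
  }
  chains <- c(chains, open)
  if (!length(chains)) return(empty)
  stats <- vapply(chains, function(ch) {
    idx <- ch$idx
    w <- pmax(all$intensity_bg[idx], 1e-9)
    sw <- sum(w)
    c(sum(all$cx[idx] * w) / sw, sum(all$cy[idx] * w) / sw,
      sum(all$plane[idx] * w) / sw, min(all$plane[idx]), max(all$plane[idx]),
      length(idx), sum(all$intensity_bg[idx]), max(all$area[idx]))
  }, numeric(8))
  out <- data.frame(x = (stats[1, ] - 0.5) * pixel_um,
                    y = (stats[2, ] - 0.5) * pixel_um,
                    z = (stats[3, ] - 0.5) * z_step_um,
                    plane_min = as.integer(stats[4, ]),
                    plane_max = as.integer(stats[5, ]),
                    n_planes = as.integer(stats[6, ]),
                    intensity_bg = stats[7, ], max_area = stats[8, ])
  out
}

#' Fixed-aperture photometry of a 3-D spot
#'
#' Background-subtracted intensity (in background units) summed over a disc
#' of `aperture_px` pixels around the spot center on the centroid plane
#' +/- `aperture_planes` planes. Unlike the threshold-truncated footprint
#' sum, a fixed aperture captures the same PSF fraction for every point
#' source, so the measurement is linear in the underlying load. The default
#' 3 px disc (~2.2 lateral sigma, 90% capture) keeps flux from neighboring
#' spots in dense cytoplasm out of the aperture; contamination there
#' inflates the single-mRNA reference and deflates every ATS/mRNA ratio.
#'
#' @param channel 3-D intensity array.
#' @param x,y,z Spot position (um).
#' @param bg_by_plane Per-plane background vector.
#' @param pixel_um,z_step_um Voxel pitch (um).
#' @param aperture_px Disc radius (px).
#' @param aperture_planes Half-span of planes.
#' @return Photometric intensity in background units.
#' @export
measure_spot_intensity <- function(channel, x, y, z, bg_by_plane, pixel_um,
                                   z_step_um, aperture_px = 3,
                                   aperture_planes = 2) {
  d <- dim(channel)
  cx <- x / pixel_um + 0.5; cy <- y / pixel_um + 0.5
  pz <- round(z / z_step_um + 0.5)
  planes <- max(1, pz - aperture_planes):min(d[3], pz + aperture_planes)
  disc <- disc_indices(cx, cy, aperture_px, d[1], d[2])
  lin <- disc[, 1] + (disc[, 2] - 1) * d[1]
  np <- d[1] * d[2]
  s <- 0
  for (k in planes)
    s <- s + (sum(channel[lin + (k - 1) * np]) -
                nrow(disc) * bg_by_plane[k]) / bg_by_plane[k]
  s
}

#' Detect, filter and assemble 3-D spots in one channel
#'
#' Runs the per-plane dual-method cascade over all z-planes of a channel
#' and merges the survivors into 3-D spots, attaching fixed-aperture
#' photometric intensities.
#'
#' @param stack A `sim_stack` (after [mask_outside_signal()]).
#' @param outline The `gonad_outline`.
#' @param channel Channel name (`"exon"` or `"intron"`).
#' @param params A [probe_params()].
#' @return Data.frame of 3-D spots with columns of [merge_spots_3d()] plus
#'   `photometry_bg` and `channel`.
#' @export
detect_channel_spots <- function(stack, outline, channel,
                                 params = probe_params()) {
  a <- stack$channels[[channel]]
  if (is.null(a)) stop(sprintf("stack has no '%s' channel", channel))
  mask2d <- outline$mask2d
  bgv <- plane_backgrounds(a, mask2d)
  overall_bg <- mean(bgv)
  nz <- dim(a)[3]
  cands <- vector("list", nz)
  for (k in seq_len(nz))
    cands[[k]] <- detect_plane_candidates(a[, , k], mask2d, bgv[k],
                                          overall_bg, params)
  spots <- merge_spots_3d(cands, stack$pixel_xy_um, stack$z_step_um, params)
  if (nrow(spots)) {
    spots$photometry_bg <- vapply(seq_len(nrow(spots)), function(i)
      measure_spot_intensity(a, spots$x[i], spots$y[i], spots$z[i], bgv,
                             stack$pixel_xy_um, stack$z_step_um), numeric(1))
    spots$channel <- channel
  } else {
    spots$photometry_bg <- numeric(0)
    spots$channel <- character(0)
  }
  attr(spots, "overall_bg") <- overall_bg
  spots
}

# id (or 0) of the nucleus sphere containing a point; nearer center wins
# when spheres overlap
owning_nucleus <- function(x, y, z, nuclei, margin_um = 0) {
  if (!nrow(nuclei)) return(rep(0L, length(x)))
  vapply(seq_along(x), function(i) {
    d <- sqrt((nuclei$x - x[i])^2 + (nuclei$y - y[i])^2 + (nuclei$z - z[i])^2)
    inside <- which(d <= nuclei$radius + margin_um)
    if (!length(inside)) 0L else nuclei$id[inside[which.min(d[inside])]]
  }, integer(1))
}

#' Confirm active transcription sites from exon and intron spots
#'
#' A potential ATS (3-D spot spanning >= `ats_min_planes` planes with
#' integrated intensity > `ats_total_bg_ratio_min` x background) is a
#' confirmed ATS iff (1) an intron-channel spot lies inside a nucleus
#' sphere, (2) an exon-channel nuclear spot colocalizes with it within
#' `colocalization_radius_um`, and (3) both photometric intensities are at
#' least as bright as the single-mRNA reference.
#'
#' @param exon_spots,intron_spots Spot tables from [detect_channel_spots()].
#' @param nuclei Nucleus table (germ nuclei; `is_dtc` rows are ignored).
#' @param params A [probe_params()].
#' @param single_mrna_ref Mean photometric intensity of cytoplasmic
#'   single-mRNA spots (background units) in the same gonad.
#' @return Data.frame of ATS records: `nucleus_id, x, y, z,
#'   distal_distance, exon_intensity_au, intron_intensity_bg, gene`,
#'   where `exon_intensity_au` is on the 10-a.u.-per-mRNA scale.
#' @export
classify_ats <- function(exon_spots, intron_spots, nuclei,
                         params = probe_params(), single_mrna_ref) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  empty <- data.frame(nucleus_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), distal_distance = numeric(),
                      exon_intensity_au = numeric(),
                      intron_intensity_bg = numeric(), gene = character(),
                      stringsAsFactors = FALSE)
  gate <- function(s) s[s$n_planes >= params$ats_min_planes &
                          s$intensity_bg > params$ats_total_bg_ratio_min, ,
                        drop = FALSE]
  ex <- gate(exon_spots); it <- gate(intron_spots)
  if (!nrow(ex) || !nrow(it) || !nrow(germ)) return(empty)
  mg <- params$ats_nucleus_margin_um %||% 0
  it$nucleus_id <- owning_nucleus(it$x, it$y, it$z, germ, mg)
  it <- it[it$nucleus_id > 0, , drop = FALSE]
  ex$nucleus_id <- owning_nucleus(ex$x, ex$y, ex$z, germ, mg)
  ex <- ex[ex$nucleus_id > 0, , drop = FALSE]
  if (!nrow(ex) || !nrow(it)) return(empty)
  used_ex <- rep(FALSE, nrow(ex))
  recs <- list()
  for (i in seq_len(nrow(it))) {
    d <- sqrt((ex$x - it$x[i])^2 + (ex$y - it$y[i])^2 + (ex$z - it$z[i])^2)
    d[used_ex] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > params$colocalization_radius_um) next
    if (ex$photometry_bg[j] < single_mrna_ref ||
        it$photometry_bg[i] < single_mrna_ref) next
    used_ex[j] <- TRUE
    recs[[length(recs) + 1L]] <- data.frame(
      nucleus_id = it$nucleus_id[i], x = ex$x[j], y = ex$y[j], z = ex$z[j],
      distal_distance = germ$distal_distance[match(it$nucleus_id[i], germ$id)],
      exon_intensity_au = ex$photometry_bg[j] / single_mrna_ref * 10,
      intron_intensity_bg = it$photometry_bg[i], gene = params$gene,
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Call cytoplasmic mRNA spots
#'
#' Nuclear exon spots are removed first; the remaining 3-D exon spots
#' spanning >= `mrna_min_planes` planes are mRNA candidates. Spots below
#' 20% of the gonad's mean mRNA intensity AND below 20% of the mean mRNA
#' size are removed; spots at least 2 x brighter AND 2 x larger than those
#' means are called as multi-mRNA packets (`copy_count` = rounded
#' intensity/mean, minimum 2), all others carry `copy_count` 1.
#'
#' @param exon_spots Spot table from [detect_channel_spots()].
#' @param nuclei Nucleus table.
#' @param params A [probe_params()].
#' @return Data.frame of mRNA records: `id, x, y, z, distal_distance,
#'   intensity_bg (photometric), size_px, copy_count`.
#' @export
call_mrnas <- function(exon_spots, nuclei, params = probe_params()) {
  s <- exon_spots[exon_spots$n_planes >= params$mrna_min_planes, , drop = FALSE]
  if (nrow(s)) {
    nuc_id <- owning_nucleus(s$x, s$y, s$z, nuclei)
    s <- s[nuc_id == 0, , drop = FALSE]
  }
  if (!nrow(s))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), distal_distance = numeric(),
                      intensity_bg = numeric(), size_px = numeric(),
                      copy_count = integer()))
  mean_int <- mean(s$photometry_bg)
  mean_size <- mean(s$max_area)
  drop <- s$photometry_bg < 0.2 * mean_int & s$max_area < 0.2 * mean_size
  s <- s[!drop, , drop = FALSE]
  multi <- s$photometry_bg >= 2 * mean_int & s$max_area >= 2 * mean_size
  copy <- rep(1L, nrow(s))
  copy[multi] <- pmax(2L, as.integer(round(s$photometry_bg[multi] / mean_int)))
  data.frame(id = seq_len(nrow(s)), x = s$x, y = s$y, z = s$z,
             distal_distance = s$x, intensity_bg = s$photometry_bg,
             size_px = s$max_area, copy_count = copy)
}
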