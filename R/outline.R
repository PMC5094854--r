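#' Detect the gonad boundary from the transmitted-light channel
#'
#' The boundary is estimated from the mean of the central 8 z-planes of the
#' DIC channel (fallback: DAPI if no DIC channel exists): light smoothing,
#' Otsu threshold, largest connected component, hole filling. Because the
#' imaged stack is a central slab of the gonad tube, the 2-D outline is
#' extruded over z to form the 3-D inclusion mask. The distal end is the
#' end with the blunt cap (where the outline width collapses); use
#' `distal_end` to override.
#'
#' @param stack A `sim_stack`.
#' @param distal_end `"auto"`, `"left"` or `"right"`.
#' @return An object of class `gonad_outline`: `mask2d` (nx x ny logical),
#'   per-column boundary (`ymin_px`, `ymax_px`), `distal_end`
#'   (`"left"`/`"right"`), `distal_x_um` (distal tip position on the x
#'   axis), pixel metadata, and `oriented` (TRUE when distal is at low x).
#' @export
detect_gonad_boundary <- function(stack, distal_end = c("auto", "left", "right")) {
  distal_end <- match.arg(distal_end)
  ch <- if (!is.null(stack$channels$dic)) stack$channels$dic else stack$channels$dapi
  if (is.null(ch)) stop("no DIC (or fallback DAPI) channel in stack")
  d <- dim(ch)
  mid <- floor(d[3] / 2)
  planes <- max(1, mid - 3):min(d[3], mid + 4)   # central 8 z-planes
  mimg <- apply(ch[, , planes, drop = FALSE], c(1, 2), mean)
  sm <- gauss_blur2d(mimg, 2)
  thr <- otsu_threshold(sm)
  bw <- sm > thr
  lab <- .cc_label(bw)
  nlab <- attr(lab, "n")
  if (nlab == 0) stop("no closed gonad boundary found (blank image?)")
  areas <- tabulate(lab[lab > 0], nlab)
  if (max(areas) < 0.02 * length(bw))
    stop("no closed gonad boundary found (largest region too small)")
  mask <- .fill_holes(lab == which.max(areas))
  # a real outline separates tissue from slide background; featureless
  # stacks split their noise at Otsu without real contrast
  if (mean(sm[mask]) < 1.2 * mean(sm[!mask]))
    stop("no closed gonad boundary found (insufficient contrast)")

  widths <- rowSums(mask)
  occ <- which(widths > 0)
  if (!length(occ)) stop("no closed gonad boundary found")
  k <- max(3L, round(0.1 * length(occ)))
  w_left <- mean(widths[head(occ, k)])
  w_right <- mean(widths[tail(occ, k)])
  detected <- if (w_left <= w_right) "left" else "right"
  de <- if (distal_end == "auto") detected else distal_end

  ymin <- apply(mask, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  ymax <- apply(mask, 1, function(r) if (any(r)) tail(which(r), 1) else NA_integer_)
  distal_x <- if (de == "left") (occ[1] - 1) * stack$pixel_xy_um
              else occ[length(occ)] * stack$pixel_xy_um
  structure(list(mask2d = mask, ymin_px = ymin, ymax_px = ymax,
                 distal_end = de, distal_x_um = distal_x,
                 pixel_xy_um = stack$pixel_xy_um, z_step_um = stack$z_step_um,
                 dim = d, oriented = de == "left"),
            class = "gonad_outline")
}

#' Orient a stack and its outline distal-left
#'
#' Flips the stack along x when the detected distal end is on the right, so
#' that distal distance is simply the x coordinate.
#'
#' @param stack A `sim_stack`.
#' @param outline A `gonad_outline` from [detect_gonad_boundary()].
#' @return List with `stack` and `outline`, distal end at x = 0.
#' @export
orient_distal_left <- function(stack, outline) {
  if (outline$distal_end == "right") {
    stack <- flip_stack_x(stack)
    nx <- outline$dim[1]
    outline$mask2d <- outline$mask2d[rev(seq_len(nx)), , drop = FALSE]
    outline$ymin_px <- rev(outline$ymin_px)
    outline$ymax_px <- rev(outline$ymax_px)
    occ <- which(rowSums(outline$mask2d) > 0)
    outline$distal_x_um <- (occ[1] - 1) * outline$pixel_xy_um
    outline$distal_end <- "left"
  }
  outline$oriented <- TRUE
  list(stack = stack, outline = outline)
}

#' Estimate the background level of one z-plane
#'
#' Mean intensity of in-gonad pixels away from detected objects. When no
#' explicit object mask is supplied, bright pixels (> 1.5 x the running
#' estimate) are excluded iteratively, which reproduces "a location without
#' nuclei" on DAPI planes and spot-free background on probe channels.
#'
#' @param plane Numeric matrix (one z-plane).
#' @param mask2d Logical in-gonad mask (same dim).
#' @param exclude Optional logical matrix of detected-object footprints to
#'   exclude.
#' @return The background level (strictly positive).
#' @export
estimate_plane_background <- function(plane, mask2d, exclude = NULL) {
  sel <- mask2d
  if (!is.null(exclude)) sel <- sel & !exclude
  v <- plane[sel]
  if (!length(v)) stop("no background pixels available in plane")
  bg <- mean(v)
  if (is.null(exclude)) {
    for (i in 1:2) {
      keep <- v <= 1.5 * bg
      if (!any(keep)) break
      bg <- mean(v[keep])
    }
  }
  if (bg <= 0) stop("non-positive background estimate")
  bg
}

#' Replace signal outside the gonad with the plane background
#'
#' Voxels outside the inclusion mask are set to that plane's in-gonad
#' background estimate, removing non-specific signal outside the tissue;
#' in-mask voxels are untouched.
#'
#' @param stack A `sim_stack`.
#' @param outline A `gonad_outline` for the same stack.
#' @param channels Channel names to mask (default: all fluorescence
#'   channels, i.e. everything except `dic`).
#' @return The masked `sim_stack`.
#' @export
mask_outside_signal <- function(stack, outline,
                                channels = setdiff(names(stack$channels), "dic")) {
  out_idx <- which(!outline$mask2d)
  nz <- dim(stack$channels[[1]])[3]
  np <- length(outline$mask2d)
  stack$plane_bg <- stack$plane_bg %||% list()
  for (nm in channels) {
    a <- stack$channels[[nm]]
    bgv <- plane_backgrounds(a, outline$mask2d)
    stack$plane_bg[[nm]] <- bgv
    if (length(out_idx)) {
      a[rep(out_idx, nz) + rep((seq_len(nz) - 1L) * np, each = length(out_idx))] <-
        rep(bgv, each = length(out_idx))
      stack$channels[[nm]] <- a
    }
  }
  stack
}

# per-plane background levels of one channel (vector over z); in-mask
# pixels are subsampled (<= 50k per plane) — the estimator is a mean over
# ~2e5 i.i.d. pixels, so a stride changes nothing statistically
plane_backgrounds <- function(channel, mask2d) {
  idx <- which(mask2d)
  if (!length(idx)) stop("no background pixels available")
  if (length(idx) > 50000) idx <- idx[seq(1, length(idx), length.out = 50000)]
  np <- length(mask2d)
  vapply(seq_len(dim(channel)[3]), function(k) {
    v <- channel[idx + (k - 1) * np]
    bg <- mean(v)
    for (i in 1:2) {
      keep <- v <= 1.5 * bg
      if (!any(keep)) break
      bg <- mean(v[keep])
    }
    if (bg <= 0) stop("non-positive background estimate")
    bg
  }, numeric(1))
}
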