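#' Detect nuclear cross-section circles in one DAPI plane
#'
#' Pixels above `dapi_threshold_factor` x the automatic (Otsu) in-gonad
#' threshold are labeled into connected components (holes filled, so
#' DAPI-poor nucleolar centers do not split a nucleus); each component in
#' the accepted radius range yields one circle. The circle radius is
#' refined to the half-maximum crossing of the DAPI edge profile, which is
#' unbiased for a sphere rendered with a symmetric edge ramp, unlike the
#' threshold crossing itself.
#'
#' @param plane DAPI z-plane (matrix).
#' @param mask2d In-gonad logical mask.
#' @param params A [nucleus_detection_params()].
#' @param pixel_um XY pixel size (um).
#' @param bg Optional plane background; estimated if `NULL`.
#' @return Data.frame of plane circles: `cx_um, cy_um, r_um, interior_bg`
#'   (mean interior DAPI over background).
#' @export
detect_nucleus_circles <- function(plane, mask2d, params = nucleus_detection_params(),
                                   pixel_um, bg = NULL) {
  if (is.null(bg)) bg <- estimate_plane_background(plane, mask2d)
  v <- plane[mask2d]
  thr <- params$dapi_threshold_factor * otsu_threshold(v)
  bw <- plane > thr & mask2d
  empty <- data.frame(cx_um = numeric(), cy_um = numeric(), r_um = numeric(),
                      interior_bg = numeric())
  if (!any(bw)) return(empty)
  # no global hole filling: a DAPI-poor nucleolar ring stays one component,
  # and the half-max refinement below fills holes on its own small crop
  lab <- .cc_label(bw)
  st <- component_stats(lab, plane)
  if (!nrow(st)) return(empty)
  rmin_px <- params$radius_range_um[1] / pixel_um
  rmax_px <- params$radius_range_um[2] / pixel_um
  st <- st[st$area >= 0.5 * pi * rmin_px^2 & st$area <= 1.8 * pi * rmax_px^2, ,
           drop = FALSE]
  if (!nrow(st)) return(empty)
  nr <- nrow(plane); nc <- ncol(plane)
  m <- nrow(st)
  cx_um <- cy_um <- r_um <- interior_bg <- numeric(m)
  for (i in seq_len(m)) {
    r_eq <- sqrt(st$area[i] / pi)
    cx <- st$cx[i]; cy <- st$cy[i]
    core <- disc_indices(cx, cy, max(2, 0.5 * r_eq), nr, nc)
    # upper-quartile core intensity is robust to the dim nucleolar center
    interior <- unname(stats::quantile(plane[core], 0.75))
    half <- bg + (interior - bg) / 2
    rbox <- min(1.6 * r_eq + 3, 1.6 * rmax_px)
    i0 <- max(1L, floor(cx - rbox)); i1 <- min(nr, ceiling(cx + rbox))
    j0 <- max(1L, floor(cy - rbox)); j1 <- min(nc, ceiling(cy + rbox))
    sub <- plane[i0:i1, j0:j1] > half
    # only the connected region containing this circle's center counts:
    # neighboring nuclear cross-sections inside the box must not inflate
    # the half-max area
    sl <- .cc_label(sub)
    cl <- sl[round(cx) - i0 + 1L, round(cy) - j0 + 1L]
    r_half <- if (cl > 0) sqrt(sum(.fill_holes(sl == cl)) / pi) else r_eq
    cx_um[i] <- (cx - 0.5) * pixel_um
    cy_um[i] <- (cy - 0.5) * pixel_um
    r_um[i] <- r_half * pixel_um
    interior_bg[i] <- mean(plane[core]) / bg
  }
  out <- data.frame(cx_um = cx_um, cy_um = cy_um, r_um = r_um,
                    interior_bg = interior_bg)
  out[out$r_um >= params$radius_range_um[1] &
        out$r_um <= params$radius_range_um[2], , drop = FALSE]
}

#' Reconstruct 3-D nuclei from per-plane circles
#'
#' Circles are grouped into candidate nuclei greedily by nearest XY center
#' between adjacent planes (within `max_center_var_um`). A nucleus is
#' accepted iff its circles span at least `min_consecutive_planes`
#' consecutive planes and the XY spread of centers around their mean stays
#' below `max_center_var_um`. A sphere is then fit by least squares
#' (`r_i^2 = R^2 - (z_i - z0)^2` is linear in `z_i` after moving `z_i^2`
#' across), and total DAPI is integrated within the fitted sphere when the
#' stack is supplied.
#'
#' @param circles_by_plane List (length nz) of data.frames from
#'   [detect_nucleus_circles()].
#' @param params A [nucleus_detection_params()].
#' @param z_step_um Z-plane spacing (um).
#' @param dapi Optional DAPI array for DAPI integration.
#' @param dapi_bg Optional per-plane DAPI backgrounds (vector over z).
#' @param pixel_um XY pixel size (um), required with `dapi`.
#' @return Data.frame of nucleus records: `id, x, y, z, radius,
#'   summed_dapi, distal_distance, is_dtc, n_planes`.
#' @export
reconstruct_nuclei <- function(circles_by_plane, params = nucleus_detection_params(),
                               z_step_um, dapi = NULL, dapi_bg = NULL,
                               pixel_um = NULL) {
  keep_pl <- !vapply(circles_by_plane, function(x) is.null(x) || !nrow(x),
                     logical(1))
  all <- if (any(keep_pl))
    do.call(rbind, lapply(which(keep_pl), function(p)
      cbind(plane = p, circles_by_plane[[p]])))
  else NULL
  chains <- list()
  open <- list()   # each: list(last_plane, cx, cy (running means), idx)
  for (p in seq_along(circles_by_plane)) {
    live <- vapply(open, function(ch) ch$last_plane == p - 1L, logical(1))
    if (length(open)) {
      chains <- c(chains, open[!live])
      open <- open[live]
    }
    if (!keep_pl[p]) next
    rows <- which(all$plane == p)
    assigned_chain <- rep(NA_integer_, length(rows))
    if (length(open)) {
      ocx <- vapply(open, `[[`, numeric(1), "cx")
      ocy <- vapply(open, `[[`, numeric(1), "cy")
      dmat <- sqrt(outer(all$cx_um[rows], ocx, "-")^2 +
                     outer(all$cy_um[rows], ocy, "-")^2)
      dmat <- matrix(dmat, nrow = length(rows))
      repeat {
        m <- which(dmat == min(dmat), arr.ind = TRUE)[1, , drop = TRUE]
        if (!is.finite(dmat[m[1], m[2]]) ||
            dmat[m[1], m[2]] > params$max_center_var_um) break
        assigned_chain[m[1]] <- m[2]
        dmat[m[1], ] <- Inf
        dmat[, m[2]] <- Inf
      }
    }
    for (i in seq_along(rows)) {
      r <- rows[i]
      j <- assigned_chain[i]
      if (!is.na(j)) {
        ch <- open[[j]]
        ch$idx <- c(ch$idx, r)
        ch$cx <- mean(all$cx_um[ch$idx]); ch$cy <- mean(all$cy_um[ch$idx])
        ch$last_plane <- p
        open[[j]] <- ch
      } else {
        open[[length(open) + 1L]] <- list(last_plane = p, cx = all$cx_um[r],
                                          cy = all$cy_um[r], idx = r)
      }
    }
  }
  chains <- c(chains, open)

  recs <- list()
  for (ch in chains) {
    rows <- all[ch$idx, , drop = FALSE]
    if (nrow(rows) < params$min_consecutive_planes) next
    mx <- mean(rows$cx_um); my <- mean(rows$cy_um)
    if (max(sqrt((rows$cx_um - mx)^2 + (rows$cy_um - my)^2)) >
        params$max_center_var_um) next
    zc <- (rows$plane - 0.5) * z_step_um
    u <- rows$r_um^2 + zc^2
    if (nrow(rows) >= 3 && stats::var(zc) > 0) {
      fit <- stats::lm.fit(cbind(1, zc), u)
      z0 <- fit$coefficients[2] / 2
      R2 <- fit$coefficients[1] + z0^2
    } else {
      z0 <- mean(zc); R2 <- max(rows$r_um)^2
    }
    if (!is.finite(R2) || R2 <= 0) next
    R <- sqrt(R2)
    if (R < params$radius_range_um[1] || R > 1.5 * params$radius_range_um[2]) next
    w <- rows$r_um^2
    recs[[length(recs) + 1L]] <-
      c(sum(rows$cx_um * w) / sum(w), sum(rows$cy_um * w) / sum(w),
        z0, R, nrow(rows))
  }
  if (!length(recs))
    return(data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric(), summed_dapi = numeric(),
                      distal_distance = numeric(), is_dtc = logical(),
                      n_planes = integer()))
  rm <- do.call(rbind, recs)
  out <- data.frame(x = rm[, 1], y = rm[, 2], z = rm[, 3], radius = rm[, 4],
                    n_planes = as.integer(rm[, 5]))
  # de-duplicate: keep the record with more planes when two fitted spheres
  # overlap heavily (possible when a chain is split by a missed plane)
  o <- order(-out$n_planes)
  out <- out[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in (i + 1):nrow(out)) {
        if (!keep[j]) next
        dd <- sqrt(sum((out[i, c("x", "y", "z")] - out[j, c("x", "y", "z")])^2))
        if (dd < 0.6 * (out$radius[i] + out$radius[j])) keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$x), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$summed_dapi <- NA_real_
  if (!is.null(dapi)) {
    stopifnot(!is.null(pixel_um), !is.null(dapi_bg))
    d <- dim(dapi)
    for (i in seq_len(nrow(out))) {
      cx <- out$x[i] / pixel_um + 0.5; cy <- out$y[i] / pixel_um + 0.5
      cz <- out$z[i] / z_step_um + 0.5
      rpx <- out$radius[i] / pixel_um; rpz <- out$radius[i] / z_step_um
      ix <- max(1, floor(cx - rpx)):min(d[1], ceiling(cx + rpx))
      iy <- max(1, floor(cy - rpx)):min(d[2], ceiling(cy + rpx))
      iz <- max(1, floor(cz - rpz)):min(d[3], ceiling(cz + rpz))
      dx2 <- (ix - cx)^2; dy2 <- (iy - cy)^2
      s <- 0
      for (k in iz) {
        rz2 <- ((k - cz) * z_step_um / pixel_um)^2
        inside <- outer(dx2, dy2, "+") + rz2 <= rpx^2
        s <- s + sum(dapi[ix, iy, k][inside]) / dapi_bg[k]
      }
      out$summed_dapi[i] <- s
    }
  }
  out$distal_distance <- out$x
  out$is_dtc <- FALSE
  rownames(out) <- NULL
  out[, c("id", "x", "y", "z", "radius", "summed_dapi", "distal_distance",
          "is_dtc", "n_planes")]
}

#' Flag and exclude the distal tip cell nucleus
#'
#' With a GFP channel, the nucleus most completely wrapped by
#' membrane-GFP -- the largest super-threshold fraction in a thin shell
#' just outside the fitted sphere, near the distal cap -- is flagged
#' `is_dtc` (the niche cell body envelops its own nucleus, while germ
#' nuclei only touch processes).
#' Without GFP, an optional positional fallback flags the distal-most
#' nucleus whose center lies within 2 um of the distal cap. Flagged nuclei
#' stay in the table (excluded from germ-cell analyses via `is_dtc`).
#'
#' @param nuclei Nucleus table from [reconstruct_nuclei()].
#' @param stack A `sim_stack` (for the GFP channel), or `NULL`.
#' @param outline A `gonad_outline` (for background estimation).
#' @param fallback Logical: apply the positional heuristic when no GFP
#'   channel exists.
#' @param params A [dtc_params()].
#' @return The nucleus table with `is_dtc` updated.
#' @export
exclude_dtc <- function(nuclei, stack = NULL, outline = NULL, fallback = FALSE,
                        params = dtc_params()) {
  if (!nrow(nuclei)) return(nuclei)
  gfp <- if (!is.null(stack)) stack$channels$gfp else NULL
  if (!is.null(gfp)) {
    stopifnot(!is.null(outline))
    bg <- mean(plane_backgrounds(gfp, outline$mask2d))
    thr <- params$gfp_bg_ratio_min * bg
    px <- stack$pixel_xy_um; dz <- stack$z_step_um
    d <- dim(gfp)
    # restrict to the cell-body region near the distal cap so thin
    # processes do not attract germ nuclei
    body_x_max <- outline$distal_x_um + 6
    shell_um <- 0.5
    frac <- vapply(seq_len(nrow(nuclei)), function(i) {
      if (nuclei$x[i] > body_x_max + nuclei$radius[i]) return(0)
      cx <- nuclei$x[i] / px + 0.5; cy <- nuclei$y[i] / px + 0.5
      cz <- nuclei$z[i] / dz + 0.5
      r_in <- nuclei$radius[i]; r_out <- r_in + shell_um
      rpx <- r_out / px; rpz <- r_out / dz
      ix <- max(1, floor(cx - rpx)):min(d[1], ceiling(cx + rpx))
      iy <- max(1, floor(cy - rpx)):min(d[2], ceiling(cy + rpx))
      iz <- max(1, floor(cz - rpz)):min(d[3], ceiling(cz + rpz))
      tot <- 0; hit <- 0
      for (k in iz) {
        rz2_um <- ((k - cz) * dz)^2
        rr <- sqrt(outer(((ix - cx) * px)^2, ((iy - cy) * px)^2, "+") + rz2_um)
        shell <- rr >= r_in & rr <= r_out
        tot <- tot + sum(shell)
        hit <- hit + sum(gfp[ix, iy, k][shell] > thr)
      }
      if (tot == 0) 0 else hit / tot
    }, numeric(1))
    if (max(frac) > 0.25) nuclei$is_dtc[which.max(frac)] <- TRUE
  } else if (isTRUE(fallback)) {
    distal0 <- if (!is.null(outline)) outline$distal_x_um else min(nuclei$x)
    cand <- which(nuclei$x - distal0 <= 2)
    if (length(cand)) nuclei$is_dtc[cand[which.min(nuclei$x[cand])]] <- TRUE
  }
  nuclei
}
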