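#' Dimensions of the rendered stack for a gonad spec
#'
#' @param spec A [gonad_spec()].
#' @param optics An [optics_params()].
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
stack_dims <- function(spec, optics) {
  c(nx = as.integer(round((spec$length_um + 2 * spec$lead_um) /
                            optics$pixel_xy_um)),
    ny = as.integer(round(2 * (spec$radius_max_um + 2) / optics$pixel_xy_um)),
    nz = as.integer(round(spec$slab_z_um / optics$z_step_um)))
}

#' Construct a multi-channel simulated stack object
#'
#' @param channels Named list of numeric arrays with identical dim.
#' @param optics An [optics_params()].
#' @param distal_end `"left"` or `"right"`.
#' @return An object of class `sim_stack`.
#' @export
sim_stack <- function(channels, optics, distal_end = "left") {
  stopifnot(length(channels) >= 1, !is.null(names(channels)))
  d <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), d))
  structure(list(channels = channels, optics = optics,
                 pixel_xy_um = optics$pixel_xy_um, z_step_um = optics$z_step_um,
                 distal_end = distal_end),
            class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("sim_stack: %d x %d x %d voxels (%.3f um XY, %.2f um Z), channels: %s\n",
              d[1], d[2], d[3], x$pixel_xy_um, x$z_step_um,
              paste(names(x$channels), collapse = "/")))
  invisible(x)
}

# 3-D Gaussian patch with integrated intensity `amp` at physical position
# (x, y, z); returns voxel index ranges plus the patch values, or NULL when
# the patch misses the volume. The caller applies the patch with an
# in-place subassignment (routing the big array through a function call
# would force a full copy per spot).
gaussian_patch <- function(x, y, z, amp, optics, d) {
  px <- optics$pixel_xy_um; dz <- optics$z_step_um
  sx <- optics$psf_sigma_xy_um / px
  sz <- optics$psf_sigma_z_um / dz
  cx <- x / px + 0.5; cy <- y / px + 0.5; cz <- z / dz + 0.5
  r <- ceiling(4 * sx); rz <- ceiling(3.5 * sz)
  ix <- max(1, floor(cx - r)):min(d[1], ceiling(cx + r))
  iy <- max(1, floor(cy - r)):min(d[2], ceiling(cy + r))
  iz <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
  gx <- exp(-((ix - cx)^2) / (2 * sx^2))
  gy <- exp(-((iy - cy)^2) / (2 * sx^2))
  gz <- exp(-((iz - cz)^2) / (2 * sz^2))
  norm <- amp / ((2 * pi)^1.5 * sx * sx * sz)
  list(ix = ix, iy = iy, iz = iz, patch = outer(outer(gx, gy), gz) * norm)
}

#' Render a ground-truth gonad model into a noisy multi-channel stack
#'
#' Forward model: nuclei become filled DAPI spheres (per-voxel density
#' proportional to DNA content over volume, soft edge of width `edge_um`,
#' optional dim nucleolar center); every ATS/mRNA becomes a 3-D Gaussian
#' whose integrated intensity is proportional to its load (exon channel;
#' ATS additionally in the intron channel); the DIC channel carries the
#' gonad outline; the GFP channel carries the DTC arbor when enabled.
#' Channel backgrounds and signal-dependent Gaussian noise are applied last.
#'
#' @param truth A `gonad_truth` from [sample_gonad_truth()].
#' @param optics An [optics_params()].
#' @param distal_end `"left"` (default) or `"right"`.
#' @param noise Logical; overrides `optics$noise`.
#' @return A `sim_stack` with channels `dapi`, `exon`, `intron`, `dic` and,
#'   if the spec has a DTC, `gfp`. Attribute `n_clipped` counts spots whose
#'   centers fell outside the rendered volume (also warned about).
#' @export
render_stack <- function(truth, optics = optics_params(),
                         distal_end = "left", noise = optics$noise) {
  spec <- truth$spec
  d <- stack_dims(spec, optics)
  px <- optics$pixel_xy_um; dz <- optics$z_step_um
  dapi <- array(0, d); exon <- array(0, d); intron <- array(0, d)

  # DAPI spheres
  nuc <- truth$nuclei
  for (i in seq_len(nrow(nuc))) {
    R <- nuc$radius[i]
    cx <- nuc$x[i] / px + 0.5; cy <- nuc$y[i] / px + 0.5; cz <- nuc$z[i] / dz + 0.5
    rpx <- (R + optics$edge_um) / px; rpz <- (R + optics$edge_um) / dz
    ix <- max(1, floor(cx - rpx)):min(d[1], ceiling(cx + rpx))
    iy <- max(1, floor(cy - rpx)):min(d[2], ceiling(cy + rpx))
    iz <- max(1, floor(cz - rpz)):min(d[3], ceiling(cz + rpz))
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- ((ix - cx) * px)^2; dy2 <- ((iy - cy) * px)^2; dz2 <- ((iz - cz) * dz)^2
    rr <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    dens <- optics$dapi_density * (nuc$dna_content[i] / 3) *
      (spec$nucleus_radius_um / R)^3
    f <- pmin(1, pmax(0, (R - rr) / optics$edge_um + 0.5))
    f[rr < optics$nucleolus_rel_radius * R] <- optics$nucleolus_factor
    dapi[ix, iy, iz] <- dapi[ix, iy, iz] + dens * f
  }

  # smFISH spots: patch computation in a helper, application in place here
  n_clipped <- 0L
  spot_jobs <- list(list(df = truth$ats, amp = optics$single_mrna_photon_scale,
                         ch = "exon"),
                    list(df = truth$ats, amp = optics$intron_photon_scale,
                         ch = "intron"),
                    list(df = truth$mrna, amp = optics$single_mrna_photon_scale,
                         ch = "exon"))
  for (job in spot_jobs) {
    df <- job$df
    for (i in seq_len(nrow(df))) {
      if (df$x[i] < 0 || df$x[i] > d[1] * px ||
          df$y[i] < 0 || df$y[i] > d[2] * px ||
          df$z[i] < 0 || df$z[i] > spec$slab_z_um) {
        if (job$ch == "exon") n_clipped <- n_clipped + 1L
        next
      }
      p <- gaussian_patch(df$x[i], df$y[i], df$z[i], df$load[i] * job$amp,
                          optics, d)
      if (is.null(p)) next
      if (job$ch == "exon")
        exon[p$ix, p$iy, p$iz] <- exon[p$ix, p$iy, p$iz] + p$patch
      else
        intron[p$ix, p$iy, p$iz] <- intron[p$ix, p$iy, p$iz] + p$patch
    }
  }
  if (n_clipped > 0)
    warning(sprintf("%d spot(s) outside the rendered volume were clipped",
                    n_clipped))

  # DIC: outline contrast, constant over z
  xs <- (seq_len(d[1]) - 0.5) * px
  ys <- (seq_len(d[2]) - 0.5) * px
  hw <- gonad_halfwidth(spec, xs)
  inside2d <- abs(outer(rep(1, d[1]), ys - (spec$radius_max_um + 2))) <=
    outer(hw, rep(1, d[2]))
  dic <- array(rep(as.numeric(inside2d) * optics$dic_contrast, d[3]), d)

  channels <- list(dapi = dapi, exon = exon, intron = intron, dic = dic)
  if (isTRUE(spec$dtc$enabled))
    channels$gfp <- render_dtc_arbor(spec, optics, d,
                                     nuc[nuc$is_dtc, , drop = FALSE])

  for (nm in names(channels)) {
    bg <- optics$backgrounds[[nm]]
    a <- channels[[nm]] + bg
    if (isTRUE(noise)) {
      a <- a + rnorm(length(a)) * sqrt(optics$noise_gain * a + optics$noise_sd0^2)
      a[a < 0] <- 0
    }
    channels[[nm]] <- a
  }
  st <- sim_stack(channels, optics, distal_end = "left")
  if (distal_end == "right") st <- flip_stack_x(st)
  attr(st, "n_clipped") <- n_clipped
  attr(st, "n_rendered") <- 2L * nrow(truth$ats) + nrow(truth$mrna) - n_clipped
  st
}

# DTC arbor: membrane-GFP cell body wrapping the DTC nucleus (a bright
# shell), a thin cap hugging the distal tissue tip, and straight thin
# processes running proximally through the tissue
render_dtc_arbor <- function(spec, optics, d, dtc_nucleus = NULL) {
  px <- optics$pixel_xy_um; dz <- optics$z_step_um
  yc <- spec$radius_max_um + 2
  a <- array(0, d)
  xs <- (seq_len(d[1]) - 0.5) * px
  ys <- (seq_len(d[2]) - 0.5) * px
  zs <- (seq_len(d[3]) - 0.5) * dz
  # body: a membrane shell around the DTC nucleus
  if (!is.null(dtc_nucleus) && nrow(dtc_nucleus)) {
    cx <- dtc_nucleus$x[1]; cy <- dtc_nucleus$y[1]; cz <- dtc_nucleus$z[1]
    R <- dtc_nucleus$radius[1]
    rout <- R + 1.4
    ix <- which(abs(xs - cx) <= rout); iy <- which(abs(ys - cy) <= rout)
    iz <- which(abs(zs - cz) <= rout)
    if (length(ix) && length(iy) && length(iz)) {
      rr <- sqrt(outer(outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+"),
                       (zs[iz] - cz)^2, "+"))
      sub <- a[ix, iy, iz]
      shell <- rr >= R - 0.2 & rr <= rout
      sub[shell] <- sub[shell] + optics$gfp_density
      a[ix, iy, iz] <- sub
    }
  }
  # thin cap at the distal tissue tip
  bx <- which(xs > spec$lead_um - 0.2 & xs < spec$lead_um + 0.8)
  if (length(bx)) {
    hw <- gonad_halfwidth(spec, xs[bx])
    in2d <- abs(outer(rep(1, length(bx)), ys - yc)) <= outer(hw, rep(1, length(ys)))
    a[bx, , ] <- a[bx, , ] + rep(as.numeric(in2d), d[3]) * optics$gfp_density
  }
  # processes: segments from the cap to (process_length, y_end, z_end)
  np <- spec$dtc$n_processes
  ang <- seq(0, 2 * pi, length.out = np + 1)[seq_len(np)]
  y0 <- yc + 2 * cos(ang); z0 <- spec$slab_z_um / 2 + 1.5 * sin(ang)
  y1 <- yc + (spec$radius_max_um - 2.5) * cos(ang)
  z1 <- pmin(pmax(spec$slab_z_um / 2 + (spec$slab_z_um / 2 - 1.5) * sin(ang), 1),
             spec$slab_z_um - 1)
  rp <- spec$dtc$process_radius_um
  for (k in seq_len(np)) {
    p0 <- c(spec$dtc$body_um * 0.5, y0[k], z0[k])
    p1 <- c(spec$dtc$process_length_um, y1[k], z1[k])
    v <- p1 - p0; L2 <- sum(v^2)
    ix <- which(xs >= min(p0[1], p1[1]) - rp & xs <= max(p0[1], p1[1]) + rp)
    iy <- which(ys >= min(p0[2], p1[2]) - rp & ys <= max(p0[2], p1[2]) + rp)
    iz <- which(zs >= min(p0[3], p1[3]) - rp & zs <= max(p0[3], p1[3]) + rp)
    if (!length(ix) || !length(iy) || !length(iz)) next
    X <- array(xs[ix], c(length(ix), length(iy), length(iz)))
    Y <- aperm(array(ys[iy], c(length(iy), length(ix), length(iz))), c(2, 1, 3))
    Z <- aperm(array(zs[iz], c(length(iz), length(ix), length(iy))), c(2, 3, 1))
    t <- pmin(1, pmax(0, ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] +
                            (Z - p0[3]) * v[3]) / L2))
    d2 <- (X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
      (Z - (p0[3] + t * v[3]))^2
    sub <- a[ix, iy, iz]
    sub[d2 <= rp^2] <- sub[d2 <= rp^2] + optics$gfp_density
    a[ix, iy, iz] <- sub
  }
  a
}

#' Reverse a stack along the distal-proximal (x) axis
#'
#' @param stack A `sim_stack`.
#' @return The flipped `sim_stack` (distal_end label toggled).
#' @export
flip_stack_x <- function(stack) {
  stack$channels <- lapply(stack$channels, function(a) {
    a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  })
  stack$distal_end <- if (identical(stack$distal_end, "left")) "right" else "left"
  stack
}
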