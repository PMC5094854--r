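# point-in-outline query at physical coordinates (um); the outline mask is
# an xy region extruded over z
in_outline <- function(outline, x, y) {
  px <- outline$pixel_xy_um
  i <- pmin(pmax(ceiling(x / px), 1L), nrow(outline$mask2d))
  j <- pmin(pmax(ceiling(y / px), 1L), ncol(outline$mask2d))
  outline$mask2d[cbind(i, j)] & x >= 0 & y >= 0
}

#' Normalize spot intensities to the 10-a.u. single-mRNA scale
#'
#' Rescales all exon-channel intensities of a gonad so that the mean
#' cytoplasmic spot intensity is exactly `mrna_mean_au` (10 a.u.). ATS exon
#' intensities share the same scale (fold over single mRNA x 10); intron
#' intensities stay background-normalized. Idempotent.
#'
#' @param mrna mRNA record table (needs `intensity_bg`).
#' @param ats ATS record table (needs `exon_intensity_au` on any scale
#'   proportional to the exon photometry), may be empty.
#' @param params A [normalization_params()].
#' @return List with `mrna` (gains `intensity_au`), `ats`
#'   (`exon_intensity_au` rescaled) and `scale`.
#' @export
normalize_gonad <- function(mrna, ats, params = normalization_params()) {
  if (!nrow(mrna)) stop("no cytoplasmic mRNA spots: normalization undefined")
  m <- mean(mrna$intensity_bg)
  mrna$intensity_au <- mrna$intensity_bg / m * params$mrna_mean_au
  if (nrow(ats)) {
    # exon_intensity_au was set against the same-gonad mRNA photometric
    # mean, so re-anchoring keeps it consistent under repeated calls
    ats$exon_intensity_au <- ats$exon_intensity_au /
      mean(mrna$intensity_au) * params$mrna_mean_au
  }
  list(mrna = mrna, ats = ats, scale = params$mrna_mean_au / m)
}

#' Build capped 3-D Voronoi germ-cell territories
#'
#' Voxel-level nearest-nucleus labeling of the gonad mask on a regular
#' grid, clipped to `cap_radius_um` around each nucleus center (germ cell
#' boundaries lie midway between neighboring nuclei; cell size is capped
#' at 3 um from the center). In-mask voxels assigned to no nucleus form
#' the rachis.
#'
#' @param nuclei Nucleus table (only `is_dtc == FALSE` rows get cells).
#' @param outline A `gonad_outline`.
#' @param params A [voronoi_params()].
#' @param z_extent_um Z-depth of the volume (um).
#' @return An object of class `voronoi_cells`: list with `grid_um`, voxel
#'   label array `label` (0 = rachis, -1 = outside mask), `cells`
#'   data.frame (`nucleus_id, volume_um3, cyto_volume_um3`),
#'   `rachis_volume_um3`, and grid coordinates.
#' @export
build_voronoi_cells <- function(nuclei, outline, params = voronoi_params(),
                                z_extent_um = NULL) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  if (!nrow(germ)) stop("no germ nuclei to build cells from")
  g <- params$grid_um
  if (is.null(z_extent_um)) z_extent_um <- outline$dim[3] * outline$z_step_um
  nx <- ceiling(nrow(outline$mask2d) * outline$pixel_xy_um / g)
  ny <- ceiling(ncol(outline$mask2d) * outline$pixel_xy_um / g)
  nz <- ceiling(z_extent_um / g)
  xs <- (seq_len(nx) - 0.5) * g
  ys <- (seq_len(ny) - 0.5) * g
  zs <- (seq_len(nz) - 0.5) * g
  inmask2d <- matrix(in_outline(outline, rep(xs, ny), rep(ys, each = nx)),
                     nrow = nx)
  lab <- array(-1L, c(nx, ny, nz))
  lab[rep(as.vector(inmask2d), nz)] <- 0L
  best <- array(Inf, c(nx, ny, nz))
  nucvox <- array(FALSE, c(nx, ny, nz))
  cap2 <- params$cap_radius_um^2
  for (i in seq_len(nrow(germ))) {
    cx <- germ$x[i]; cy <- germ$y[i]; cz <- germ$z[i]
    ix <- which(abs(xs - cx) <= params$cap_radius_um)
    iy <- which(abs(ys - cy) <= params$cap_radius_um)
    iz <- which(abs(zs - cz) <= params$cap_radius_um)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+"), (zs[iz] - cz)^2, "+")
    sub_best <- best[ix, iy, iz]
    sub_lab <- lab[ix, iy, iz]
    upd <- d2 <= cap2 & d2 < sub_best & sub_lab >= 0L
    sub_best[upd] <- d2[upd]
    sub_lab[upd] <- germ$id[i]
    best[ix, iy, iz] <- sub_best
    lab[ix, iy, iz] <- sub_lab
    sub_n <- nucvox[ix, iy, iz]
    sub_n[d2 <= germ$radius[i]^2] <- TRUE
    nucvox[ix, iy, iz] <- sub_n
  }
  vox <- g^3
  ids <- germ$id
  counts <- tabulate(factor(lab[lab > 0L], levels = ids), length(ids))
  cyto <- tabulate(factor(lab[lab > 0L & !nucvox], levels = ids), length(ids))
  cells <- data.frame(nucleus_id = ids, volume_um3 = counts * vox,
                      cyto_volume_um3 = cyto * vox)
  structure(list(grid_um = g, label = lab, cells = cells,
                 rachis_volume_um3 = sum(lab == 0L) * vox,
                 rachis_cyto_volume_um3 = sum(lab == 0L & !nucvox) * vox,
                 xs = xs, ys = ys, zs = zs, nuclei = germ,
                 cap_radius_um = params$cap_radius_um),
            class = "voronoi_cells")
}

#' Brute-force Voronoi labeling oracle
#'
#' Exhaustive per-voxel argmin of center distances with the cap rule;
#' independent of the neighborhood-update implementation in
#' [build_voronoi_cells()]. Intended for small grids.
#'
#' @param nuclei Germ nucleus table.
#' @param inmask Logical 3-D array of in-mask voxels.
#' @param xs,ys,zs Voxel center coordinates (um).
#' @param cap_radius_um Cell cap radius.
#' @return Integer array of labels (0 rachis, -1 outside).
#' @export
voronoi_oracle <- function(nuclei, inmask, xs, ys, zs, cap_radius_um = 3) {
  d <- dim(inmask)
  lab <- array(-1L, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!inmask[i, j, k]) next
    d2 <- (nuclei$x - xs[i])^2 + (nuclei$y - ys[j])^2 + (nuclei$z - zs[k])^2
    m <- which.min(d2)
    lab[i, j, k] <- if (d2[m] <= cap_radius_um^2) nuclei$id[m] else 0L
  }
  lab
}

#' Assign mRNA spots to Voronoi cells
#'
#' Each mRNA is assigned to the cell containing its position (nearest
#' nucleus center within the cap), weighted by `copy_count`; mRNAs nearer
#' than the cap to no nucleus fall in the rachis; mRNAs outside the gonad
#' mask are flagged and unassigned.
#'
#' @param mrna mRNA record table.
#' @param cells A `voronoi_cells` object.
#' @param outline The `gonad_outline` (for the out-of-mask flag).
#' @return List with `mrna` (gains `cell_id`: nucleus id, 0 = rachis, NA =
#'   flagged), `counts` (per-cell copy-weighted counts joined onto the
#'   cells table), `rachis_copies`, `flagged_copies`.
#' @export
assign_mrnas <- function(mrna, cells, outline) {
  germ <- cells$nuclei
  n <- nrow(mrna)
  cell_id <- rep(0L, n)
  if (n) {
    inm <- in_outline(outline, mrna$x, mrna$y)
    for (i in seq_len(n)) {
      if (!inm[i]) { cell_id[i] <- NA_integer_; next }
      d2 <- (germ$x - mrna$x[i])^2 + (germ$y - mrna$y[i])^2 +
        (germ$z - mrna$z[i])^2
      m <- which.min(d2)
      cell_id[i] <- if (d2[m] <= cells$cap_radius_um^2) germ$id[m] else 0L
    }
  }
  mrna$cell_id <- cell_id
  w <- if ("copy_count" %in% names(mrna)) mrna$copy_count else rep(1L, n)
  counts <- cells$cells
  counts$mrna_copies <- vapply(counts$nucleus_id, function(id)
    sum(w[!is.na(cell_id) & cell_id == id]), numeric(1))
  counts$mrna_density <- ifelse(counts$cyto_volume_um3 > 0,
                                counts$mrna_copies / counts$cyto_volume_um3, NA)
  list(mrna = mrna, counts = counts,
       rachis_copies = sum(w[!is.na(cell_id) & cell_id == 0L]),
       flagged_copies = sum(w[is.na(cell_id)]))
}

#' Basal mRNA level of a gonad
#'
#' Mean per-cell mRNA count (and density) over `bin_um` sections of the
#' basal window (40-60 um), where mRNAs are least abundant and no longer
#' graded.
#'
#' @param counts Per-cell table from [assign_mrnas()] joined with nucleus
#'   positions (`distal_distance` column required).
#' @param params A [normalization_params()].
#' @return List with `basal_count`, `basal_density`, `bins` (per-bin
#'   means).
#' @export
compute_basal_level <- function(counts, params = normalization_params()) {
  w <- params$basal_window_um
  edges <- seq(w[1], w[2], by = params$bin_um)
  sel <- counts$distal_distance >= w[1] & counts$distal_distance < w[2]
  if (!any(sel)) stop("no cells in the basal window")
  cc <- counts[sel, , drop = FALSE]
  b <- findInterval(cc$distal_distance, edges, rightmost.closed = FALSE)
  bins <- data.frame(
    bin_start = edges[-length(edges)],
    mean_count = vapply(seq_len(length(edges) - 1), function(i)
      if (any(b == i)) mean(cc$mrna_copies[b == i]) else NA_real_, numeric(1)),
    mean_density = vapply(seq_len(length(edges) - 1), function(i)
      if (any(b == i)) mean(cc$mrna_density[b == i], na.rm = TRUE) else NA_real_,
      numeric(1)))
  list(basal_count = mean(bins$mean_count, na.rm = TRUE),
       basal_density = mean(bins$mean_density, na.rm = TRUE),
       bins = bins)
}

#' mRNA density of a region
#'
#' Count divided by cytoplasmic volume.
#'
#' @param count Total mRNA copies in the region.
#' @param cyto_volume_um3 Cytoplasmic volume of the region (um^3).
#' @return Density (copies / um^3).
#' @export
compute_density <- function(count, cyto_volume_um3) {
  if (cyto_volume_um3 <= 0) stop("region volume must be > 0")
  count / cyto_volume_um3
}

#' Per-nucleus and per-cell quantitation summary
#'
#' Adds per-nucleus ATS counts and summed ATS intensities (pooled a.u.
#' within the same nucleus) and per-cell above-basal flags (strictly more
#' mRNA copies than the basal level).
#'
#' @param nuclei Germ nucleus table.
#' @param ats ATS record table (normalized).
#' @param counts Per-cell count table (from [assign_mrnas()], with
#'   `distal_distance`).
#' @param basal Basal level list from [compute_basal_level()] or `NULL`.
#' @return An object of class `gonad_quant`: list with `per_nucleus`,
#'   `per_cell`, `basal_count`.
#' @export
summarize_nuclei <- function(nuclei, ats, counts = NULL, basal = NULL) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  pn <- germ
  pn$ats_count <- vapply(germ$id, function(id)
    sum(ats$nucleus_id == id), integer(1))
  pn$summed_ats_au <- vapply(germ$id, function(id)
    sum(ats$exon_intensity_au[ats$nucleus_id == id]), numeric(1))
  per_cell <- NULL
  basal_count <- if (!is.null(basal)) basal$basal_count else NA_real_
  if (!is.null(counts)) {
    per_cell <- counts
    per_cell$above_basal <- !is.na(basal_count) &
      per_cell$mrna_copies > basal_count
  }
  structure(list(per_nucleus = pn, per_cell = per_cell,
                 basal_count = basal_count), class = "gonad_quant")
}
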