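#' Specification of a synthetic distal gonad
#'
#' A `gonad_spec` is the stated world the simulator draws from: geometry of
#' the imaged region, nucleus packing, cell-cycle mix, per-locus firing
#' probability profile along the distal-proximal axis, nascent-load
#' distribution at active sites, the cytoplasmic mRNA field, decay half-lives
#' used by the time-course mode, and the optional DTC (niche cell) arbor.
#'
#' The imaged stack is modeled as the central z-slab of the gonad tube (the
#' physical stacks are shallower than the tube diameter), so the in-gonad
#' region is an xy outline -- half-width `radius_max_um` with a blunt distal
#' cap of extent `cap_um` -- extruded over the full z-depth `slab_z_um`.
#'
#' @param length_um Extent of the imaged region along the distal-proximal
#'   axis (um). The distal end is at x = 0.
#' @param radius_max_um Maximum half-width of the gonad outline (um).
#' @param cap_um Extent of the rounded distal cap (um).
#' @param slab_z_um Imaged z-depth (um).
#' @param nucleus_spacing_um Target mean nearest-neighbor distance between
#'   nucleus centers; this is the germ-cell-diameter (gcd) unit, 4.55 um.
#' @param nucleus_radius_um Mean nuclear radius (um); per-nucleus radii scale
#'   with DNA content (volume proportional to C-value) plus lognormal jitter.
#' @param radius_jitter_sd Lognormal sd of the nuclear radius jitter.
#' @param cycle_fractions Named probabilities of G1/S/G2/M; must sum to 1.
#' @param firing_profile List with `p_distal` (per-locus firing probability
#'   at the distal end), `x_half` and `slope_um` (logistic midpoint and scale
#'   of the decline, um). The per-locus probability is
#'   `p(x) = p_distal * (1 + exp(-x_half/slope)) / (1 + exp((x-x_half)/slope))`.
#' @param load_mean,load_cv Mean and coefficient of variation of the
#'   per-ATS nascent-transcript load in single-mRNA equivalents (lognormal,
#'   truncated to load >= 1).
#' @param mrna_profile List with `distal_mean` (expected mRNAs per cell on
#'   the distal plateau), `plateau_um` (plateau extent), `basal_start_um`
#'   (distance at which the field reaches the basal level) and `basal_mean`
#'   (expected mRNAs per cell beyond that).
#' @param mutant List with `positivity_scale` (scale on *nucleus-level* ATS
#'   positivity), `extent_scale` (compression of the firing region) and
#'   `load_scale` (scale on the nascent-load mean). The permissive-temperature
#'   weak-Notch configuration is [q224_spec()].
#' @param mrna_halflife_min,ats_halflife_min Decay half-lives (minutes) used
#'   by [simulate_timecourse()].
#' @param dtc List describing the niche-cell arbor: `enabled`, `body_um`
#'   (cell-body cap extent), `n_processes`, `process_length_um`,
#'   `process_radius_um`.
#' @param nucleus_margin_um Clearance kept between nucleus centers and the
#'   outline / stack faces so rendered spheres stay inside the imaged volume.
#' @param lead_um Imaged slide-background margin beyond each end of the
#'   tissue along x (real stacks image past the tissue tip); structures of
#'   the distal-most cells protruding slightly past the tip stay inside
#'   the rendered volume instead of being clipped.
#'
#' @return An object of class `gonad_spec`.
#' @seealso [q224_spec()], [sample_nuclei()], [simulate_gonad()]
#' @export
gonad_spec <- function(length_um = 60,
                       radius_max_um = 13,
                       cap_um = 4,
                       slab_z_um = 15,
                       nucleus_spacing_um = 4.55,
                       nucleus_radius_um = 2.0,
                       radius_jitter_sd = 0.03,
                       cycle_fractions = c(G1 = 0.04, S = 0.71, G2 = 0.22, M = 0.03),
                       firing_profile = list(p_distal = 0.327, x_half = 15, slope_um = 3.5),
                       load_mean = 17.2,
                       load_cv = 0.8,
                       mrna_profile = list(distal_mean = 15, plateau_um = 20,
                                           basal_start_um = 45, basal_mean = 1),
                       mutant = list(positivity_scale = 1, extent_scale = 1, load_scale = 1),
                       mrna_halflife_min = 60,
                       ats_halflife_min = 10,
                       dtc = list(enabled = FALSE, body_um = 4, n_processes = 8,
                                  process_length_um = 30, process_radius_um = 0.7),
                       nucleus_margin_um = 2.35,
                       lead_um = 3) {
  spec <- structure(
    list(length_um = length_um, radius_max_um = radius_max_um, cap_um = cap_um,
         slab_z_um = slab_z_um, nucleus_spacing_um = nucleus_spacing_um,
         nucleus_radius_um = nucleus_radius_um, radius_jitter_sd = radius_jitter_sd,
         cycle_fractions = cycle_fractions, firing_profile = firing_profile,
         load_mean = load_mean, load_cv = load_cv, mrna_profile = mrna_profile,
         mutant = mutant, mrna_halflife_min = mrna_halflife_min,
         ats_halflife_min = ats_halflife_min, dtc = dtc,
         nucleus_margin_um = nucleus_margin_um, lead_um = lead_um),
    class = "gonad_spec")
  validate_gonad_spec(spec)
  spec
}

#' Validate a gonad specification
#'
#' Checks the type invariants: cell-cycle fractions sum to 1, all
#' probabilities lie in \[0, 1\], all lengths are positive.
#'
#' @param spec A [gonad_spec()].
#' @return `spec`, invisibly; errors if an invariant is violated.
#' @export
validate_gonad_spec <- function(spec) {
  stopifnot(inherits(spec, "gonad_spec"))
  f <- spec$cycle_fractions
  if (length(f) != 4L || is.null(names(f)) ||
      !setequal(names(f), c("G1", "S", "G2", "M")))
    stop("cycle_fractions must be named G1/S/G2/M")
  if (abs(sum(f) - 1) > 1e-9) stop("cycle_fractions must sum to 1")
  if (any(f < 0 | f > 1)) stop("cycle_fractions must lie in [0, 1]")
  p0 <- spec$firing_profile$p_distal
  if (p0 < 0 || p0 > 1) stop("firing_profile$p_distal must lie in [0, 1]")
  if (spec$mutant$positivity_scale < 0 || spec$mutant$positivity_scale > 1)
    stop("mutant$positivity_scale must lie in [0, 1]")
  lens <- c(spec$length_um, spec$radius_max_um, spec$cap_um, spec$slab_z_um,
            spec$nucleus_spacing_um, spec$nucleus_radius_um,
            spec$firing_profile$slope_um, spec$mrna_halflife_min,
            spec$ats_halflife_min)
  if (any(!is.finite(lens)) || any(lens <= 0)) stop("all lengths must be > 0")
  if (spec$load_mean < 1) stop("load distribution support must be >= 1")
  invisible(spec)
}

#' Weak-Notch (glp-1(q224), permissive temperature) gonad configuration
#'
#' Returns the default [gonad_spec()] modified for the weak-NICD mutant:
#' nucleus-level ATS positivity scaled by 0.5, the firing region compressed
#' from 30 um to 20 um, and the mean nascent load halved.
#'
#' @param ... Further arguments passed to [gonad_spec()].
#' @return A `gonad_spec`.
#' @export
q224_spec <- function(...) {
  gonad_spec(mutant = list(positivity_scale = 0.5, extent_scale = 20 / 30,
                           load_scale = 0.5), ...)
}

#' Distribution of target-gene locus counts implied by the cell-cycle mix
#'
#' G1 nuclei carry 2 loci; S-phase nuclei carry 2 + Binomial(2, u) replicated
#' loci with replication progress u ~ U(0,1) (so 2, 3 or 4 with probability
#' 1/3 each); G2 and M nuclei carry 4.
#'
#' @param cycle_fractions Named G1/S/G2/M probabilities.
#' @return Named numeric vector `c("2", "3", "4")` of probabilities.
#' @keywords internal
locus_count_mixture <- function(cycle_fractions) {
  f <- cycle_fractions
  c("2" = unname(f["G1"] + f["S"] / 3),
    "3" = unname(f["S"] / 3),
    "4" = unname(f["G2"] + f["M"] + f["S"] / 3))
}

#' Nucleus-level ATS positivity implied by a per-locus firing probability
#'
#' `P(>=1 ATS) = E_L[1 - (1 - p)^L]` over the locus-count mixture.
#'
#' @param p Per-locus firing probability (vectorized).
#' @param cycle_fractions Named G1/S/G2/M probabilities.
#' @return Probability of at least one ATS in a nucleus.
#' @export
positivity_from_plocus <- function(p, cycle_fractions = c(G1 = 0.04, S = 0.71,
                                                          G2 = 0.22, M = 0.03)) {
  w <- locus_count_mixture(cycle_fractions)
  unname(w["2"] * (1 - (1 - p)^2) + w["3"] * (1 - (1 - p)^3) +
           w["4"] * (1 - (1 - p)^4))
}

#' Per-locus firing probability giving a target nucleus-level positivity
#'
#' Numerical inverse of [positivity_from_plocus()].
#'
#' @param pos Target nucleus-level positivity (vectorized, in \[0, 1)).
#' @param cycle_fractions Named G1/S/G2/M probabilities.
#' @return Per-locus probability.
#' @export
plocus_from_positivity <- function(pos, cycle_fractions = c(G1 = 0.04, S = 0.71,
                                                            G2 = 0.22, M = 0.03)) {
  vapply(pos, function(P) {
    if (P <= 0) return(0)
    if (P >= 1) return(1)
    stats::uniroot(function(p) positivity_from_plocus(p, cycle_fractions) - P,
                   c(0, 1), tol = 1e-10)$root
  }, numeric(1))
}

#' Per-locus firing probability profile of a gonad specification
#'
#' Builds the function `p_locus(x)` from the spec's logistic profile and its
#' mutant configuration. Mutant scaling operates on nucleus-level positivity
#' (inverted through the locus-count mixture) and on the spatial extent.
#'
#' @param spec A [gonad_spec()].
#' @return A function of distal distance x (um) returning the per-locus
#'   firing probability.
#' @export
firing_profile_fun <- function(spec) {
  fp <- spec$firing_profile
  mu <- spec$mutant
  amp <- fp$p_distal * (1 + exp(-fp$x_half / fp$slope_um))
  base <- function(x) amp / (1 + exp((x - fp$x_half) / fp$slope_um))
  if (mu$positivity_scale == 1 && mu$extent_scale == 1) return(base)
  cf <- spec$cycle_fractions
  function(x) {
    p_wt <- base(x / mu$extent_scale)
    plocus_from_positivity(mu$positivity_scale * positivity_from_plocus(p_wt, cf), cf)
  }
}

#' Expected mRNA-per-cell profile of a gonad specification
#'
#' Distal plateau, linear decline, then flat basal level past
#' `basal_start_um`.
#'
#' @param spec A [gonad_spec()].
#' @return A function of distal distance x (um) returning the expected
#'   cytoplasmic mRNA count per cell.
#' @export
mrna_profile_fun <- function(spec) {
  mp <- spec$mrna_profile
  function(x) {
    y <- numeric(length(x))
    y[x <= mp$plateau_um] <- mp$distal_mean
    mid <- x > mp$plateau_um & x < mp$basal_start_um
    frac <- (x[mid] - mp$plateau_um) / (mp$basal_start_um - mp$plateau_um)
    y[mid] <- mp$distal_mean + frac * (mp$basal_mean - mp$distal_mean)
    y[x >= mp$basal_start_um] <- mp$basal_mean
    y
  }
}

#' Gonad outline half-width at a distal distance
#'
#' Blunt elliptical cap of extent `cap_um`, then constant `radius_max_um`.
#'
#' @param spec A [gonad_spec()].
#' @param x Position along the stack x axis (um), vectorized; the tissue
#'   tip sits at `x = lead_um`.
#' @return Half-width of the gonad outline (um); 0 outside the tissue.
#' @export
gonad_halfwidth <- function(spec, x) {
  halfwidth_tissue(spec, x - spec$lead_um)
}

# half-width as a function of tissue distal distance (tip at 0)
halfwidth_tissue <- function(spec, u) {
  h <- rep(spec$radius_max_um, length(u))
  cap <- u < spec$cap_um
  h[cap] <- spec$radius_max_um *
    sqrt(pmax(0, 1 - ((spec$cap_um - u[cap]) / spec$cap_um)^2))
  h[u < 0 | u > spec$length_um] <- 0
  h
}

#' Optical/rendering parameters for the forward model
#'
#' Defaults place the rendered single-mRNA footprint at roughly 4 x 4 px
#' (XY pixel 0.065 um, PSF sigma 0.09 um laterally and 0.35 um axially,
#' z-step 0.3 um). Noise is signal-dependent Gaussian:
#' `sd = sqrt(gain * I + sd0^2)`.
#'
#' @param pixel_xy_um XY pixel size (um).
#' @param z_step_um Z-step between planes (um).
#' @param psf_sigma_xy_um,psf_sigma_z_um Gaussian PSF sigmas (um).
#' @param backgrounds Named per-channel background levels (photon a.u.).
#' @param noise_gain,noise_sd0 Signal-dependent and additive noise terms.
#' @param single_mrna_photon_scale Integrated photons rendered per
#'   single-mRNA equivalent in the exon channel.
#' @param intron_photon_scale Integrated photons per load unit in the intron
#'   channel.
#' @param dapi_density DAPI photon density added inside a 2C..4C-scaled
#'   nucleus (per-voxel, before noise); constant across cycle stages because
#'   nuclear volume scales with DNA content.
#' @param nucleolus_factor,nucleolus_rel_radius Dimming factor and relative
#'   radius of the DAPI-poor nucleolar center.
#' @param edge_um Width of the linear intensity ramp at the nucleus edge,
#'   centered on the true radius (a stand-in for PSF blurring of the
#'   sphere boundary).
#' @param dic_contrast Excess DIC intensity inside the gonad outline.
#' @param gfp_density GFP photon density inside the DTC arbor.
#' @param noise Logical; render noise (disable for linearity checks).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(pixel_xy_um = 0.065,
                          z_step_um = 0.3,
                          psf_sigma_xy_um = 0.09,
                          psf_sigma_z_um = 0.35,
                          backgrounds = c(dapi = 50, exon = 100, intron = 100,
                                          gfp = 80, dic = 100),
                          noise_gain = 1,
                          noise_sd0 = 3,
                          single_mrna_photon_scale = 9000,
                          intron_photon_scale = 9000,
                          dapi_density = 420,
                          nucleolus_factor = 0.75,
                          nucleolus_rel_radius = 0.35,
                          edge_um = 0.25,
                          dic_contrast = 100,
                          gfp_density = 400,
                          noise = TRUE) {
  stopifnot(pixel_xy_um > 0, z_step_um > 0, psf_sigma_xy_um > 0,
            psf_sigma_z_um > 0, all(backgrounds >= 0))
  structure(list(pixel_xy_um = pixel_xy_um, z_step_um = z_step_um,
                 psf_sigma_xy_um = psf_sigma_xy_um, psf_sigma_z_um = psf_sigma_z_um,
                 backgrounds = backgrounds, noise_gain = noise_gain,
                 noise_sd0 = noise_sd0,
                 single_mrna_photon_scale = single_mrna_photon_scale,
                 intron_photon_scale = intron_photon_scale,
                 dapi_density = dapi_density, nucleolus_factor = nucleolus_factor,
                 nucleolus_rel_radius = nucleolus_rel_radius, edge_um = edge_um,
                 dic_contrast = dic_contrast, gfp_density = gfp_density,
                 noise = noise),
            class = "optics_params")
}

#' Spot-detection thresholds for a probe set
#'
#' The published fixed threshold cascade. Per-plane candidates must satisfy:
#' peak/overall-background > `overall_bg_ratio_min`, peak/local-background >
#' `local_bg_ratio_min`, Welch t-test of footprint versus local-annulus
#' pixels with p < `pixel_ttest_p_max`, footprint size > 3 x 3 px
#' (`min_size_px`) and circularity >= `circularity_min`. Candidate
#' segmentation uses `intron_candidate_bg_ratio_min` x background; assembled
#' 3-D ATS candidates must additionally exceed
#' `ats_total_bg_ratio_min` x background in integrated intensity.
#'
#' @param gene `"sygl-1"` or `"lst-1"`; selects the published per-gene
#'   ratio/p-value constants.
#' @param overall_bg_ratio_min,local_bg_ratio_min,pixel_ttest_p_max Per-gene
#'   cascade constants (overridable).
#' @param min_size_px Minimum footprint pixel count (> 3 x 3 px).
#' @param circularity_min Minimum circularity `4*pi*area/perimeter^2`.
#' @param intron_candidate_bg_ratio_min Segmentation threshold factor over
#'   plane background (both channels).
#' @param ats_total_bg_ratio_min Integrated-intensity gate for potential ATS.
#' @param colocalization_radius_um Max exon-intron centroid distance for ATS
#'   confirmation.
#' @param local_bg_annulus_factor Local background is measured in a box
#'   extending this multiple of the spot extent from the center.
#' @param match_radius_px Centroid tolerance when intersecting the two
#'   detection methods.
#' @param mrna_min_planes,ats_min_planes Minimum contiguous plane span for an
#'   assembled cytoplasmic mRNA / nuclear ATS candidate.
#' @param ats_nucleus_margin_um Boundary tolerance when testing whether a
#'   potential ATS lies inside a nucleus sphere (fitted nuclear radii carry
#'   about one DAPI-edge-width of uncertainty and peripheral chromatin loci
#'   sit at the envelope); mRNA removal uses the strict sphere.
#' @return An object of class `probe_params`.
#' @export
probe_params <- function(gene = c("sygl-1", "lst-1"),
                         overall_bg_ratio_min = NULL,
                         local_bg_ratio_min = NULL,
                         pixel_ttest_p_max = NULL,
                         min_size_px = 9,
                         circularity_min = 0.7,
                         intron_candidate_bg_ratio_min = 1.5,
                         ats_total_bg_ratio_min = 10,
                         colocalization_radius_um = 0.3,
                         local_bg_annulus_factor = 3,
                         match_radius_px = 2,
                         mrna_min_planes = 2,
                         ats_min_planes = 3,
                         ats_nucleus_margin_um = 0.2) {
  gene <- match.arg(gene)
  defaults <- switch(gene,
    "sygl-1" = list(overall = 1.27, local = 1.9, p = 9e-10),
    "lst-1"  = list(overall = 0.8, local = 0.9, p = 1e-1))
  p <- structure(list(
    gene = gene,
    overall_bg_ratio_min = overall_bg_ratio_min %||% defaults$overall,
    local_bg_ratio_min = local_bg_ratio_min %||% defaults$local,
    pixel_ttest_p_max = pixel_ttest_p_max %||% defaults$p,
    min_size_px = min_size_px, circularity_min = circularity_min,
    intron_candidate_bg_ratio_min = intron_candidate_bg_ratio_min,
    ats_total_bg_ratio_min = ats_total_bg_ratio_min,
    colocalization_radius_um = colocalization_radius_um,
    local_bg_annulus_factor = local_bg_annulus_factor,
    match_radius_px = match_radius_px,
    mrna_min_planes = mrna_min_planes, ats_min_planes = ats_min_planes,
    ats_nucleus_margin_um = ats_nucleus_margin_um),
    class = "probe_params")
  stopifnot(p$overall_bg_ratio_min > 0, p$local_bg_ratio_min > 0,
            p$pixel_ttest_p_max > 0, p$pixel_ttest_p_max < 1,
            p$circularity_min > 0, p$circularity_min <= 1)
  p
}

#' Nucleus detection parameters
#'
#' @param dapi_threshold_factor Factor applied to the automatic (Otsu)
#'   per-plane DAPI threshold (published value: 150%).
#' @param min_consecutive_planes Minimum consecutive z-planes with concentric
#'   circles for a nucleus to be scored.
#' @param max_center_var_um Maximum XY deviation of circle centers from their
#'   mean (um, Euclidean).
#' @param radius_range_um Accepted per-plane circle radius range (um).
#' @return An object of class `nucleus_detection_params`.
#' @export
nucleus_detection_params <- function(dapi_threshold_factor = 1.5,
                                     min_consecutive_planes = 4,
                                     max_center_var_um = 0.5,
                                     radius_range_um = c(1.3, 3.0)) {
  stopifnot(dapi_threshold_factor > 1, min_consecutive_planes >= 2,
            max_center_var_um > 0, length(radius_range_um) == 2,
            radius_range_um[1] > 0, diff(radius_range_um) > 0)
  structure(list(dapi_threshold_factor = dapi_threshold_factor,
                 min_consecutive_planes = min_consecutive_planes,
                 max_center_var_um = max_center_var_um,
                 radius_range_um = radius_range_um),
            class = "nucleus_detection_params")
}

#' Intensity normalization parameters
#'
#' @param mrna_mean_au Target mean intensity of cytoplasmic spots per gonad
#'   (10 a.u.).
#' @param basal_window_um Window in which the basal mRNA level is averaged
#'   (40-60 um).
#' @param bin_um Bin width used inside the basal window (5 um).
#' @return An object of class `normalization_params`.
#' @export
normalization_params <- function(mrna_mean_au = 10,
                                 basal_window_um = c(40, 60),
                                 bin_um = 5) {
  stopifnot(mrna_mean_au > 0, length(basal_window_um) == 2,
            diff(basal_window_um) > 0,
            abs(diff(basal_window_um) %% bin_um) < 1e-9)
  structure(list(mrna_mean_au = mrna_mean_au, basal_window_um = basal_window_um,
                 bin_um = bin_um), class = "normalization_params")
}

#' Voronoi cell parameters
#'
#' @param cap_radius_um Germ cell size cap: territory voxels must lie within
#'   this distance of the nucleus center (3 um).
#' @param grid_um Voxel edge length of the labeling grid (um).
#' @return An object of class `voronoi_params`.
#' @export
voronoi_params <- function(cap_radius_um = 3.0, grid_um = 0.5) {
  stopifnot(cap_radius_um > 0, grid_um > 0)
  structure(list(cap_radius_um = cap_radius_um, grid_um = grid_um),
            class = "voronoi_params")
}

#' DTC contact parameters
#'
#' @param gfp_bg_ratio_min GFP threshold factor over in-gonad background.
#' @param contact_min_pixels A cell is in DTC contact if strictly more than
#'   this many of its territory voxels are face-adjacent to the DTC mask.
#' @return An object of class `dtc_params`.
#' @export
dtc_params <- function(gfp_bg_ratio_min = 3, contact_min_pixels = 10) {
  stopifnot(gfp_bg_ratio_min > 0, contact_min_pixels > 0)
  structure(list(gfp_bg_ratio_min = gfp_bg_ratio_min,
                 contact_min_pixels = contact_min_pixels),
            class = "dtc_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
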