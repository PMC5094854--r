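# Nucleus packing uses a jittered hexagonal-close-packed lattice: germ cell
# nuclei in the distal gonad sit in a dense quasi-regular packing, and a
# lattice parameterization is the only sampler that controllably hits the
# "mean nearest-neighbor distance = gcd +/- 5%" contract. The lattice
# constant is spacing * .lattice_scale, where .lattice_scale compensates the
# mean nearest-neighbor shrinkage caused by the positional jitter
# (calibrated once at jitter 0.30 um; see methods vignette).
.lattice_scale <- 1.0557
.lattice_jitter_um <- 0.30

#' Sample ground-truth nuclei for a synthetic gonad
#'
#' Packs nuclei into the gonad slab at a mean nearest-neighbor spacing of
#' `nucleus_spacing_um`, assigns cell-cycle stages i.i.d. from
#' `cycle_fractions`, DNA content (2C in G1, uniform 2C-4C in S, 4C in
#' G2/M), locus counts (2 in G1; 2-4 in S; 4 in G2/M) and radii scaling with
#' the cube root of DNA content. Radii are capped so that no two nuclei
#' violate the non-overlap invariant (center distance >= 0.9 x sum of
#' radii).
#'
#' @param spec A [gonad_spec()].
#' @return A data.frame with columns `id, x, y, z, radius, cycle_stage,
#'   locus_count, dna_content, is_dtc` (positions in um; x is distal
#'   distance). If `spec$dtc$enabled`, the DTC nucleus is appended with
#'   `is_dtc = TRUE` and `locus_count = 0`.
#' @export
sample_nuclei <- function(spec) {
  validate_gonad_spec(spec)
  if (spec$nucleus_spacing_um < 2 * spec$nucleus_radius_um)
    stop("infeasible packing: nucleus_spacing_um < 2 * nucleus_radius_um")
  a <- spec$nucleus_spacing_um * .lattice_scale
  dy <- a * sqrt(3) / 2
  dz <- a * sqrt(2 / 3)
  m <- spec$nucleus_margin_um
  yc <- spec$radius_max_um + 2
  zlim <- c(m, spec$slab_z_um - m)

  # lattice covering the bounding box, with a random global phase
  phase <- runif(3, 0, a)
  xs <- seq(-a, spec$length_um + a, by = a)
  ks <- seq(0, ceiling((zlim[2] - zlim[1]) / dz) + 1)
  js <- seq(-ceiling((2 * yc) / dy) - 1, ceiling((2 * yc) / dy) + 1)
  grid <- expand.grid(i = seq_along(xs), j = js, k = ks)
  px <- xs[grid$i] + (grid$j %% 2) * a / 2 + (grid$k %% 2) * a / 2 + phase[1]
  py <- grid$j * dy + (grid$k %% 2) * dy / 3 + phase[2] %% dy + yc - yc %% dy
  pz <- zlim[1] + grid$k * dz + phase[3] %% dz
  # positional jitter, uniform in a ball
  n <- length(px)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * .lattice_jitter_um
  px <- px + u[, 1]; py <- py + u[, 2]; pz <- pz + u[, 3]

  keep <- px >= 0.2 & px <= spec$length_um &
    pz >= zlim[1] & pz <= zlim[2] &
    abs(py - yc) <= halfwidth_tissue(spec, px) - m
  # shift into stack coordinates: the tissue tip sits lead_um into the
  # imaged volume
  px <- px[keep] + spec$lead_um; py <- py[keep]; pz <- pz[keep]
  n <- length(px)
  if (n < 2) stop("infeasible packing: gonad too small for the lattice")

  stage <- sample(c("G1", "S", "G2", "M"), n, replace = TRUE,
                  prob = spec$cycle_fractions[c("G1", "S", "G2", "M")])
  dna <- numeric(n)
  loci <- integer(n)
  dna[stage == "G1"] <- 2
  loci[stage == "G1"] <- 2L
  is_s <- stage == "S"
  u_s <- runif(sum(is_s))
  dna[is_s] <- 2 + 2 * u_s
  loci[is_s] <- 2L + rbinom(sum(is_s), 2L, u_s)
  g2m <- stage %in% c("G2", "M")
  dna[g2m] <- 4
  loci[g2m] <- 4L
  radius <- spec$nucleus_radius_um * (dna / 3)^(1 / 3) *
    exp(rnorm(n, 0, spec$radius_jitter_sd))
  # enforce non-overlap: cap radii at nearest-neighbor distance / 1.8
  nnd <- nn_distances(cbind(px, py, pz))
  radius <- pmin(radius, nnd / 1.8)

  out <- data.frame(id = seq_len(n), x = px, y = py, z = pz, radius = radius,
                    cycle_stage = stage, locus_count = loci, dna_content = dna,
                    is_dtc = FALSE, stringsAsFactors = FALSE)
  if (isTRUE(spec$dtc$enabled)) {
    dtc_pos <- c(1.6 + spec$lead_um, yc, mean(zlim))
    # the niche cell body occupies the distal tip: clear germ nuclei that
    # would overlap its nucleus
    keep_g <- sqrt((out$x - dtc_pos[1])^2 + (out$y - dtc_pos[2])^2 +
                     (out$z - dtc_pos[3])^2) >= 0.9 * (out$radius + 2.0) + 0.2
    out <- out[keep_g, , drop = FALSE]
    out$id <- seq_len(nrow(out))
    # dna_content 3 keeps the rendered chromatin density of a 2.0-um
    # nucleus at the germ-cell level (the DTC's DNA content is not an
    # analyte; the nucleus only needs to be detectable for exclusion)
    out <- rbind(out, data.frame(
      id = nrow(out) + 1L, x = dtc_pos[1], y = dtc_pos[2], z = dtc_pos[3],
      radius = 2.0, cycle_stage = "G1", locus_count = 0L, dna_content = 3,
      is_dtc = TRUE, stringsAsFactors = FALSE))
  }
  out
}

#' Nearest-neighbor center distances
#'
#' @param centers n x 3 matrix of positions.
#' @return Numeric vector of each point's distance to its nearest neighbor.
#' @keywords internal
nn_distances <- function(centers) {
  n <- nrow(centers)
  if (n < 2) return(rep(NA_real_, n))
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Sample active transcription sites (ATS) for a set of nuclei
#'
#' Each chromosomal locus of each germ nucleus fires independently
#' (Bernoulli) with probability `firing_fun(x)` at that nucleus's distal
#' distance. Every active locus receives a nascent-transcript load drawn
#' from the spec's lognormal load distribution (mean `load_mean x
#' mutant$load_scale`, CV `load_cv`, truncated to load >= 1) and a position
#' uniform inside the nucleus sphere.
#'
#' @param nuclei Data.frame from [sample_nuclei()].
#' @param firing_fun Per-locus probability function of distal distance;
#'   defaults to [firing_profile_fun()] of `spec`.
#' @param spec A [gonad_spec()].
#' @return Data.frame of ATS ground truth: `kind, x, y, z, owner_id, load`.
#' @export
sample_transcription_state <- function(nuclei, spec,
                                       firing_fun = firing_profile_fun(spec)) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  p <- firing_fun(pmax(0, germ$x - spec$lead_um))
  stopifnot(all(p >= 0 & p <= 1))
  fired_n <- rbinom(nrow(germ), germ$locus_count, p)
  idx <- rep.int(seq_len(nrow(germ)), fired_n)
  n <- length(idx)
  if (n == 0)
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), owner_id = integer(), load = numeric(),
                      stringsAsFactors = FALSE))
  # uniform position in the owner sphere
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3) * germ$radius[idx]
  load <- rlnorm_load(n, spec$load_mean * spec$mutant$load_scale, spec$load_cv)
  data.frame(kind = "ATS", x = germ$x[idx] + u[, 1], y = germ$y[idx] + u[, 2],
             z = germ$z[idx] + u[, 3], owner_id = germ$id[idx], load = load,
             stringsAsFactors = FALSE)
}

# lognormal with given mean and CV, truncated (by resampling) to >= 1
rlnorm_load <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- rlnorm(n, meanlog, sdlog)
  bad <- x < 1
  for (i in 1:20) {
    if (!any(bad)) break
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    bad <- x < 1
  }
  pmax(x, 1)
}

#' Sample the cytoplasmic mRNA field
#'
#' Per-cell mRNA counts are Poisson with mean `profile_fun(x)`; positions
#' are uniform in the cell's cytoplasmic territory: within
#' `territory_radius_um` of the nucleus center, nearer to it than to any
#' other nucleus, outside every nucleus sphere and inside the gonad slab.
#'
#' @param nuclei Data.frame from [sample_nuclei()].
#' @param spec A [gonad_spec()].
#' @param profile_fun Expected-count function of distal distance; defaults
#'   to [mrna_profile_fun()] of `spec`.
#' @param territory_radius_um Cytoplasmic territory cap (um).
#' @return Data.frame of mRNA ground truth: `kind, x, y, z, owner_id, load`
#'   (load is identically 1).
#' @export
sample_mrna_field <- function(nuclei, spec, profile_fun = mrna_profile_fun(spec),
                              territory_radius_um = 3.0) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  counts <- rpois(nrow(germ), profile_fun(pmax(0, germ$x - spec$lead_um)))
  yc <- spec$radius_max_um + 2
  centers <- as.matrix(nuclei[, c("x", "y", "z")])
  res <- vector("list", nrow(germ))
  for (i in seq_len(nrow(germ))) {
    k <- counts[i]
    if (k == 0) next
    got <- matrix(numeric(0), ncol = 3)
    cx <- germ$x[i]; cy <- germ$y[i]; cz <- germ$z[i]
    # neighbors that could matter for ownership / overlap tests
    near <- which(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 +
                         (centers[, 3] - cz)^2) < 2 * territory_radius_um + 3)
    for (attempt in 1:40) {
      need <- k - nrow(got)
      if (need <= 0) break
      m <- 3 * need + 8
      u <- matrix(rnorm(3 * m), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * runif(m)^(1 / 3) * territory_radius_um
      q <- cbind(cx + u[, 1], cy + u[, 2], cz + u[, 3])
      ok <- q[, 3] >= 0 & q[, 3] <= spec$slab_z_um &
        abs(q[, 2] - yc) <= gonad_halfwidth(spec, q[, 1])
      if (length(near)) {
        d2 <- vapply(near, function(j)
          (q[, 1] - centers[j, 1])^2 + (q[, 2] - centers[j, 2])^2 +
            (q[, 3] - centers[j, 3])^2, numeric(nrow(q)))
        d2 <- matrix(d2, nrow = nrow(q))
        rad2 <- matrix(rep(nuclei$radius[near]^2, each = nrow(q)), nrow = nrow(q))
        ok <- ok & rowSums(d2 < rad2) == 0            # outside all nuclei
        own <- near[max.col(-d2, ties.method = "first")]
        ok <- ok & own == germ$id[i]                  # own territory
      }
      got <- rbind(got, q[ok, , drop = FALSE])
    }
    if (nrow(got) > k) got <- got[seq_len(k), , drop = FALSE]
    if (nrow(got))
      res[[i]] <- data.frame(kind = "mRNA", x = got[, 1], y = got[, 2],
                             z = got[, 3], owner_id = germ$id[i], load = 1,
                             stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric(), owner_id = integer(), load = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a complete ground-truth gonad model
#'
#' Runs [sample_nuclei()], [sample_transcription_state()] and
#' [sample_mrna_field()] under one spec.
#'
#' @param spec A [gonad_spec()].
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return An object of class `gonad_truth`: list with `spec`, `nuclei`,
#'   `ats`, `mrna`.
#' @export
sample_gonad_truth <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nuclei <- sample_nuclei(spec)
  ats <- sample_transcription_state(nuclei, spec)
  mrna <- sample_mrna_field(nuclei, spec)
  structure(list(spec = spec, nuclei = nuclei, ats = ats, mrna = mrna),
            class = "gonad_truth")
}

#' Simulate a decay time course after signaling shut-off
#'
#' At t = 0 signaling is switched off (restrictive-temperature shift of a
#' temperature-sensitive Notch receptor): no new firing occurs, existing ATS
#' decay exponentially with half-life `ats_halflife_min` and mRNAs with
#' `mrna_halflife_min`. Each spot receives one exponential death time, so
#' later timepoints contain nested subsets of earlier ones.
#'
#' @param spec A [gonad_spec()].
#' @param timepoints_min Non-negative timepoints (minutes).
#' @param seed Optional integer seed.
#' @return List with one element per timepoint: `list(time, truth)` where
#'   `truth` is a `gonad_truth` thinned to the surviving spots.
#' @export
simulate_timecourse <- function(spec, timepoints_min, seed = NULL) {
  if (any(timepoints_min < 0)) stop("timepoints must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  base <- sample_gonad_truth(spec)
  death_ats <- rexp(nrow(base$ats), rate = log(2) / spec$ats_halflife_min)
  death_mrna <- rexp(nrow(base$mrna), rate = log(2) / spec$mrna_halflife_min)
  lapply(timepoints_min, function(t) {
    tr <- base
    tr$ats <- base$ats[death_ats > t, , drop = FALSE]
    tr$mrna <- base$mrna[death_mrna > t, , drop = FALSE]
    list(time = t, truth = tr)
  })
}

#' Simulate a gonad: ground truth plus rendered image stack
#'
#' @param spec A [gonad_spec()].
#' @param optics An [optics_params()].
#' @param seed Optional integer seed.
#' @param distal_end `"left"` or `"right"`: where the distal cap lies in the
#'   rendered stack.
#' @return List with `truth` (a `gonad_truth`) and `stack` (a `sim_stack`).
#' @export
simulate_gonad <- function(spec, optics = optics_params(), seed = NULL,
                           distal_end = "left") {
  if (!is.null(seed)) set.seed(seed)
  truth <- sample_gonad_truth(spec)
  stack <- render_stack(truth, optics, distal_end = distal_end)
  list(truth = truth, stack = stack)
}
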