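#' Convert microns along the distal-proximal axis to germ cell diameters
#'
#' @param x_um Distance(s) from the distal end (um), >= 0.
#' @param gcd_um Germ cell diameter (um); default the published constant.
#' @return List with `gcd` (real-valued) and `gcd_label` (rounded half-up,
#'   the convention used for axis labels).
#' @export
micron_to_gcd <- function(x_um, gcd_um = 4.55) {
  stopifnot(all(x_um >= 0), gcd_um > 0)
  g <- x_um / gcd_um
  list(gcd = g, gcd_label = floor(g + 0.5))
}

#' Estimate the germ cell diameter from nucleus spacing
#'
#' Mean nearest-neighbor center distance over germ nuclei.
#'
#' @param nuclei Nucleus table (rows with `is_dtc == TRUE` are excluded).
#' @return List of class `gcd_scale`: `gcd_um`, `method = "estimated"`.
#' @export
estimate_gcd <- function(nuclei) {
  germ <- nuclei[!nuclei$is_dtc, , drop = FALSE]
  if (nrow(germ) < 2) stop("need >= 2 germ nuclei to estimate gcd")
  nnd <- nn_distances(as.matrix(germ[, c("x", "y", "z")]))
  structure(list(gcd_um = mean(nnd), method = "estimated"), class = "gcd_scale")
}

#' Gradient profile along the distal-proximal axis
#'
#' Bins entities into half-open `[a, a + bin_um)` bins from the distal end
#' and computes, per gonad and per bin, either the percentage of entities
#' satisfying a predicate or the mean of a value; then averages across
#' gonads with the SEM taken across gonads (the published error bars are
#' per-gonad SEM). Bins with no entities in a gonad are missing for that
#' gonad and excluded from the cross-gonad mean/SEM.
#'
#' @param data Data.frame with columns `gonad` (id) and `distal_distance`.
#' @param value Either a logical vector (predicate per row; profile is a
#'   percentage) or a numeric vector (profile of means).
#' @param bin_um Bin width (5 or 2 um typically).
#' @param length_um Axis extent tiled by the bins.
#' @return Data.frame of class `gradient_profile`: `bin_start, bin_mid,
#'   gcd_label, value, sem, n_gonads`.
#' @export
gradient_profile <- function(data, value, bin_um = 5, length_um = 60) {
  stopifnot(nrow(data) == length(value))
  edges <- seq(0, length_um, by = bin_um)
  nb <- length(edges) - 1
  keep <- data$distal_distance >= 0 & data$distal_distance < length_um
  data <- data[keep, , drop = FALSE]
  value <- value[keep]
  b <- findInterval(data$distal_distance, edges, rightmost.closed = FALSE)
  gonads <- unique(data$gonad)
  per <- matrix(NA_real_, length(gonads), nb)
  for (gi in seq_along(gonads)) {
    sel <- data$gonad == gonads[gi]
    for (bi in seq_len(nb)) {
      v <- value[sel & b == bi]
      if (length(v))
        per[gi, bi] <- if (is.logical(value)) 100 * mean(v) else mean(v)
    }
  }
  val <- colMeans(per, na.rm = TRUE)
  n <- colSums(!is.na(per))
  sem <- vapply(seq_len(nb), function(bi) {
    v <- per[!is.na(per[, bi]), bi]
    if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  val[n == 0] <- NA_real_
  structure(data.frame(bin_start = edges[-length(edges)],
                       bin_mid = edges[-length(edges)] + bin_um / 2,
                       gcd_label = floor(edges[-length(edges)] / 4.55 + 0.5),
                       value = val, sem = sem, n_gonads = n),
            class = c("gradient_profile", "data.frame"))
}

#' Boundary of a graded region from a percentage profile
#'
#' The distal edge of the first bin whose mean falls below `threshold_pct`
#' with all more-proximal bins also below it. Missing bins count as below
#' threshold (no evidence of signal). If the profile never settles below
#' threshold, the axis length is returned with `flagged = TRUE`.
#'
#' @param profile A [gradient_profile()] (percent values).
#' @param threshold_pct Threshold percentage (default 5).
#' @return List with `boundary_um` and `flagged`.
#' @export
region_boundary <- function(profile, threshold_pct = 5) {
  v <- profile$value
  below <- is.na(v) | v < threshold_pct
  n <- length(v)
  idx <- NA_integer_
  for (i in seq_len(n)) {
    if (all(below[i:n])) { idx <- i; break }
  }
  if (is.na(idx)) {
    w <- profile$bin_start[2] - profile$bin_start[1]
    return(list(boundary_um = profile$bin_start[n] + w, flagged = TRUE))
  }
  list(boundary_um = profile$bin_start[idx], flagged = FALSE)
}

#' DTC mask and germ-cell contact calls
#'
#' Binarizes the GFP channel per z-plane at `gfp_bg_ratio_min` x the
#' in-gonad background, reconstructs the mask in 3-D on the Voronoi grid,
#' and calls a cell "in contact" iff strictly more than
#' `contact_min_pixels` of its territory voxels are face-adjacent
#' (6-connectivity) to mask voxels.
#'
#' @param stack A `sim_stack` with a `gfp` channel.
#' @param outline The `gonad_outline`.
#' @param cells A `voronoi_cells` object.
#' @param params A [dtc_params()].
#' @return Data.frame: `nucleus_id, contact_voxels, contact` plus attribute
#'   `dtc_voxels` (mask size on the grid).
#' @export
dtc_mask_and_contacts <- function(stack, outline, cells, params = dtc_params()) {
  gfp <- stack$channels$gfp
  if (is.null(gfp)) stop("stack has no GFP channel")
  bgv <- plane_backgrounds(gfp, outline$mask2d)
  d <- dim(gfp)
  g <- cells$grid_um
  px <- stack$pixel_xy_um; dz <- stack$z_step_um
  lab <- cells$label
  dims <- dim(lab)
  # downsample the per-plane binary mask onto the quant grid by physical
  # position: a grid voxel is DTC if >= 25% of its image pixels exceed
  # threshold in the planes it spans
  dtc <- array(FALSE, dims)
  gi <- pmin(floor((seq_len(d[1]) - 0.5) * px / g) + 1L, dims[1])
  gj <- pmin(floor((seq_len(d[2]) - 0.5) * px / g) + 1L, dims[2])
  cnt <- tabulate(gi, dims[1]) %o% tabulate(gj, dims[2])
  zc <- (seq_len(d[3]) - 0.5) * dz
  for (k in seq_len(dims[3])) {
    kz <- which(zc >= (k - 1) * g & zc < k * g)
    if (!length(kz)) kz <- which.min(abs(zc - (k - 0.5) * g))
    acc <- matrix(0, dims[1], dims[2])
    for (kk in kz) {
      bw <- gfp[, , kk] >= params$gfp_bg_ratio_min * bgv[kk]
      s <- rowsum(bw * 1, gi)
      s <- t(rowsum(t(s), gj))
      acc[seq_len(nrow(s)), seq_len(ncol(s))] <-
        acc[seq_len(nrow(s)), seq_len(ncol(s))] + s
    }
    dtc[, , k] <- acc / (cnt * length(kz)) >= 0.25
  }
  # face-adjacency counts per cell
  adj <- array(FALSE, dims)
  sh <- function(a, di, dj, dk) {
    out <- array(FALSE, dim(a))
    src_i <- seq_len(dims[1]) + di; src_j <- seq_len(dims[2]) + dj
    src_k <- seq_len(dims[3]) + dk
    ok_i <- src_i >= 1 & src_i <= dims[1]
    ok_j <- src_j >= 1 & src_j <= dims[2]
    ok_k <- src_k >= 1 & src_k <= dims[3]
    out[ok_i, ok_j, ok_k] <- a[src_i[ok_i], src_j[ok_j], src_k[ok_k]]
    out
  }
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    adj <- adj | sh(dtc, s[1], s[2], s[3])
  ids <- cells$cells$nucleus_id
  cnt <- tabulate(factor(lab[adj & lab > 0L], levels = ids), length(ids))
  out <- data.frame(nucleus_id = ids, contact_voxels = cnt,
                    contact = cnt > params$contact_min_pixels)
  attr(out, "dtc_voxels") <- sum(dtc)
  out
}

#' Chi-square contingency test of DTC contact versus ATS positivity
#'
#' 2 x 2 Pearson chi-square test of independence (no continuity
#' correction) between contact status and ATS positivity for cells within
#' `max_um` of the distal end.
#'
#' @param contacts Contact table from [dtc_mask_and_contacts()].
#' @param quant Per-nucleus table with `ats_count` and `distal_distance`.
#' @param max_um Distal window (30 um).
#' @return A `stat_result` list: `test, statistic, p, table`.
#' @export
contact_ats_contingency <- function(contacts, quant, max_um = 30) {
  m <- merge(contacts, quant[, c("id", "ats_count", "distal_distance")],
             by.x = "nucleus_id", by.y = "id")
  m <- m[m$distal_distance < max_um, , drop = FALSE]
  tab <- table(factor(m$contact, levels = c(FALSE, TRUE)),
               factor(m$ats_count > 0, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in contact x ATS contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(test = "chi-square", statistic = unname(ct$statistic),
                 p = ct$p.value, table = tab), class = "stat_result")
}

#' Levene's test for equality of variances
#'
#' Classic (mean-centered) Levene: one-way ANOVA on absolute deviations
#' from group means.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List with `statistic` (F), `df`, and `p`.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2)
  dev <- abs(values - stats::ave(values, groups))
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(statistic = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

#' Anderson-Darling normality test
#'
#' Case with estimated mean and variance; small-sample adjusted statistic
#' `A* = A^2 (1 + 0.75/n + 2.25/n^2)` with the standard piecewise p-value
#' approximation (Stephens / D'Agostino).
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (the unadjusted A^2) and `p` (from the
#'   adjusted statistic).
#' @export
ad_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 8) stop("Anderson-Darling test needs n >= 8")
  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  A2 <- -n - sum((2 * seq_len(n) - 1) * (log(p) + log(1 - rev(p)))) / n
  # the small-sample adjustment feeds the p-value approximation; the
  # reported statistic is the raw A^2 (statsmodels convention)
  A <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  pval <- if (A < 0.2) {
    1 - exp(-13.436 + 101.14 * A - 223.73 * A^2)
  } else if (A < 0.34) {
    1 - exp(-8.318 + 42.796 * A - 59.938 * A^2)
  } else if (A < 0.6) {
    exp(0.9177 - 4.279 * A - 1.38 * A^2)
  } else {
    exp(1.2937 - 5.709 * A + 0.0186 * A^2)
  }
  list(statistic = A2, p = min(max(pval, 0), 1))
}

#' Assumption-gated statistical test dispatch
#'
#' Runs Levene's test across groups and an Anderson-Darling normality test
#' per group (groups with n < 8 are too small for the AD approximation and
#' are recorded but not gated on). If every gate has p >= 0.05 the
#' parametric test is used (Student t for 2 groups, one-way ANOVA for
#' more); otherwise the nonparametric analog (Kolmogorov-Smirnov for 2
#' groups, Kruskal-Wallis for more).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 3).
#' @return A `stat_result` list: `test`, `statistic`, `p`, and `gates`
#'   (Levene p and per-group AD p-values).
#' @export
dispatch_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("each group needs n >= 3")
  values <- unlist(groups, use.names = FALSE)
  glab <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  lev <- levene_test(values, glab)
  ad <- lapply(groups, function(g)
    if (length(g) >= 8) ad_test(g)$p else NA_real_)
  ad <- unlist(ad)
  gates_ok <- lev$p >= 0.05 && all(is.na(ad) | ad >= 0.05)
  k <- length(groups)
  if (gates_ok) {
    if (k == 2) {
      tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      res <- list(test = "t", statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      fit <- stats::anova(stats::lm(values ~ factor(glab)))
      res <- list(test = "ANOVA", statistic = fit$`F value`[1],
                  p = fit$`Pr(>F)`[1])
    }
  } else {
    if (k == 2) {
      kt <- suppressWarnings(stats::ks.test(groups[[1]], groups[[2]]))
      res <- list(test = "KS", statistic = unname(kt$statistic), p = kt$p.value)
    } else {
      kw <- stats::kruskal.test(groups)
      res <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                  p = kw$p.value)
    }
  }
  res$gates <- list(levene_p = lev$p, ad_p = ad)
  structure(res, class = "stat_result")
}

#' Pairwise correlation of ATS intensities within nuclei
#'
#' All unordered pairs of ATS intensities within each nucleus holding two
#' or more ATS, symmetrized (each pair contributes both orderings), with
#' the Pearson correlation of the paired values.
#'
#' @param ats ATS record table (`nucleus_id`, `exon_intensity_au`).
#' @return A `stat_result` list: `test = "Pearson"`, `statistic` (r), `p`,
#'   `pairs` (data.frame `a, b`), `n_pairs` (unordered).
#' @export
pairwise_ats_correlation <- function(ats) {
  sp <- split(ats$exon_intensity_au, ats$nucleus_id)
  sp <- sp[vapply(sp, length, integer(1)) >= 2]
  if (!length(sp)) stop("no nuclei with >= 2 ATS")
  a <- numeric(); b <- numeric()
  for (v in sp) {
    cmb <- utils::combn(length(v), 2)
    a <- c(a, v[cmb[1, ]], v[cmb[2, ]])
    b <- c(b, v[cmb[2, ]], v[cmb[1, ]])
  }
  r <- stats::cor(a, b)
  n <- length(a)
  p <- tryCatch(stats::cor.test(a, b)$p.value, error = function(e) NA_real_)
  structure(list(test = "Pearson", statistic = r, p = p,
                 pairs = data.frame(a = a, b = b), n_pairs = n / 2),
            class = "stat_result")
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean.
#'
#' @param values Numeric vector with nonzero mean.
#' @return sd/mean.
#' @export
cv <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m
}

#' Fit an exponential half-life to a decay time course
#'
#' Least-squares fit of `N(t) = N0 * 2^(-t/h)` (nonlinear on the count
#' scale, started from the log-linear solution). A non-decaying series is
#' flagged and returns `NA`.
#'
#' @param timepoints_min Timepoints (minutes), >= 3 values.
#' @param counts Spot counts per timepoint; `counts[1] > 0` required at
#'   t = 0.
#' @return List of class `halflife_fit`: `halflife_min`, `n0`, `flagged`.
#' @export
fit_halflife <- function(timepoints_min, counts) {
  stopifnot(length(timepoints_min) >= 3,
            length(counts) == length(timepoints_min))
  o <- order(timepoints_min)
  t <- timepoints_min[o]; y <- counts[o]
  if (y[1] <= 0) stop("count at the first timepoint must be > 0")
  pos <- y > 0
  slope <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
  if (!is.finite(slope) || slope >= -1e-9)
    return(structure(list(halflife_min = NA_real_, n0 = y[1], flagged = TRUE),
                     class = "halflife_fit"))
  h0 <- -log(2) / slope
  fit <- tryCatch(
    stats::nls(y ~ n0 * 2^(-t / h), start = list(n0 = y[1], h = h0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    h <- h0; n0 <- y[1]
  } else {
    cf <- stats::coef(fit)
    h <- unname(cf["h"]); n0 <- unname(cf["n0"])
  }
  structure(list(halflife_min = h, n0 = n0, flagged = FALSE),
            class = "halflife_fit")
}
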