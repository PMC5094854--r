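#' Build a pipeline run configuration
#'
#' Bundles every tunable of a run: the gonad spec and optics for simulation
#' runs, per-gene probe thresholds, nucleus detection, normalization,
#' Voronoi and DTC parameters, bin width, seed and output directory. All
#' thresholds surface in the run manifest; there are no hidden constants.
#'
#' @param spec A [gonad_spec()] (simulation runs).
#' @param optics An [optics_params()].
#' @param n_gonads Number of gonads in the cohort.
#' @param gene Probe gene, `"sygl-1"` or `"lst-1"`.
#' @param probe A [probe_params()]; defaults to `probe_params(gene)`.
#' @param nucleus A [nucleus_detection_params()].
#' @param normalization A [normalization_params()].
#' @param voronoi A [voronoi_params()].
#' @param dtc A [dtc_params()].
#' @param bin_um Profile bin width (5 or 2).
#' @param seed Integer seed for the cohort.
#' @param distal_end `"auto"`, `"left"` or `"right"` (orientation override).
#' @param out Optional output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = gonad_spec(), optics = optics_params(),
                       n_gonads = 20, gene = "sygl-1",
                       probe = probe_params(gene),
                       nucleus = nucleus_detection_params(),
                       normalization = normalization_params(),
                       voronoi = voronoi_params(), dtc = dtc_params(),
                       bin_um = 5, seed = 1, distal_end = "auto", out = NULL) {
  stopifnot(bin_um > 0, n_gonads >= 1)
  structure(list(spec = spec, optics = optics, n_gonads = n_gonads,
                 gene = gene, probe = probe, nucleus = nucleus,
                 normalization = normalization, voronoi = voronoi,
                 dtc = dtc, bin_um = bin_um, seed = seed,
                 distal_end = distal_end, out = out),
            class = "run_config")
}

#' Serialize / restore a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config()` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  flat <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  # named vectors must survive as JSON objects, not bare arrays
  flat$spec$cycle_fractions <- as.list(flat$spec$cycle_fractions)
  flat$optics$backgrounds <- as.list(flat$optics$backgrounds)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec_args <- raw$spec
  spec_args$cycle_fractions <- unlist(spec_args$cycle_fractions)
  for (nm in c("firing_profile", "mrna_profile", "mutant", "dtc"))
    spec_args[[nm]] <- as.list(spec_args[[nm]])
  spec <- do.call(gonad_spec, spec_args)
  opt_args <- raw$optics
  opt_args$backgrounds <- unlist(opt_args$backgrounds)
  optics <- do.call(optics_params, opt_args)
  probe <- do.call(probe_params, raw$probe)
  run_config(spec = spec, optics = optics, n_gonads = raw$n_gonads,
             gene = raw$gene, probe = probe,
             nucleus = do.call(nucleus_detection_params, raw$nucleus),
             normalization = do.call(normalization_params,
                                     lapply(raw$normalization, unlist)),
             voronoi = do.call(voronoi_params, raw$voronoi),
             dtc = do.call(dtc_params, raw$dtc),
             bin_um = raw$bin_um, seed = raw$seed,
             distal_end = raw$distal_end,
             out = if (is.null(raw$out)) NULL else raw$out)
}

#' Analyze one image stack end to end
#'
#' Boundary detection and orientation, outside-signal masking, nucleus
#' reconstruction, DTC exclusion, exon/intron spot cascades, ATS
#' confirmation, mRNA calling, normalization to 10 a.u., Voronoi cells,
#' mRNA assignment, basal level and per-nucleus summaries, DTC contacts
#' when a GFP channel is present.
#'
#' @param stack A `sim_stack` with at least `dapi`, `exon` and `intron`
#'   channels.
#' @param config A [run_config()].
#' @return An object of class `gonad_result`: list with `outline`,
#'   `nuclei`, `ats`, `mrna`, `cells`, `quant`, `basal`, `contacts`
#'   (or NULL), `counts`, `warnings`.
#' @export
analyze_stack <- function(stack, config = run_config()) {
  for (ch in c("dapi", "exon", "intron"))
    if (is.null(stack$channels[[ch]]))
      stop(sprintf("stack is missing required channel '%s'", ch))
  warns <- character()
  outline <- detect_gonad_boundary(stack, config$distal_end)
  o <- orient_distal_left(stack, outline)
  stack <- o$stack; outline <- o$outline
  stack <- mask_outside_signal(stack, outline)

  dapi <- stack$channels$dapi
  dapi_bg <- stack$plane_bg$dapi %||% plane_backgrounds(dapi, outline$mask2d)
  nz <- dim(dapi)[3]
  circles <- vector("list", nz)
  for (k in seq_len(nz))
    circles[[k]] <- detect_nucleus_circles(dapi[, , k], outline$mask2d,
                                           config$nucleus, stack$pixel_xy_um,
                                           bg = dapi_bg[k])
  nuclei <- reconstruct_nuclei(circles, config$nucleus, stack$z_step_um,
                               dapi = dapi, dapi_bg = dapi_bg,
                               pixel_um = stack$pixel_xy_um)
  nuclei$distal_distance <- nuclei$x - outline$distal_x_um
  has_gfp <- !is.null(stack$channels$gfp)
  nuclei <- exclude_dtc(nuclei, if (has_gfp) stack else NULL, outline,
                        fallback = FALSE, params = config$dtc)

  exon <- detect_channel_spots(stack, outline, "exon", config$probe)
  intron <- detect_channel_spots(stack, outline, "intron", config$probe)
  mrna <- call_mrnas(exon, nuclei, config$probe)
  if (!nrow(mrna)) stop("no cytoplasmic mRNA spots detected")
  single_ref <- mean(mrna$intensity_bg)
  ats <- classify_ats(exon, intron, nuclei, config$probe, single_ref)
  norm <- normalize_gonad(mrna, ats, config$normalization)
  mrna <- norm$mrna; ats <- norm$ats
  mrna$distal_distance <- mrna$x - outline$distal_x_um
  if (nrow(ats))
    ats$distal_distance <- ats$x - outline$distal_x_um

  cells <- build_voronoi_cells(nuclei, outline, config$voronoi)
  asg <- assign_mrnas(mrna, cells, outline)
  mrna <- asg$mrna
  counts <- merge(asg$counts,
                  nuclei[, c("id", "distal_distance")],
                  by.x = "nucleus_id", by.y = "id")
  basal <- tryCatch(compute_basal_level(counts, config$normalization),
                    error = function(e) {
                      warns <<- c(warns, conditionMessage(e)); NULL
                    })
  quant <- summarize_nuclei(nuclei, ats, counts, basal)
  contacts <- NULL
  if (has_gfp)
    contacts <- dtc_mask_and_contacts(stack, outline, cells, config$dtc)
  structure(list(outline = outline, nuclei = nuclei, ats = ats, mrna = mrna,
                 cells = cells, counts = quant$per_cell, quant = quant,
                 basal = basal, contacts = contacts,
                 rachis_copies = asg$rachis_copies,
                 flagged_copies = asg$flagged_copies, warnings = warns),
            class = "gonad_result")
}

#' Run the full simulate-and-analyze pipeline over a cohort
#'
#' Simulates `n_gonads` gonads from the config's spec (per-gonad seeds are
#' derived from the cohort seed), analyzes each stack, pools the per-gonad
#' tables after per-gonad normalization, computes gradient profiles and
#' headline metrics, and writes tables plus a manifest when an output
#' directory is configured.
#'
#' @param config A [run_config()].
#' @param keep_truth Logical; retain each gonad's ground truth (for
#'   evaluation runs).
#' @return An object of class `pipeline_run`: list with `results` (per
#'   gonad), `truths` (if kept), pooled `nuclei`, `ats`, `mrna`, `counts`
#'   tables (with `gonad` column), `profiles`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), keep_truth = FALSE) {
  results <- vector("list", config$n_gonads)
  truths <- if (keep_truth) vector("list", config$n_gonads) else NULL
  for (i in seq_len(config$n_gonads)) {
    sim <- simulate_gonad(config$spec, config$optics,
                          seed = config$seed * 1000L + i)
    results[[i]] <- analyze_stack(sim$stack, config)
    if (keep_truth) truths[[i]] <- sim$truth
  }
  pooled <- pool_results(results)
  profiles <- cohort_profiles(pooled, config)
  rep <- report_metrics(pooled, profiles, config)
  manifest <- list(
    # the output path is not part of the scientific configuration
    config_hash = hash_object(config[setdiff(names(config), "out")]),
    package_version = as.character(utils::packageVersion("gonadFISH")),
    n_gonads = config$n_gonads,
    seed = config$seed,
    counts = list(nuclei = nrow(pooled$nuclei), ats = nrow(pooled$ats),
                  mrna = nrow(pooled$mrna)),
    per_gonad_counts = lapply(results, function(r)
      list(nuclei = nrow(r$nuclei), ats = nrow(r$ats), mrna = nrow(r$mrna))),
    thresholds = unclass_deep(config[c("probe", "nucleus", "normalization",
                                       "voronoi", "dtc")]),
    warnings = unlist(lapply(results, `[[`, "warnings")))
  run <- structure(list(results = results, truths = truths,
                        nuclei = pooled$nuclei, ats = pooled$ats,
                        mrna = pooled$mrna, counts = pooled$counts,
                        profiles = profiles, report = rep,
                        manifest = manifest, config = config),
                   class = "pipeline_run")
  if (!is.null(config$out)) write_run_outputs(run, config$out)
  run
}

pool_results <- function(results) {
  tag <- function(field) {
    do.call(rbind, lapply(seq_along(results), function(i) {
      df <- results[[i]][[field]]
      if (is.null(df) || !nrow(df)) return(NULL)
      cbind(gonad = i, df)
    }))
  }
  pn <- do.call(rbind, lapply(seq_along(results), function(i)
    cbind(gonad = i, results[[i]]$quant$per_nucleus)))
  list(nuclei = pn, ats = tag("ats"), mrna = tag("mrna"), counts = tag("counts"))
}

cohort_profiles <- function(pooled, config) {
  nuc <- pooled$nuclei
  L <- config$spec$length_um
  out <- list(
    ats_positive = gradient_profile(nuc, nuc$ats_count >= 1, config$bin_um, L),
    mean_ats_count = gradient_profile(nuc, as.numeric(nuc$ats_count),
                                      config$bin_um, L),
    summed_ats_au = gradient_profile(nuc, nuc$summed_ats_au, config$bin_um, L))
  if (!is.null(pooled$ats) && nrow(pooled$ats))
    out$ats_intensity <- gradient_profile(pooled$ats,
                                          pooled$ats$exon_intensity_au,
                                          config$bin_um, L)
  if (!is.null(pooled$counts)) {
    cc <- pooled$counts
    out$mrna_per_cell <- gradient_profile(cc, cc$mrna_copies, config$bin_um, L)
    if ("above_basal" %in% names(cc))
      out$mrna_above_basal <- gradient_profile(cc, cc$above_basal,
                                               config$bin_um, L)
  }
  out
}

report_metrics <- function(pooled, profiles, config) {
  mrna <- pooled$mrna
  ats <- pooled$ats
  nuc <- pooled$nuclei
  singles <- mrna[mrna$copy_count == 1, , drop = FALSE]
  bnd <- region_boundary(profiles$ats_positive, 5)
  # gcd per gonad (nuclei of different gonads share no space), then averaged
  gcd <- tryCatch(
    mean(vapply(split(nuc, nuc$gonad), function(g)
      estimate_gcd(g)$gcd_um, numeric(1))),
    error = function(e) NA_real_)
  list(
    n_gonads = length(unique(nuc$gonad)),
    n_nuclei = nrow(nuc),
    n_mrna_spots = nrow(mrna),
    n_ats = if (is.null(ats)) 0L else nrow(ats),
    mean_mrna_au = mean(mrna$intensity_au),
    mrna_cv = cv(singles$intensity_au),
    multi_mrna_pct = 100 * mean(mrna$copy_count >= 2),
    mean_ats_au = if (is.null(ats) || !nrow(ats)) NA_real_
                  else mean(ats$exon_intensity_au),
    ats_fold_over_mrna = if (is.null(ats) || !nrow(ats)) NA_real_
                         else mean(ats$exon_intensity_au) /
                              mean(mrna$intensity_au),
    max_ats_per_nucleus = max(nuc$ats_count),
    distal_bin_ats_positive_pct = profiles$ats_positive$value[1],
    ats_region_boundary_um = bnd$boundary_um,
    ats_region_flagged = bnd$flagged,
    gcd_estimate_um = gcd)
}

#' Render a human-readable run report
#'
#' @param run A `pipeline_run`.
#' @return Markdown string (invisibly also returned by `print`).
#' @export
report_run <- function(run) {
  r <- run$report
  lines <- c(
    "# gonadFISH run report", "",
    sprintf("- gonads analyzed: %d", r$n_gonads),
    sprintf("- nuclei: %d; mRNA spots: %d; ATS: %d",
            r$n_nuclei, r$n_mrna_spots, r$n_ats),
    sprintf("- mean mRNA intensity: %.2f a.u. (CV %.2f)",
            r$mean_mrna_au, r$mrna_cv),
    sprintf("- mean ATS intensity: %.1f a.u. (%.1f-fold over single mRNA)",
            r$mean_ats_au, r$ats_fold_over_mrna),
    sprintf("- max ATS per nucleus: %d", r$max_ats_per_nucleus),
    sprintf("- ATS-positive in distal bin: %.1f%%",
            r$distal_bin_ats_positive_pct),
    sprintf("- ATS region boundary (<5%% rule): %.0f um%s",
            r$ats_region_boundary_um,
            if (isTRUE(r$ats_region_flagged)) " (never below threshold)" else ""),
    sprintf("- multi-mRNA spots: %.2f%%", r$multi_mrna_pct),
    sprintf("- gcd estimate: %.2f um", r$gcd_estimate_um))
  paste(lines, collapse = "\n")
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df))
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(run$nuclei, "nuclei.csv")
  wr(run$ats, "ats.csv")
  wr(run$mrna, "mrna.csv")
  wr(run$counts, "cells.csv")
  prof <- do.call(rbind, lapply(names(run$profiles), function(nm)
    cbind(profile = nm, run$profiles[[nm]])))
  wr(prof, "profiles.csv")
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report_run(run), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Match detected spots to ground truth and score precision/recall
#'
#' Greedy nearest-neighbor matching within `radius_um`.
#'
#' @param detected Data.frame with `x, y, z`.
#' @param truth Data.frame with `x, y, z`.
#' @param radius_um Match radius (0.5 um).
#' @return List with `precision`, `recall`, `n_matched`, `mean_error_um`.
#' @export
match_spots <- function(detected, truth, radius_um = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0,
                n_matched = 0L, mean_error_um = NA_real_))
  d2 <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2 +
    outer(detected$z, truth$z, "-")^2
  d2[d2 > radius_um^2] <- Inf
  matched <- 0L; errs <- numeric()
  repeat {
    if (all(!is.finite(d2))) break
    m <- which(d2 == min(d2), arr.ind = TRUE)[1, , drop = TRUE]
    matched <- matched + 1L
    errs <- c(errs, sqrt(d2[m[1], m[2]]))
    d2[m[1], ] <- Inf
    d2[, m[2]] <- Inf
  }
  list(precision = matched / nd, recall = matched / nt, n_matched = matched,
       mean_error_um = if (matched) mean(errs) else NA_real_)
}

#' Evaluate a pipeline run against its ground truth
#'
#' @param run A `pipeline_run` created with `keep_truth = TRUE`.
#' @param radius_um Spot match radius.
#' @return List with per-class precision/recall (`mrna`, `ats`) and nucleus
#'   recovery stats.
#' @export
evaluate_run <- function(run, radius_um = 0.5) {
  stopifnot(!is.null(run$truths))
  agg <- function(field_det, field_truth) {
    ms <- lapply(seq_along(run$results), function(i)
      match_spots(run$results[[i]][[field_det]],
                  run$truths[[i]][[field_truth]], radius_um))
    nd <- sum(vapply(seq_along(ms), function(i)
      nrow(run$results[[i]][[field_det]]), numeric(1)))
    nt <- sum(vapply(seq_along(ms), function(i)
      nrow(run$truths[[i]][[field_truth]]), numeric(1)))
    nm <- sum(vapply(ms, `[[`, numeric(1), "n_matched"))
    list(precision = nm / nd, recall = nm / nt, n_detected = nd, n_truth = nt)
  }
  nuc_stats <- lapply(seq_along(run$results), function(i) {
    det <- run$results[[i]]$nuclei
    tru <- run$truths[[i]]$nuclei
    tru <- tru[!tru$is_dtc, , drop = FALSE]
    d2 <- outer(det$x, tru$x, "-")^2 + outer(det$y, tru$y, "-")^2 +
      outer(det$z, tru$z, "-")^2
    j <- max.col(-d2)
    err <- sqrt(d2[cbind(seq_len(nrow(det)), j)])
    ok <- err < 0.5
    rad_err <- abs(det$radius - tru$radius[j]) / tru$radius[j]
    list(n_truth = nrow(tru), n_matched = sum(ok),
         center_err = err[ok], radius_relerr = rad_err[ok])
  })
  list(mrna = agg("mrna", "mrna"), ats = agg("ats", "ats"),
       nuclei = list(
         recall = sum(vapply(nuc_stats, `[[`, numeric(1), "n_matched")) /
           sum(vapply(nuc_stats, `[[`, numeric(1), "n_truth")),
         mean_center_err_um = mean(unlist(lapply(nuc_stats, `[[`, "center_err"))),
         mean_radius_relerr = mean(unlist(lapply(nuc_stats, `[[`,
                                                 "radius_relerr")))))
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
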