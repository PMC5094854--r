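# Shared fixtures, all generated in code. The "tiny" gonad keeps unit tests
# fast (a ~24 x 16 x 9 um stack renders in a few seconds); cohort-scale
# checks live in test-acceptance.R.

tiny_spec <- function(...) {
  gonad_spec(length_um = 24, radius_max_um = 6, cap_um = 3, slab_z_um = 9,
             mrna_profile = list(distal_mean = 12, plateau_um = 10,
                                 basal_start_um = 18, basal_mean = 1), ...)
}

# one rendered tiny gonad, memoized across test files (deterministic seed)
.fixture_env <- new.env(parent = emptyenv())

get_tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_gonad(tiny_spec(), optics_params(), seed = 101)
  }
  .fixture_env$sim
}

get_dtc_sim <- function() {
  if (is.null(.fixture_env$dtc_sim)) {
    spec <- tiny_spec(dtc = list(enabled = TRUE, body_um = 4, n_processes = 4,
                                 process_length_um = 12,
                                 process_radius_um = 0.7))
    .fixture_env$dtc_sim <- list(sim = simulate_gonad(spec, optics_params(),
                                                      seed = 55),
                                 spec = spec)
  }
  .fixture_env$dtc_sim
}

get_dtc_result <- function() {
  if (is.null(.fixture_env$dtc_res)) {
    d <- get_dtc_sim()
    .fixture_env$dtc_res <- analyze_stack(d$sim$stack,
                                          run_config(spec = d$spec))
  }
  .fixture_env$dtc_res
}

get_tiny_result <- function() {
  if (is.null(.fixture_env$res)) {
    sim <- get_tiny_sim()
    cfg <- run_config(spec = tiny_spec())
    .fixture_env$res <- analyze_stack(sim$stack, cfg)
  }
  .fixture_env$res
}

# a flat in-gonad outline covering an nx x ny plane (for plane-level tests)
flat_outline <- function(nx, ny, pixel_um = 0.065, nz = 1) {
  structure(list(mask2d = matrix(TRUE, nx, ny),
                 ymin_px = rep(1L, nx), ymax_px = rep(ny, nx),
                 distal_end = "left", distal_x_um = 0,
                 pixel_xy_um = pixel_um, z_step_um = 0.3,
                 dim = c(nx, ny, nz), oriented = TRUE),
            class = "gonad_outline")
}

# render an isolated Gaussian spot on a constant background plane stack
render_single_spot <- function(load = 1, optics = optics_params(noise = FALSE),
                               nx = 60, ny = 60, nz = 15) {
  spec <- gonad_spec()
  a <- array(0, c(nx, ny, nz))
  p <- gonadFISH:::gaussian_patch(nx / 2 * optics$pixel_xy_um,
                                  ny / 2 * optics$pixel_xy_um,
                                  nz / 2 * optics$z_step_um,
                                  load * optics$single_mrna_photon_scale,
                                  optics, dim(a))
  a[p$ix, p$iy, p$iz] <- a[p$ix, p$iy, p$iz] + p$patch
  a + optics$backgrounds[["exon"]]
}
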