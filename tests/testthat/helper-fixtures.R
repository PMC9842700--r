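# Expensive fixtures are generated once per test run and shared across files.
fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (is.null(fixture_env[[key]])) assign(key, fn(), envir = fixture_env)
  get(key, envir = fixture_env)
}

zero_overlap_specs <- function() {
  dplyr::mutate(imagetx:::default_marker_specs(), n_overlap = 0L)
}

# desk-scale config: 3 donors x 40 samples, 120 genes, 12 affected samples
tiny_config <- function(seed = 11, mask_fraction = 0.1, ...) {
  specs <- tibble::tibble(set_name = c("M_hit", "M_null"),
                          set_size = c(5L, 5L),
                          n_overlap = c(4L, 0L))
  simulation_config(n_donors = 3, samples_per_donor = 40, n_genes = 120,
                    n_planted_de = 10, mask_fraction = mask_fraction,
                    marker_set_specs = specs, seed = seed, ...)
}

default_sim <- function() {
  cached_fixture("default_sim",
                 function() simulate_atlas(simulation_config(seed = 1)))
}

default_run_dir <- function() {
  cached_fixture("default_run_dir", function() {
    dir <- file.path(tempdir(), "imagetx-default-run")
    unlink(dir, recursive = TRUE)
    simulate_atlas(simulation_config(seed = 1), dir = dir)
    dir
  })
}

default_pipeline <- function() {
  cached_fixture("default_pipeline", function() {
    dir <- default_run_dir()
    pc <- pipeline_config(
      bundle_dirs = sort(list.files(dir, "^donor_", full.names = TRUE)),
      mask_paths = file.path(dir, "mask_left.nii"),
      marker_gmt = file.path(dir, "markers.gmt"),
      outdir = file.path(dir, "out"), seed = 1)
    suppressMessages(run_pipeline(pc))
  })
}

# report comparison helper: everything but wall-clock timings
report_fingerprint <- function(report) {
  j <- imagetx:::report_to_json(report)
  j$timings <- NULL
  j
}

# independent 8-corner trilinear oracle (closed form, voxel index space)
trilinear_oracle <- function(grid, idx) {
  i0 <- floor(idx[1]); j0 <- floor(idx[2]); k0 <- floor(idx[3])
  fx <- idx[1] - i0; fy <- idx[2] - j0; fz <- idx[3] - k0
  v <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    v <- v + w * grid[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
  }
  v
}
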