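# Shared fixtures, built in code. The motility fixture is expensive enough
# to be worth caching per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_motility_fixture <- function(seed = 1) {
  key <- paste0("motility_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- two_class_motility_fixture(seed)
    trajs <- suppressWarnings(link_tracks_to_masks(sim$tracks, sim$movie))
    profiles <- suppressWarnings(
      cell_profiles(sim$movie, trajs, truth = sim$truth))
    .fixture_cache[[key]] <- list(sim = sim, trajectories = trajs,
                                  profiles = profiles)
  }
  .fixture_cache[[key]]
}

small_population_spec <- function(seed = 7, step_sd = 1, n_cells = 4,
                                  n_frames = 10, size = 96) {
  population_spec(
    classes = list(list(name = "A", n_cells = n_cells, mean_area = 120,
                        area_sd = 10, aspect_ratio = 1.5, texture_sd = 10,
                        step_sd = step_sd)),
    n_frames = n_frames, width = size, height = size, seed = seed
  )
}

# Build a cell_instance directly from a mask (+ optional intensities).
make_instance <- function(mask, intensity = NULL) {
  if (is.null(intensity)) intensity <- matrix(100, nrow(mask), ncol(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  cell_instance(intensity, lab, 1L)
}

# An instance embedded at a row/col offset inside a larger frame.
embedded_instance <- function(mask, at = c(5, 5), frame_dim = c(40, 40),
                              intensity_values = NULL) {
  img <- matrix(0, frame_dim[1], frame_dim[2])
  lab <- matrix(0L, frame_dim[1], frame_dim[2])
  rr <- at[1]:(at[1] + nrow(mask) - 1)
  cc <- at[2]:(at[2] + ncol(mask) - 1)
  lab[rr, cc][mask] <- 1L
  if (is.null(intensity_values)) {
    img[rr, cc][mask] <- 100
  } else {
    img[rr, cc][mask] <- intensity_values
  }
  cell_instance(img, lab, 1L)
}

solo_context <- function(inst, diagonal = sqrt(2) * 100) {
  list(centroids = data.frame(x = inst$centroid["x"], y = inst$centroid["y"]),
       self = 1, prev_centroid = NULL, diagonal = diagonal,
       density_radius = 100)
}

expect_snapshot_free_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(a, b, tolerance = tol)
}
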