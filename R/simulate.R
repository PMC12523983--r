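# Synthetic class-structured time-lapse movies: elliptical cells performing
# Gaussian random walks over a noisy background, emitted together with the
# ground-truth track table and class map so the whole pipeline is testable
# without real imaging data.
#
# Reproducibility protocol: one master seed; every cell draws its geometry and
# its walk from a substream keyed by (seed, cell index), and its per-frame
# interior noise from (seed, cell index, frame). Adding a class appends cells
# and leaves existing cells' streams untouched.

#' Specify a synthetic multi-class cell population
#'
#' @param classes list of per-class parameter lists, each with `name`,
#'   `n_cells`, `mean_area` (px^2), `area_sd`, `aspect_ratio` (major/minor,
#'   >= 1), `texture_sd` (interior intensity noise SD), `step_sd`
#'   (random-walk step SD, px/frame).
#' @param n_frames number of frames (>= 8).
#' @param width,height image size in pixels.
#' @param base_intensity mean interior intensity (default 400).
#' @param background_intensity mean background intensity (default 100).
#' @param seed master integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(classes, n_frames = 16, width = 256, height = 256,
                            base_intensity = 400, background_intensity = 100,
                            seed = 1) {
  stopifnot(n_frames >= 8, width > 0, height > 0, length(classes) >= 1)
  for (cl in classes) {
    stopifnot(cl$n_cells > 0, cl$mean_area > 0, cl$aspect_ratio >= 1,
              cl$texture_sd >= 0, cl$step_sd >= 0)
  }
  structure(list(classes = classes, n_frames = as.integer(n_frames),
                 width = as.integer(width), height = as.integer(height),
                 base_intensity = base_intensity,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# Pixel indices (row, col 1-based) of an ellipse: centre (cx, cy) in 0-based
# x=col / y=row coordinates, semi-axes a >= b, rotation theta. A pixel is
# included iff its centre satisfies the ellipse inequality.
rasterise_ellipse <- function(cx, cy, a, b, theta, width, height) {
  r0 <- max(0, floor(cy - a)); r1 <- min(height - 1, ceiling(cy + a))
  c0 <- max(0, floor(cx - a)); c1 <- min(width - 1, ceiling(cx + a))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  dx <- g$col - cx
  dy <- g$row - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u * u + v * v <= 1
  cbind(row = g$row[keep] + 1L, col = g$col[keep] + 1L)
}

reflect_into <- function(p, lo, hi) {
  span <- 2 * (hi - lo)
  q <- (p - lo) %% span
  q <- ifelse(q < 0, q + span, q)
  lo + ifelse(q > (hi - lo), span - q, q)
}

#' Simulate a class-structured synthetic movie
#'
#' Each cell is a rotated ellipse whose centroid follows an isotropic Gaussian
#' random walk (SD `step_sd` per class), reflected at the image borders.
#' Interior intensity is `base_intensity` plus Gaussian noise with per-class
#' SD `texture_sd`. Initial placements that overlap an earlier cell are
#' redrawn (up to 100 attempts). Per-frame labels are an arbitrary (seeded)
#' permutation of the cells; the emitted track table links them by
#' construction. Identical seeds give bit-identical output.
#'
#' @param spec a [population_spec()].
#' @return list with `movie` (a `labelled_movie`), `tracks` (generic track
#'   table: frame, cell, x, y) and `truth` (data.frame track_id, class).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  W <- spec$width; H <- spec$height; nf <- spec$n_frames
  cls_of <- unlist(lapply(spec$classes, function(cl) rep(cl$name, cl$n_cells)))
  par_of <- do.call(rbind, lapply(spec$classes, function(cl) {
    data.frame(mean_area = cl$mean_area, area_sd = cl$area_sd,
               aspect_ratio = cl$aspect_ratio, texture_sd = cl$texture_sd,
               step_sd = cl$step_sd)[rep(1, cl$n_cells), , drop = FALSE]
  }))
  ncell <- length(cls_of)

  # geometry + full trajectory per cell, drawn from the cell's substream
  cells <- vector("list", ncell)
  occupancy <- matrix(FALSE, H, W)
  for (i in seq_len(ncell)) {
    set.seed(derive_seed(spec$seed, i))
    area <- max(16, stats::rnorm(1, par_of$mean_area[i], par_of$area_sd[i]))
    b <- sqrt(area / (pi * par_of$aspect_ratio[i]))
    a <- par_of$aspect_ratio[i] * b
    theta <- stats::runif(1, 0, pi)
    placed <- FALSE
    for (attempt in 1:100) {
      cx <- stats::runif(1, a + 1, W - a - 2)
      cy <- stats::runif(1, a + 1, H - a - 2)
      px <- rasterise_ellipse(cx, cy, a, b, theta, W, H)
      if (nrow(px) > 0 && !any(occupancy[px])) {
        occupancy[px] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("capacity error: could not place cell ", i,
           " after 100 attempts; image too small for the population")
    }
    steps <- matrix(stats::rnorm(2 * (nf - 1), 0, par_of$step_sd[i]),
                    ncol = 2)
    xs <- reflect_into(cx + cumsum(c(0, steps[, 1])), 1, W - 2)
    ys <- reflect_into(cy + cumsum(c(0, steps[, 2])), 1, H - 2)
    cells[[i]] <- list(a = a, b = b, theta = theta, xs = xs, ys = ys,
                       texture_sd = par_of$texture_sd[i])
  }

  intensity <- vector("list", nf)
  labels <- vector("list", nf)
  tracks <- vector("list", nf)
  for (f in seq_len(nf)) {
    set.seed(derive_seed(spec$seed, 800000, f))
    img <- matrix(stats::rnorm(H * W, spec$background_intensity, 2), H, W)
    labm <- matrix(0L, H, W)
    perm <- sample.int(ncell)  # per-frame arbitrary labels
    for (i in seq_len(ncell)) {
      cell <- cells[[i]]
      px <- rasterise_ellipse(cell$xs[f], cell$ys[f], cell$a, cell$b,
                              cell$theta, W, H)
      set.seed(derive_seed(spec$seed, i, 1000 + f))
      img[px] <- spec$base_intensity +
        stats::rnorm(nrow(px), 0, cell$texture_sd)
      labm[px] <- perm[i]
    }
    # touching cells are painted in order; the centroid pixel always keeps
    # its own cell's label so every track row lies inside its region
    for (i in seq_len(ncell)) {
      cell <- cells[[i]]
      labm[round_half_away(cell$ys[f]) + 1, round_half_away(cell$xs[f]) + 1] <- perm[i]
    }
    intensity[[f]] <- round(pmin(pmax(img, 0), 65535))
    labels[[f]] <- labm
    tracks[[f]] <- data.frame(
      frame = f - 1L, cell = seq_len(ncell),
      x = vapply(cells, function(cc) cc$xs[f], numeric(1)),
      y = vapply(cells, function(cc) cc$ys[f], numeric(1))
    )
  }
  tracks <- do.call(rbind, tracks)
  tracks <- tracks[order(tracks$cell, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  list(
    movie = labelled_movie(intensity, labels),
    tracks = tracks,
    truth = data.frame(track_id = seq_len(ncell), class = cls_of,
                       stringsAsFactors = FALSE)
  )
}

#' Two-class motility fixture
#'
#' A standard simulation in which the two classes differ only in random-walk
#' step size (class A `step_sd` 0.5 px/frame, class B 4.0), mimicking a
#' weakly versus strongly migratory cell line pair: 20 cells per class,
#' 32 frames, 512x512 pixels, all morphology and texture parameters equal.
#'
#' @param seed master seed.
#' @return as [simulate_population()].
#' @export
two_class_motility_fixture <- function(seed = 1) {
  spec <- population_spec(
    classes = list(
      list(name = "A", n_cells = 20, mean_area = 250, area_sd = 30,
           aspect_ratio = 2, texture_sd = 15, step_sd = 0.5),
      list(name = "B", n_cells = 20, mean_area = 250, area_sd = 30,
           aspect_ratio = 2, texture_sd = 15, step_sd = 4.0)
    ),
    n_frames = 32, width = 512, height = 512, seed = seed
  )
  simulate_population(spec)
}
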