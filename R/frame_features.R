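# Per-frame single-cell features. Coordinate convention throughout: 0-based
# pixel indices, x = column, y = row; all geometry uses pixel centres.

# 8-connected components by vectorised frontier flood fill on a logical
# matrix; masks here are small crops, so a plain R implementation is adequate.
connected_components <- function(mask) {
  d <- dim(mask)
  # pad by one so neighbour indexing never leaves the matrix
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  comp <- matrix(0L, d[1] + 2, d[2] + 2)
  nr <- d[1] + 2
  nb_off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  cur <- 0L
  remaining <- which(pad & comp == 0L)
  while (length(remaining) > 0) {
    cur <- cur + 1L
    frontier <- remaining[1]
    comp[frontier] <- cur
    while (length(frontier) > 0) {
      cand <- unique(as.vector(outer(frontier, nb_off, "+")))
      cand <- cand[pad[cand] & comp[cand] == 0L]
      comp[cand] <- cur
      frontier <- cand
    }
    remaining <- which(pad & comp == 0L)
  }
  comp[2:(d[1] + 1), 2:(d[2] + 1), drop = FALSE]
}

#' Build a single-cell instance from a frame
#'
#' Crops the pixels carrying `label` in the frame's label image together with
#' the corresponding intensities. A disconnected mask is reduced to its
#' largest 8-connected component (with a warning).
#'
#' @param intensity numeric frame matrix.
#' @param label_image integer label matrix.
#' @param label the cell's label (> 0).
#' @return object of class `cell_instance`: cropped logical `mask`, numeric
#'   `intensity` patch, `offset` (row, col of crop origin, 0-based),
#'   `centroid` (x, y of mask pixel centres), `on_border` flag.
#' @export
cell_instance <- function(intensity, label_image, label) {
  idx <- which(label_image == label)
  if (length(idx) == 0) stop("label ", label, " absent from frame")
  d <- dim(label_image)
  rows <- ((idx - 1) %% d[1]) + 1
  cols <- ((idx - 1) %/% d[1]) + 1
  r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
  mask <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  mask[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
  if (sum(mask) > 1) {
    comp <- connected_components(mask)
    if (max(comp) > 1) {
      warning("label ", label, " is disconnected; keeping largest component")
      sizes <- tabulate(comp[comp > 0])
      mask <- comp == which.max(sizes)
      keep <- which(mask)
      rr <- ((keep - 1) %% nrow(mask)) + 1
      cc <- ((keep - 1) %/% nrow(mask)) + 1
      mask <- mask[min(rr):max(rr), min(cc):max(cc), drop = FALSE]
      r0 <- r0 + min(rr) - 1; c0 <- c0 + min(cc) - 1
      r1 <- r0 + nrow(mask) - 1; c1 <- c0 + ncol(mask) - 1
    }
  }
  patch <- intensity[r0:r1, c0:c1, drop = FALSE]
  pix <- which(mask)
  py <- ((pix - 1) %% nrow(mask)) + 1
  px <- ((pix - 1) %/% nrow(mask)) + 1
  structure(list(
    mask = mask,
    intensity = patch,
    offset = c(row = r0 - 1L, col = c0 - 1L),
    centroid = c(x = mean(px - 1) + (c0 - 1), y = mean(py - 1) + (r0 - 1)),
    on_border = r0 == 1 || c0 == 1 || r1 == d[1] || c1 == d[2]
  ), class = "cell_instance")
}

# Pixel-centre coordinates (x = col, y = row, 0-based, in crop frame).
mask_coords <- function(mask) {
  pix <- which(mask)
  data.frame(x = ((pix - 1) %/% nrow(mask)), y = ((pix - 1) %% nrow(mask)))
}

# Count of unit edges between foreground and background/outside (4-neighbour).
mask_perimeter <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  up    <- pad[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]
  down  <- pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]
  left  <- pad[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]
  right <- pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE]
  sum(core & !up) + sum(core & !down) + sum(core & !left) + sum(core & !right)
}

# Boundary pixels: foreground with at least one 4-neighbour outside the mask.
boundary_mask <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  core <- pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
  up    <- pad[1:nrow(mask), 2:(ncol(mask) + 1), drop = FALSE]
  down  <- pad[3:(nrow(mask) + 2), 2:(ncol(mask) + 1), drop = FALSE]
  left  <- pad[2:(nrow(mask) + 1), 1:ncol(mask), drop = FALSE]
  right <- pad[2:(nrow(mask) + 1), 3:(ncol(mask) + 2), drop = FALSE]
  core & !(up & down & left & right)
}

# Moore-neighbour boundary trace: ordered outer boundary pixel centres,
# clockwise in image coordinates, as an (x, y) matrix. Assumes a connected
# mask.
trace_boundary <- function(mask) {
  pts <- mask_coords(mask)
  if (nrow(pts) == 1) return(cbind(x = pts$x, y = pts$y))
  d <- dim(mask)
  at <- function(r, c) r >= 1 && r <= d[1] && c >= 1 && c <= d[2] && mask[r, c]
  # neighbours in clockwise order starting east (dr, dc in 1-based row/col)
  nb <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
              c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  # start: topmost of the leftmost foreground pixels
  cstart <- min(which(apply(mask, 2, any)))
  rstart <- min(which(mask[, cstart]))
  path <- matrix(0L, nrow = 4 * sum(mask) + 4, ncol = 2)
  path[1, ] <- c(rstart, cstart)
  np <- 1L
  dir <- 7L  # came from the west: start searching from north-west-ish
  r <- rstart; c <- cstart
  repeat {
    found <- FALSE
    for (k in 0:7) {
      j <- ((dir + k) %% 8) + 1
      rr <- r + nb[j, 1]; cc <- c + nb[j, 2]
      if (at(rr, cc)) {
        np <- np + 1L
        path[np, ] <- c(rr, cc)
        # restart search from the direction just behind where we came from
        dir <- (j - 1 + 6) %% 8
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (np >= 3 && r == rstart && c == cstart) break
    if (np >= nrow(path) - 1) break
  }
  out <- path[seq_len(np), , drop = FALSE]
  if (np >= 2 && all(out[np, ] == out[1, ])) out <- out[-np, , drop = FALSE]
  cbind(x = out[, 2] - 1, y = out[, 1] - 1)
}

# Signed turning angles (radians) at each vertex of a closed polygon.
turning_angles <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(numeric(0))
  prev <- poly[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- poly[c(2:n, 1), , drop = FALSE]
  u <- poly - prev
  w <- nxt - poly
  keep <- rowSums(u^2) > 0 & rowSums(w^2) > 0
  u <- u[keep, , drop = FALSE]; w <- w[keep, , drop = FALSE]
  atan2(u[, 1] * w[, 2] - u[, 2] * w[, 1],
        u[, 1] * w[, 1] + u[, 2] * w[, 2])
}

# Count pixels of the bounding box whose centres lie inside or on the convex
# hull polygon (vertices in hull order).
hull_pixel_count <- function(hx, hy, xr, yr) {
  g <- expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2])
  n <- length(hx)
  inside <- rep(TRUE, nrow(g))
  eps <- 1e-9
  pos <- rep(FALSE, nrow(g)); neg <- rep(FALSE, nrow(g))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (hx[j] - hx[i]) * (g$y - hy[i]) - (hy[j] - hy[i]) * (g$x - hx[i])
    pos <- pos | cr > eps
    neg <- neg | cr < -eps
  }
  sum(!(pos & neg))
}

#' Size and shape features of one cell instance
#'
#' @param instance a `cell_instance`.
#' @return named numeric vector of the 8 size and 12 shape features.
#' @export
size_shape_features <- function(instance) {
  mask <- instance$mask
  pts <- mask_coords(mask)
  area <- nrow(pts)
  perim <- mask_perimeter(mask)
  bbox_area <- (max(pts$y) - min(pts$y) + 1) * (max(pts$x) - min(pts$x) + 1)

  # convex hull of pixel centres
  if (area >= 3) {
    h <- grDevices::chull(pts$x, pts$y)
    hx <- pts$x[h]; hy <- pts$y[h]
  } else {
    hx <- pts$x; hy <- pts$y
  }
  hull_area_poly <- polygon_area(hx, hy)
  if (length(hx) >= 3 && hull_area_poly > 0) {
    conv_per <- polygon_perimeter(hx, hy)
    conv_area <- hull_pixel_count(hx, hy, range(pts$x), range(pts$y))
  } else {
    # degenerate (point or collinear) hull
    conv_per <- 2 * max(polygon_perimeter(hx, hy) / 2,
                        sqrt(diff(range(pts$x))^2 + diff(range(pts$y))^2))
    conv_area <- area
  }

  # moment ellipse
  mx <- mean(pts$x); my <- mean(pts$y)
  mu20 <- mean((pts$x - mx)^2)
  mu02 <- mean((pts$y - my)^2)
  mu11 <- mean((pts$x - mx) * (pts$y - my))
  tr <- (mu20 + mu02) / 2
  det <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- max(tr + det, 0); l2 <- max(tr - det, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  if (l1 <= .Machine$double.eps) {
    aspect <- 1; ecc <- 0           # single pixel: degenerate convention
  } else if (l2 <= .Machine$double.eps) {
    aspect <- Inf; ecc <- 1
  } else {
    aspect <- major / minor
    ecc <- sqrt(1 - l2 / l1)
  }

  # boundary radius statistics
  bnd <- mask_coords(boundary_mask(mask))
  rad <- sqrt((bnd$x - mx)^2 + (bnd$y - my)^2)
  rad_sd <- if (length(rad) > 1) stats::sd(rad) else 0
  rad_ratio <- if (max(rad) > 0) min(rad) / max(rad) else 1

  # curvature along the traced outer boundary
  ang <- turning_angles(trace_boundary(mask))
  curv_mean <- if (length(ang) > 0) mean(ang) else 0
  curv_sd <- if (length(ang) > 1) stats::sd(ang) else 0

  c(Area = area,
    Perimeter = perim,
    ConvexArea = conv_area,
    ConvexPerimeter = conv_per,
    BoundingBoxArea = bbox_area,
    EquivalentDiameter = 2 * sqrt(area / pi),
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Circularity = 4 * pi * area / perim^2,
    AspectRatio = aspect,
    Eccentricity = ecc,
    Solidity = area / conv_area,
    Extent = area / bbox_area,
    Convexity = conv_per / perim,
    RadiusSD = rad_sd,
    RadiusSkewness = moment_skewness(rad),
    RadiusKurtosis = moment_kurtosis(rad),
    RadiusMinMaxRatio = rad_ratio,
    CurvatureMean = curv_mean,
    CurvatureSD = curv_sd)
}

#' Movement and density features
#'
#' @param instance a `cell_instance`.
#' @param context list with `centroids` (data.frame x, y of all cells in the
#'   frame, including this one), `self` (index of this cell in `centroids`,
#'   or NULL to match by coordinates), `prev_centroid` (x, y of this cell on
#'   the previous trajectory frame, or NULL on the first frame), `diagonal`
#'   (image diagonal in px) and optionally `density_radius` (default 100).
#' @return named numeric vector: DisplacementFromPrev, NeighbourCount,
#'   NearestNeighbourDistance, LocalDensity.
#' @export
movement_density_features <- function(instance, context) {
  cen <- instance$centroid
  disp <- 0
  if (!is.null(context$prev_centroid)) {
    disp <- sqrt(sum((cen - context$prev_centroid)^2))
  }
  radius <- context$density_radius %||% 100
  others <- context$centroids
  if (!is.null(context$self)) {
    others <- others[-context$self, , drop = FALSE]
  }
  if (nrow(others) == 0) {
    nn_count <- 0
    nn_dist <- context$diagonal
    local_density <- 0
  } else {
    d <- sqrt((others$x - cen["x"])^2 + (others$y - cen["y"])^2)
    nn_count <- sum(d <= radius)
    nn_dist <- min(d)
    local_density <- sum(1 / pmax(d, 1))
  }
  c(DisplacementFromPrev = unname(disp),
    NeighbourCount = nn_count,
    NearestNeighbourDistance = unname(nn_dist),
    LocalDensity = unname(local_density))
}

#' All 72 frame features for one cell instance
#'
#' @param instance a `cell_instance`.
#' @param context as for [movement_density_features()].
#' @return named numeric vector of length 72 in [feature_registry()] order.
#' @export
extract_frame_features <- function(instance, context) {
  v <- c(size_shape_features(instance),
         texture_features(instance),
         movement_density_features(instance, context))
  reg <- feature_registry()$name
  stopifnot(all(reg %in% names(v)))
  v[reg]
}
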