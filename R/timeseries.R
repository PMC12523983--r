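# Time-series summarisation: each of the 72 frame-feature series of a
# trajectory is reduced to 15 statistics (6 descriptive + 9 Haar-wavelet
# detail statistics at levels 1-3), and the centroid path contributes 3
# whole-trajectory movement features, giving the 1083-feature cell profile.

#' Orthonormal Haar detail coefficients
#'
#' Level-1 details for a pair (x1, x2) are (x2 - x1)/sqrt(2); deeper levels
#' recurse on the approximation coefficients (x1 + x2)/sqrt(2). Odd-length
#' inputs are right-padded by repeating the final value before pairing at
#' each level.
#'
#' @param x numeric series.
#' @param level 1, 2 or 3.
#' @return numeric vector of detail coefficients at that level.
#' @export
#' @examples
#' haar_details(c(2, 0), 1)      # -sqrt(2)
#' haar_details(1:8, 1)          # rep(1/sqrt(2), 4)
haar_details <- function(x, level) {
  if (length(level) != 1 || !level %in% 1:3) {
    stop("parameter error: level must be 1, 2 or 3")
  }
  dec <- haar_decompose(x, level)
  dec$details[[level]]
}

#' Multi-level Haar decomposition
#'
#' @param x numeric series (length >= 2).
#' @param levels number of levels (default 3).
#' @return list with `details` (list of detail-coefficient vectors per level)
#'   and `approx` (the final approximation coefficients).
#' @export
haar_decompose <- function(x, levels = 3) {
  stopifnot(length(x) >= 2)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    if (length(a) == 1) a <- c(a, a)
    if (length(a) %% 2 == 1) a <- c(a, a[length(a)])
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    details[[l]] <- (even - odd) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(details = details, approx = a)
}

#' Summarise one feature series into 15 statistics
#'
#' Mean, Median, SD (sample), Skewness, Kurtosis (excess; 0 for constant
#' series), Max, and for Haar levels 1-3 the detail energy (sum of squared
#' details), MaxAscent (max(0, max detail)) and MaxDescent (max(0, -min
#' detail)).
#'
#' @param x numeric series, length >= 8.
#' @return named numeric vector of length 15 in [summary_stat_names()] order.
#' @export
summarise_series <- function(x) {
  stopifnot(length(x) >= 2)
  out <- c(Mean = mean(x), Median = stats::median(x), SD = stats::sd(x),
           Skewness = moment_skewness(x), Kurtosis = moment_kurtosis(x),
           Max = max(x))
  dec <- haar_decompose(x, 3)
  for (l in 1:3) {
    d <- dec$details[[l]]
    out[paste0("DetailEnergy", l)] <- sum(d^2)
    out[paste0("MaxAscent", l)] <- max(0, max(d))
    out[paste0("MaxDescent", l)] <- max(0, -min(d))
  }
  out[summary_stat_names()]
}

#' Whole-trajectory movement features
#'
#' @param centroids data.frame or matrix of ordered (x, y) positions,
#'   >= 2 rows.
#' @return named vector: TotalTrackLength (sum of consecutive Euclidean
#'   steps), NetDisplacement (first to last), TrajectoryArea (convex hull
#'   area of the visited points; 0 when collinear).
#' @export
trajectory_features <- function(centroids) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 2) stop("parameter error: need at least 2 trajectory points")
  steps <- sqrt(rowSums((centroids[-1, , drop = FALSE] -
                           centroids[-n, , drop = FALSE])^2))
  net <- sqrt(sum((centroids[n, ] - centroids[1, ])^2))
  uniq <- unique(centroids)
  area <- 0
  if (nrow(uniq) >= 3) {
    h <- grDevices::chull(uniq[, 1], uniq[, 2])
    area <- polygon_area(uniq[h, 1], uniq[h, 2])
  }
  c(TotalTrackLength = sum(steps), NetDisplacement = net,
    TrajectoryArea = area)
}

# Split a trajectory's observed frames at gaps longer than max_gap missing
# frames; returns a list of index vectors into the observed records.
split_at_gaps <- function(frames, max_gap = 3) {
  gaps <- diff(frames) - 1
  cut <- which(gaps > max_gap)
  starts <- c(1, cut + 1)
  ends <- c(cut, length(frames))
  Map(function(s, e) s:e, starts, ends)
}

# Linear interpolation of a feature matrix (frames x features) onto the full
# frame range; observed frames keep their values exactly.
interpolate_gaps <- function(frames, mat) {
  full <- seq(min(frames), max(frames))
  if (length(full) == length(frames)) {
    return(list(frames = frames, mat = mat))
  }
  out <- apply(mat, 2, function(col) {
    stats::approx(frames, col, xout = full, method = "linear")$y
  })
  list(frames = full, mat = matrix(out, nrow = length(full),
                                   dimnames = list(NULL, colnames(mat))))
}

#' Summarise one trajectory into a 1083-feature cell profile
#'
#' The 72 frame-feature series are ordered registry-major, each contributing
#' its 15 summaries, followed by the 3 whole-trajectory features. Tracking
#' gaps of up to `max_gap` missing frames are bridged by linear interpolation
#' of features and centroids; longer gaps split the trajectory and only
#' segments of at least `min_track_length` frames are summarised (one profile
#' per qualifying segment, suffixed `.2`, `.3`, ... when a track splits).
#'
#' @param traj a `trajectory`.
#' @param frame_mat matrix of frame features (rows aligned to
#'   `traj$records`, 72 registry-named columns).
#' @param min_track_length minimum frames per summarised segment (default 8,
#'   the level-3 Haar support).
#' @param max_gap longest bridgeable gap in frames (default 3).
#' @return data.frame of profiles (possibly 0 rows): `track_id`, `class`
#'   (NA), then the 1083 profile features. Excluded segments are reported via
#'   a "excluded" attribute.
#' @export
summarise_trajectory <- function(traj, frame_mat, min_track_length = 8,
                                 max_gap = 3) {
  stopifnot(inherits(traj, "trajectory"))
  reg <- feature_registry()$name
  stopifnot(identical(colnames(frame_mat), reg))
  segs <- split_at_gaps(traj$records$frame, max_gap)
  rows <- list()
  excluded <- character(0)
  for (si in seq_along(segs)) {
    idx <- segs[[si]]
    frames <- traj$records$frame[idx]
    span <- max(frames) - min(frames) + 1
    if (span < min_track_length) {
      excluded <- c(excluded, sprintf(
        "track %s segment %d: %d frames < minimum %d",
        traj$track_id, si, span, min_track_length))
      next
    }
    fi <- interpolate_gaps(frames, frame_mat[idx, , drop = FALSE])
    ci <- interpolate_gaps(frames,
                           cbind(x = traj$records$x[idx],
                                 y = traj$records$y[idx]))
    summ <- as.vector(apply(fi$mat, 2, summarise_series))
    names(summ) <- as.vector(vapply(
      reg, function(f) paste(f, summary_stat_names(), sep = "_"),
      character(15)))
    tf <- trajectory_features(ci$mat)
    id <- if (length(segs) > 1) paste0(traj$track_id, ".", si)
          else as.character(traj$track_id)
    vals <- c(summ, tf)
    row <- cbind(data.frame(track_id = id, class = NA_character_,
                            stringsAsFactors = FALSE),
                 as.data.frame(matrix(vals, nrow = 1,
                                      dimnames = list(NULL, names(vals))),
                               check.names = FALSE))
    rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    empty <- as.data.frame(matrix(numeric(0), 0, N_PROFILE_FEATURES,
                                  dimnames = list(NULL, profile_registry()$name)),
                           check.names = FALSE)
    cbind(data.frame(track_id = character(0), class = character(0),
                     stringsAsFactors = FALSE), empty)
  }
  stopifnot(ncol(out) == N_PROFILE_FEATURES + 2)
  attr(out, "excluded") <- excluded
  out
}
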