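# Movie-level feature extraction: frame features for every trajectory record,
# then time-series summarisation into cell profiles.

#' Per-frame features for every tracked cell
#'
#' @param movie a `labelled_movie`.
#' @param trajectories list of `trajectory` objects from
#'   [link_tracks_to_masks()].
#' @param density_radius neighbour-count radius in pixels (default 100).
#' @return data.frame in long format: `frame`, `track_id`, `x`, `y`,
#'   `on_border`, then the 72 registry features.
#' @export
extract_features <- function(movie, trajectories, density_radius = 100) {
  stopifnot(inherits(movie, "labelled_movie"))
  reg <- feature_registry()$name
  d <- movie_dim(movie)
  diagonal <- sqrt(sum(d^2))
  if (length(trajectories) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(reg),
                                dimnames = list(NULL, reg)),
                         check.names = FALSE)
    return(cbind(data.frame(frame = integer(0), track_id = character(0),
                            x = numeric(0), y = numeric(0),
                            on_border = logical(0)), out))
  }
  # index records by frame
  recs <- do.call(rbind, lapply(trajectories, function(tr) {
    r <- tr$records
    r$track_id <- tr$track_id
    r$prev_x <- c(NA, r$x[-nrow(r)])
    r$prev_y <- c(NA, r$y[-nrow(r)])
    r
  }))
  out <- matrix(NA_real_, nrow(recs), length(reg),
                dimnames = list(NULL, reg))
  border <- logical(nrow(recs))
  for (f in sort(unique(recs$frame))) {
    in_f <- which(recs$frame == f)
    centroids <- data.frame(x = recs$x[in_f], y = recs$y[in_f])
    labm <- movie$labels[[f + 1]]
    img <- movie$intensity[[f + 1]]
    for (k in seq_along(in_f)) {
      i <- in_f[k]
      inst <- cell_instance(img, labm, recs$label[i])
      ctx <- list(
        centroids = centroids,
        self = k,
        prev_centroid = if (is.na(recs$prev_x[i])) NULL else
          c(x = recs$prev_x[i], y = recs$prev_y[i]),
        diagonal = diagonal,
        density_radius = density_radius
      )
      out[i, ] <- extract_frame_features(inst, ctx)
      border[i] <- inst$on_border
    }
  }
  res <- cbind(data.frame(frame = recs$frame, track_id = recs$track_id,
                          x = recs$x, y = recs$y, on_border = border),
               as.data.frame(out, check.names = FALSE))
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Build 1083-feature cell profiles for a movie
#'
#' Runs [extract_features()] and [summarise_trajectory()] over all
#' trajectories; trajectories (or post-split segments) shorter than
#' `min_track_length` frames are excluded with a logged reason.
#'
#' @inheritParams extract_features
#' @inheritParams summarise_trajectory
#' @param truth optional data.frame (`track_id`, `class`) of known labels to
#'   attach.
#' @param frame_features optional precomputed output of [extract_features()].
#' @return data.frame: `track_id`, `class`, then 1083 features; exclusion
#'   messages in attribute "excluded".
#' @export
cell_profiles <- function(movie, trajectories, truth = NULL,
                          min_track_length = 8, max_gap = 3,
                          density_radius = 100, frame_features = NULL) {
  if (is.null(frame_features)) {
    frame_features <- extract_features(movie, trajectories, density_radius)
  }
  reg <- feature_registry()$name
  rows <- list()
  excluded <- character(0)
  for (tr in trajectories) {
    sel <- frame_features$track_id == tr$track_id
    sub <- frame_features[sel, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    mat <- as.matrix(sub[, reg, drop = FALSE])
    prof <- summarise_trajectory(tr, mat, min_track_length, max_gap)
    excluded <- c(excluded, attr(prof, "excluded"))
    if (nrow(prof) > 0) rows[[length(rows) + 1]] <- prof
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    summarise_trajectory_empty()
  rownames(out) <- NULL
  if (!is.null(truth) && nrow(out) > 0) {
    base_id <- sub("\\.[0-9]+$", "", out$track_id)
    m <- match(base_id, as.character(truth$track_id))
    out$class <- as.character(truth$class[m])
  }
  for (msg in excluded) pt_log(msg, level = "INFO")
  attr(out, "excluded") <- excluded
  out
}

summarise_trajectory_empty <- function() {
  empty <- as.data.frame(matrix(numeric(0), 0, N_PROFILE_FEATURES,
                                dimnames = list(NULL, profile_registry()$name)),
                         check.names = FALSE)
  cbind(data.frame(track_id = character(0), class = character(0),
                   stringsAsFactors = FALSE), empty)
}
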