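# Reading image/mask stacks and tracking tables, linking tracks to mask
# labels, and round-tripping profile tables as plain CSV.

as_frame_matrix <- function(img, what) {
  if (is.list(img)) stop("unexpected nested image structure in ", what)
  d <- dim(img)
  if (length(d) == 3) {
    warning("multi-channel ", what, " reduced to first channel")
    img <- img[, , 1]
  }
  as.matrix(img)
}

read_tiff_frames <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no-input error: no TIFF files found in ", path)
    files <- files[natural_order(basename(files))]
    frames <- lapply(files, function(f) {
      as_frame_matrix(tiff::readTIFF(f, as.is = TRUE), f)
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, as_frame_matrix, what = path)
  } else {
    stop("no-input error: path does not exist: ", path)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("dimension-mismatch error: frames have differing sizes (",
         paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", "), ")")
  }
  frames
}

#' Read a grayscale time-lapse image stack
#'
#' Accepts either a multi-page TIFF or a directory of single-frame TIFFs.
#' Directory contents are ordered by natural sort of the filenames so that
#' `t2.tif` precedes `t10.tif`.
#'
#' @param path file or directory path.
#' @return list of numeric matrices, one per frame, all the same size.
#' @export
read_image_stack <- function(path) {
  lapply(read_tiff_frames(path), function(m) {
    storage.mode(m) <- "double"
    m
  })
}

#' Read a labelled-mask stack
#'
#' Same formats and ordering as [read_image_stack()], but values are rounded
#' to integer labels; 0 is background.
#'
#' @param path file or directory path.
#' @return list of integer matrices.
#' @export
read_label_stack <- function(path) {
  lapply(read_tiff_frames(path), function(m) {
    m <- round(m)
    storage.mode(m) <- "integer"
    m
  })
}

#' Bundle intensity and label stacks into a movie
#'
#' @param intensity list of numeric matrices (one per frame).
#' @param labels list of integer label matrices, congruent with `intensity`.
#' @param pixel_size optional physical scale (length per pixel).
#' @param frame_interval optional time per frame.
#' @return an object of class `labelled_movie`.
#' @export
labelled_movie <- function(intensity, labels, pixel_size = NULL,
                           frame_interval = NULL) {
  if (length(intensity) != length(labels)) {
    stop("dimension-mismatch error: ", length(intensity), " intensity frames vs ",
         length(labels), " label frames")
  }
  if (length(intensity) == 0) stop("no-input error: empty movie")
  for (i in seq_along(intensity)) {
    if (!identical(dim(intensity[[i]]), dim(labels[[i]]))) {
      stop("dimension-mismatch error: intensity and labels differ at frame ", i)
    }
    if (!identical(dim(intensity[[i]]), dim(intensity[[1]]))) {
      stop("dimension-mismatch error: frame ", i, " size differs from frame 1")
    }
  }
  structure(list(intensity = intensity, labels = labels,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "labelled_movie")
}

#' @export
print.labelled_movie <- function(x, ...) {
  d <- dim(x$intensity[[1]])
  cat(sprintf("labelled_movie: %d frames of %dx%d\n", length(x$intensity), d[1], d[2]))
  invisible(x)
}

n_frames <- function(movie) length(movie$intensity)

movie_dim <- function(movie) dim(movie$intensity[[1]])

#' Read a cell-tracking table
#'
#' Two dialects are supported. `generic`: a delimited file with header
#' `frame,cell,x,y`. `trackmate`: a TrackMate spots export with columns
#' `TRACK_ID`, `POSITION_X`, `POSITION_Y`, `FRAME`; the non-numeric
#' unit-description rows TrackMate writes below the header are skipped.
#' Frames are normalised to a 0-based index (TrackMate `FRAME` already is;
#' the generic dialect declares its base via `frame_base`).
#'
#' @param path delimited text file.
#' @param dialect `"generic"` or `"trackmate"`.
#' @param frame_base frame index of the first movie frame in the generic
#'   dialect (default 0).
#' @return data.frame with columns `frame` (0-based integer), `cell`
#'   (integer track id), `x`, `y` (real pixel coordinates; x = column,
#'   y = row, 0-based).
#' @export
read_track_table <- function(path, dialect = c("generic", "trackmate"),
                             frame_base = 0) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "generic") {
    cols <- c("frame", "cell", "x", "y")
  } else {
    cols <- c("FRAME", "TRACK_ID", "POSITION_X", "POSITION_Y")
  }
  for (cl in cols) {
    if (!cl %in% names(raw)) stop("schema error: missing required column '", cl, "'")
  }
  raw <- raw[, cols, drop = FALSE]
  names(raw) <- c("frame", "cell", "x", "y")
  # TrackMate exports carry extra descriptive header rows; drop any row that
  # does not parse as numeric.
  num <- suppressWarnings(vapply(raw, function(v) as.numeric(v), numeric(nrow(raw))))
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(raw)))
  keep <- stats::complete.cases(num)
  tab <- as.data.frame(num[keep, , drop = FALSE])
  if (dialect == "generic") tab$frame <- tab$frame - frame_base
  tab$frame <- as.integer(round(tab$frame))
  tab$cell <- as.integer(round(tab$cell))
  if (anyDuplicated(tab[, c("frame", "cell")])) {
    stop("duplication error: repeated (frame, cell) pair in ", path)
  }
  tab[order(tab$cell, tab$frame), , drop = FALSE]
}

#' Link tracking rows to mask labels
#'
#' For each tracking row the mask label at the nearest integer pixel to
#' `(x, y)` is looked up (half-away-from-zero rounding). If that pixel is
#' background, labels within a Chebyshev radius (default 2) are searched and
#' the nearest non-zero one taken. Rows that remain unresolved are dropped
#' with a warning. Rows are grouped by track id into trajectories sorted by
#' frame.
#'
#' @param tracks data.frame from [read_track_table()].
#' @param movie a `labelled_movie`.
#' @param rescue_radius Chebyshev search radius for background centroids.
#' @return list of `trajectory` objects: each has `track_id` and a data.frame
#'   `records` with `frame`, `x`, `y`, `label`.
#' @export
link_tracks_to_masks <- function(tracks, movie, rescue_radius = 2) {
  stopifnot(inherits(movie, "labelled_movie"))
  nf <- n_frames(movie)
  if (nrow(tracks) > 0 && (min(tracks$frame) < 0 || max(tracks$frame) >= nf)) {
    stop("frame index out of movie range [0, ", nf - 1, "]")
  }
  d <- movie_dim(movie)
  off <- expand.grid(dr = -rescue_radius:rescue_radius,
                     dc = -rescue_radius:rescue_radius)
  labels <- integer(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    labm <- movie$labels[[tracks$frame[i] + 1]]
    pc <- round_half_away(tracks$x[i])   # 0-based column
    pr <- round_half_away(tracks$y[i])   # 0-based row
    lab <- 0L
    if (pr >= 0 && pr < d[1] && pc >= 0 && pc < d[2]) lab <- labm[pr + 1, pc + 1]
    if (lab == 0L) {
      rr <- pr + off$dr
      cc <- pc + off$dc
      ok <- rr >= 0 & rr < d[1] & cc >= 0 & cc < d[2]
      cand <- labm[cbind(rr[ok] + 1, cc[ok] + 1)]
      nz <- cand != 0L
      if (any(nz)) {
        dist2 <- (cc[ok][nz] - tracks$x[i])^2 + (rr[ok][nz] - tracks$y[i])^2
        best <- order(dist2, cand[nz])[1]
        lab <- cand[nz][best]
      }
    }
    labels[i] <- lab
  }
  dropped <- labels == 0L
  if (any(dropped)) {
    warning(sum(dropped), " tracking row(s) had no mask label within radius ",
            rescue_radius, " and were dropped")
  }
  tab <- tracks[!dropped, , drop = FALSE]
  tab$label <- labels[!dropped]
  lapply(split(tab, tab$cell), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    structure(list(track_id = g$cell[1],
                   records = data.frame(frame = g$frame, x = g$x, y = g$y,
                                        label = g$label)),
              class = "trajectory")
  })
}

#' Write a cell-profile table to delimited text
#'
#' The header carries `track_id`, `class`, then the 1083 profile feature
#' names in registry order. The round trip through [read_feature_table()] is
#' lossless to at least 12 significant digits.
#'
#' @param profiles data.frame with columns `track_id`, `class` and the 1083
#'   profile features.
#' @param path output file.
#' @export
write_feature_table <- function(profiles, path) {
  if (is.null(profiles) || nrow(profiles) == 0) {
    stop("no-input error: empty profile table")
  }
  check_profile_columns(profiles)
  utils::write.csv(profiles, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

check_profile_columns <- function(profiles) {
  want <- c("track_id", "class", profile_registry()$name)
  if (!identical(names(profiles), want)) {
    if (ncol(profiles) != length(want)) {
      stop("dimension error: profile table has ", ncol(profiles),
           " columns, expected ", length(want))
    }
    stop("schema error: profile column names do not match the registry")
  }
  invisible(TRUE)
}

#' Read a cell-profile table written by [write_feature_table()]
#' @param path input file.
#' @return data.frame with `track_id`, `class` and 1083 feature columns.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_profile_columns(tab)
  tab$track_id <- as.character(tab$track_id)
  tab$class <- as.character(tab$class)
  tab$class[tab$class == ""] <- NA_character_
  tab
}

#' Write a movie to disk in the formats the readers accept
#'
#' Intensities and labels are written as 16-bit multi-page TIFFs, the track
#' table as a generic-dialect CSV.
#'
#' @param movie a `labelled_movie` (intensities in [0, 65535]).
#' @param tracks generic track table data.frame.
#' @param dir output directory (created if missing).
#' @return named list of the written paths.
#' @export
write_movie <- function(movie, tracks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ipath <- file.path(dir, "intensity.tif")
  lpath <- file.path(dir, "labels.tif")
  tpath <- file.path(dir, "tracks.csv")
  tiff::writeTIFF(lapply(movie$intensity, function(m) round(m) / 65535),
                  ipath, bits.per.sample = 16)
  tiff::writeTIFF(lapply(movie$labels, function(m) m / 65535),
                  lpath, bits.per.sample = 16)
  utils::write.csv(tracks[, c("frame", "cell", "x", "y")], tpath,
                   row.names = FALSE)
  list(intensity = ipath, labels = lpath, tracks = tpath)
}
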