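# Pipeline orchestration: a resolved run configuration plus the simulate /
# extract / select / classify commands that tie the stages together. Every
# command writes its outputs under config$out together with a JSON metadata
# block carrying the full resolved configuration, the seed and the registry
# version, so runs are self-describing and reproducible.

#' Build (or load) a run configuration
#'
#' @param config named list of settings, or path to a YAML file of them.
#'   Recognised keys: `images`, `masks`, `tracks` (input paths), `dialect`
#'   ("generic"/"trackmate"), `frame_base`, `min_track_length`, `max_gap`,
#'   `density_radius`, `seed`, `out` (output directory), `n_trees`,
#'   `max_depth`, `eta`, `test_fraction`, `regroup` (named mapping).
#' @return object of class `run_config` with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    images = NULL, masks = NULL, tracks = NULL,
    dialect = "generic", frame_base = 0,
    min_track_length = 8, max_gap = 3, density_radius = 100,
    seed = 1, out = "phenotrack_run",
    n_trees = 200, max_depth = 4, eta = 0.1,
    test_fraction = 0.3, regroup = NULL
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, logical(1))])
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

ensure_out <- function(cfg) {
  if (!dir.exists(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE)
    pt_log(paste("created output directory", cfg$out))
  }
  cfg$out
}

write_run_metadata <- function(cfg, stage, extra = list()) {
  meta <- c(list(stage = stage, seed = cfg$seed,
                 registry_version = REGISTRY_VERSION,
                 config = unclass(cfg)), extra)
  path <- file.path(cfg$out, paste0(stage, ".meta.json"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Simulate a movie and write it to disk
#'
#' Writes `intensity.tif`, `labels.tif`, `tracks.csv` (generic dialect) and
#' `truth.csv` under `config$out`, in the formats the readers accept.
#'
#' @param config a [run_config()] (or list); `spec` may be a
#'   [population_spec()] — by default the two-class motility fixture built
#'   from `config$seed` is used.
#' @param spec optional `population_spec`.
#' @return list of written paths (invisibly) plus the simulation in memory.
#' @export
cmd_simulate <- function(config = list(), spec = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  ensure_out(cfg)
  sim <- if (is.null(spec)) two_class_motility_fixture(cfg$seed) else
    simulate_population(spec)
  paths <- write_movie(sim$movie, sim$tracks, cfg$out)
  truth_path <- file.path(cfg$out, "truth.csv")
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  write_run_metadata(cfg, "simulate")
  pt_log(sprintf("simulated %d frames, %d cells -> %s",
                 n_frames(sim$movie), nrow(sim$truth), cfg$out))
  invisible(c(paths, list(truth = truth_path, sim = sim)))
}

#' Extract per-frame features and cell profiles from disk inputs
#'
#' Reads the image, mask and track files named in the config, links tracks to
#' mask labels, and writes `frame_features.csv`, `profiles.csv` and an
#' exclusion log under `config$out`.
#'
#' @param config a [run_config()] or list with `images`, `masks`, `tracks`.
#' @return the profile table (invisibly).
#' @export
cmd_extract <- function(config) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  for (key in c("images", "masks", "tracks")) {
    if (is.null(cfg[[key]])) stop("parameter error: config lacks '", key, "'")
  }
  ensure_out(cfg)
  movie <- labelled_movie(read_image_stack(cfg$images),
                          read_label_stack(cfg$masks))
  tracks <- read_track_table(cfg$tracks, dialect = cfg$dialect,
                             frame_base = cfg$frame_base)
  truth <- NULL
  truth_path <- file.path(dirname(cfg$tracks), "truth.csv")
  if (file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  trajectories <- link_tracks_to_masks(tracks, movie)
  ff <- extract_features(movie, trajectories, cfg$density_radius)
  profiles <- cell_profiles(movie, trajectories, truth = truth,
                            min_track_length = cfg$min_track_length,
                            max_gap = cfg$max_gap,
                            density_radius = cfg$density_radius,
                            frame_features = ff)
  utils::write.csv(ff, file.path(cfg$out, "frame_features.csv"),
                   row.names = FALSE)
  if (nrow(profiles) > 0) {
    write_feature_table(profiles, file.path(cfg$out, "profiles.csv"))
  } else {
    utils::write.csv(profiles, file.path(cfg$out, "profiles.csv"),
                     row.names = FALSE)
    warning("no qualifying trajectories; empty profile table written")
  }
  writeLines(attr(profiles, "excluded") %||% character(0),
             file.path(cfg$out, "exclusions.log"))
  write_run_metadata(cfg, "extract",
                     list(n_profiles = nrow(profiles),
                          n_excluded = length(attr(profiles, "excluded"))))
  pt_log(sprintf("extracted %d profiles (%d exclusions)", nrow(profiles),
                 length(attr(profiles, "excluded"))))
  invisible(profiles)
}

#' Rank features, pick the elbow threshold, write reduced profiles
#'
#' @param config a [run_config()]; `profiles` defaults to
#'   `<out>/profiles.csv`. An optional `regroup` mapping in the config is
#'   applied before scoring.
#' @param profiles optional in-memory profile table.
#' @return the `separation_result` (invisibly).
#' @export
cmd_select <- function(config, profiles = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  ensure_out(cfg)
  if (is.null(profiles)) {
    profiles <- read_feature_table(file.path(cfg$out, "profiles.csv"))
  }
  if (!is.null(cfg$regroup)) {
    profiles <- regroup_labels(profiles, unlist(cfg$regroup))
  }
  result <- feature_selection(profiles)
  write_selection(result, file.path(cfg$out, "separation_scores.csv"))
  reduced <- select_features(profiles, result)
  utils::write.csv(reduced, file.path(cfg$out, "profiles_selected.csv"),
                   row.names = FALSE)
  write_run_metadata(cfg, "select",
                     list(threshold = result$threshold,
                          n_selected = length(result$selected)))
  pt_log(sprintf("selection threshold %.4g, %d/%d features kept",
                 result$threshold, length(result$selected),
                 nrow(result$scores)))
  invisible(result)
}

#' Train and evaluate a classifier, write the confusion report
#'
#' Splits the labelled profiles into train/test with a seeded stratified
#' split (unless a separate `test` table is supplied), trains the boosted
#' classifier on the selected features and writes `confusion.csv` and
#' `tpr.csv` under `config$out`.
#'
#' @param config a [run_config()].
#' @param profiles optional in-memory profile table (default
#'   `<out>/profiles.csv`).
#' @param selection optional `separation_result` (default recomputed).
#' @param test optional separate labelled test table.
#' @return list(model, confusion) invisibly.
#' @export
cmd_classify <- function(config, profiles = NULL, selection = NULL,
                         test = NULL) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  ensure_out(cfg)
  if (is.null(profiles)) {
    profiles <- read_feature_table(file.path(cfg$out, "profiles.csv"))
  }
  if (!is.null(cfg$regroup)) {
    profiles <- regroup_labels(profiles, unlist(cfg$regroup))
  }
  if (is.null(selection)) selection <- feature_selection(profiles)
  if (is.null(test)) {
    is_test <- stratified_split(profiles$class, cfg$test_fraction, cfg$seed)
    train <- profiles[!is_test, , drop = FALSE]
    test <- profiles[is_test, , drop = FALSE]
  } else {
    train <- profiles
  }
  model <- train_classifier(train, selection, n_trees = cfg$n_trees,
                            max_depth = cfg$max_depth, eta = cfg$eta,
                            seed = cfg$seed)
  confusion <- evaluate_classifier(model, test)
  utils::write.csv(as.data.frame(confusion$confusion),
                   file.path(cfg$out, "confusion.csv"), row.names = TRUE)
  utils::write.csv(data.frame(class = names(confusion$tpr),
                              tpr_percent = as.numeric(confusion$tpr)),
                   file.path(cfg$out, "tpr.csv"), row.names = FALSE)
  write_run_metadata(cfg, "classify",
                     list(macro_tpr = confusion$macro_tpr,
                          tpr = as.list(confusion$tpr)))
  pt_log(sprintf("classification macro TPR %.1f%%", confusion$macro_tpr))
  invisible(list(model = model, confusion = confusion))
}

#' Run the full pipeline: simulate, extract, select, classify
#'
#' @param config a [run_config()] or list; if `images`/`masks`/`tracks` are
#'   unset the synthetic motility fixture is simulated first.
#' @return list with profiles, selection result and confusion summary.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  if (is.null(cfg$images)) {
    paths <- cmd_simulate(cfg)
    cfg$images <- paths$intensity
    cfg$masks <- paths$labels
    cfg$tracks <- paths$tracks
  }
  profiles <- cmd_extract(cfg)
  selection <- cmd_select(cfg, profiles = profiles)
  fit <- cmd_classify(cfg, profiles = profiles, selection = selection)
  invisible(list(profiles = profiles, selection = selection,
                 model = fit$model, confusion = fit$confusion))
}
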