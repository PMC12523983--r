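# Multiclass separation-score feature ranking and elbow-point threshold
# selection.
#
# For a feature measured on G labelled classes with sizes n_g, means x_g and
# sample variances s_g^2 (N = sum n_g):
#   grand mean      xbar = (1/N) sum n_g x_g
#   between-class   VB   = (1/(N-G)) sum n_g (x_g - xbar)^2
#   within-class    VW   = (1/(N-G)) sum (n_g - 1) s_g^2
#   Separation           = VB / VW
# Higher scores mark more discriminatory features. Conventions for the
# degenerate cases: VB = 0 gives score 0 regardless of VW; VW = 0 with
# VB > 0 gives +Inf (perfectly separated constant classes).

#' Separation score of one feature across labelled classes
#'
#' @param values list of numeric vectors, one per class (G >= 2, every class
#'   non-empty, total N > G).
#' @return single number: the between/within-class variance ratio.
#' @export
#' @examples
#' separation_score(list(c(1, 3), c(5, 7)))   # 4
separation_score <- function(values) {
  G <- length(values)
  if (G < 2) stop("parameter error: need at least 2 classes")
  n <- vapply(values, length, integer(1))
  if (any(n < 1)) stop("parameter error: empty class")
  N <- sum(n)
  if (N <= G) stop("parameter error: need N > G observations")
  means <- vapply(values, mean, numeric(1))
  vars <- vapply(values, function(v) if (length(v) > 1) stats::var(v) else 0,
                 numeric(1))
  grand <- sum(n * means) / N
  VB <- sum(n * (means - grand)^2) / (N - G)
  VW <- sum((n - 1) * vars) / (N - G)
  if (VB == 0) return(0)
  if (VW == 0) return(Inf)
  VB / VW
}

#' Separation scores for every profile feature
#'
#' Scores each feature column of a labelled profile table. Features carrying
#' non-finite values in some cells are scored on the finite subset and
#' flagged; a feature left with fewer than 2 populated classes (or N <= G)
#' scores NA.
#'
#' @param profiles data.frame with a `class` column and feature columns
#'   (typically the 1083-column profile table; `track_id` is ignored).
#' @param features optional character vector restricting which columns to
#'   score (default: all profile-registry columns present, or all numeric
#'   columns otherwise).
#' @return data.frame: `feature`, `category`, `score`, `n_used`, `flagged`.
#' @export
separation_scores <- function(profiles, features = NULL) {
  cls <- profiles$class
  if (is.null(cls)) stop("parameter error: profiles carry no class column")
  keep <- !is.na(cls)
  profiles <- profiles[keep, , drop = FALSE]
  cls <- cls[keep]
  if (length(unique(cls)) < 2) {
    stop("parameter error: separation scores need at least 2 classes")
  }
  reg <- profile_registry()
  if (is.null(features)) {
    features <- if (all(reg$name %in% names(profiles))) reg$name else
      setdiff(names(profiles)[vapply(profiles, is.numeric, logical(1))],
              c("track_id"))
  }
  cat_of <- stats::setNames(reg$category, reg$name)
  score_one <- function(fname) {
    x <- profiles[[fname]]
    ok <- is.finite(x)
    flag <- any(!ok)
    groups <- split(x[ok], cls[ok])
    groups <- groups[vapply(groups, length, integer(1)) > 0]
    if (length(groups) < 2 || sum(lengths(groups)) <= length(groups)) {
      return(list(score = NA_real_, n = sum(ok), flag = TRUE))
    }
    list(score = separation_score(groups), n = sum(ok), flag = flag)
  }
  res <- lapply(features, score_one)
  data.frame(
    feature = features,
    category = unname(cat_of[features]),
    score = vapply(res, `[[`, numeric(1), "score"),
    n_used = vapply(res, `[[`, numeric(1), "n"),
    flagged = vapply(res, `[[`, logical(1), "flag"),
    stringsAsFactors = FALSE
  )
}

#' Elbow-point threshold on a score vector
#'
#' Scores are sorted in descending order; a straight line is drawn from the
#' maximum to the minimum finite score; the elbow is the score with the
#' largest vertical distance below that line (signed: points above the chord
#' cannot be elbows; ties take the smallest index, i.e. fewest features). The
#' threshold is the score at the elbow. Infinite scores rank first, are
#' always selected, and are excluded from the chord fit. With two or fewer
#' finite scores the threshold is the minimum score (all selected).
#'
#' @param scores numeric vector (NAs ignored).
#' @return list: `threshold`, `elbow_index` (1-based position in the
#'   descending finite scores, NA in degenerate cases), `n_selected`.
#' @export
#' @examples
#' elbow_threshold(c(10, 9, 1, 0.5, 0.4))  # threshold 1, 3 selected
elbow_threshold <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(s) == 0) stop("parameter error: no scores")
  s <- sort(s, decreasing = TRUE)
  fin <- s[is.finite(s)]
  n_inf <- sum(!is.finite(s))
  K <- length(fin)
  if (K == 0) {
    return(list(threshold = Inf, elbow_index = NA_integer_,
                n_selected = n_inf))
  }
  if (K <= 2) {
    thr <- min(fin)
    return(list(threshold = thr, elbow_index = NA_integer_,
                n_selected = n_inf + sum(fin >= thr)))
  }
  i <- seq_len(K) - 1
  line <- fin[1] + (fin[K] - fin[1]) * i / (K - 1)
  dist <- line - fin
  elbow <- which.max(dist)  # ties: smallest index
  thr <- fin[elbow]
  list(threshold = thr, elbow_index = elbow,
       n_selected = n_inf + sum(fin >= thr))
}

#' Rank features and pick the elbow threshold
#'
#' @param profiles labelled profile table (see [separation_scores()]).
#' @param features optional restriction of columns to score.
#' @return object of class `separation_result`: the score table (descending,
#'   with a `selected` column), `threshold`, `elbow_index`,
#'   `selected` feature names.
#' @export
feature_selection <- function(profiles, features = NULL) {
  tab <- separation_scores(profiles, features)
  ord <- order(-is.infinite(tab$score), -tab$score, tab$feature,
               na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  eb <- elbow_threshold(tab$score)
  tab$selected <- !is.na(tab$score) & tab$score >= eb$threshold
  structure(list(scores = tab, threshold = eb$threshold,
                 elbow_index = eb$elbow_index,
                 selected = tab$feature[tab$selected]),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("separation_result: %d features scored, threshold %.4g, %d selected\n",
              nrow(x$scores), x$threshold, length(x$selected)))
  cat("top features:\n")
  print(utils::head(x$scores[, c("feature", "category", "score")], 5))
  invisible(x)
}

#' Reduce a profile table to the selected features
#'
#' @param profiles profile table.
#' @param result a `separation_result` (or character vector of feature
#'   names).
#' @return profiles restricted to `track_id`, `class` (if present) and the
#'   selected feature columns, original order preserved.
#' @export
select_features <- function(profiles, result) {
  sel <- if (inherits(result, "separation_result")) result$selected else result
  if (length(sel) == 0) stop("parameter error: empty selection")
  keep <- intersect(names(profiles), c("track_id", "class"))
  cols <- names(profiles)[names(profiles) %in% sel]
  profiles[, c(keep, cols), drop = FALSE]
}

#' Write a separation-score table and its threshold metadata
#'
#' @param result a `separation_result`.
#' @param path CSV output path; a JSON sidecar `<path>.meta.json` records the
#'   threshold and elbow index.
#' @export
write_selection <- function(result, path) {
  utils::write.csv(result$scores, path, row.names = FALSE)
  meta <- list(threshold = result$threshold,
               elbow_index = result$elbow_index,
               n_selected = length(result$selected),
               registry_version = REGISTRY_VERSION)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
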