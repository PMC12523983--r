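# The canonical feature registry. Its shape is frozen: 72 per-frame features
# (size 8, shape 12, texture 48, movement 1, density 3), each summarised over
# a trajectory by 15 statistics, plus 3 whole-trajectory features, giving the
# fixed 1083-column cell profile. Code elsewhere relies on this ordering;
# bump REGISTRY_VERSION if it ever changes.

REGISTRY_VERSION <- "1.0"

TEXTURE_SCALES <- c("s1", "s2", "s4")

texture_stat_names <- function() {
  c("IntensityMean", "IntensitySD", "IntensitySkewness", "IntensityKurtosis",
    "IntensityRange", "IntensityEntropy",
    "ASM", "Contrast", "Correlation", "GLCMVariance", "Homogeneity",
    "SumAverage", "SumEntropy", "GLCMEntropy", "Dissimilarity", "SumVariance")
}

#' The per-frame feature registry
#'
#' Returns the canonical ordered registry of the 72 single-cell features
#' computed on every frame, tagged by category. Texture features are computed
#' at three spatial scales (`s1` original, `s2`/`s4` block-mean downsampled).
#'
#' @return a data.frame with columns `name` and `category`
#'   (size/shape/texture/movement/density), exactly 72 rows.
#' @export
feature_registry <- function() {
  size <- c("Area", "Perimeter", "ConvexArea", "ConvexPerimeter",
            "BoundingBoxArea", "EquivalentDiameter",
            "MajorAxisLength", "MinorAxisLength")
  shape <- c("Circularity", "AspectRatio", "Eccentricity", "Solidity",
             "Extent", "Convexity", "RadiusSD", "RadiusSkewness",
             "RadiusKurtosis", "RadiusMinMaxRatio",
             "CurvatureMean", "CurvatureSD")
  texture <- as.vector(vapply(
    TEXTURE_SCALES,
    function(sc) paste0(texture_stat_names(), "_", sc),
    character(16)
  ))
  movement <- "DisplacementFromPrev"
  density <- c("NeighbourCount", "NearestNeighbourDistance", "LocalDensity")
  data.frame(
    name = c(size, shape, texture, movement, density),
    category = c(rep("size", length(size)), rep("shape", length(shape)),
                 rep("texture", length(texture)), rep("movement", length(movement)),
                 rep("density", length(density))),
    stringsAsFactors = FALSE
  )
}

#' Names of the 15 per-series summary statistics
#' @return character vector of length 15.
#' @export
summary_stat_names <- function() {
  c("Mean", "Median", "SD", "Skewness", "Kurtosis", "Max",
    paste0("DetailEnergy", 1:3),
    paste0("MaxAscent", 1:3),
    paste0("MaxDescent", 1:3))
}

trajectory_feature_names <- function() {
  c("TotalTrackLength", "NetDisplacement", "TrajectoryArea")
}

#' The cell-profile registry
#'
#' The fixed-order registry of the 1083 profile features: each of the 72
#' frame features crossed with the 15 time-series summaries (registry-major
#' order), followed by the 3 whole-trajectory movement features.
#'
#' @return a data.frame with columns `name` and `category`, exactly 1083 rows.
#' @export
profile_registry <- function() {
  fr <- feature_registry()
  ss <- summary_stat_names()
  data.frame(
    name = c(as.vector(t(outer(fr$name, ss, paste, sep = "_"))),
             trajectory_feature_names()),
    category = c(rep(fr$category, each = length(ss)), rep("movement", 3)),
    stringsAsFactors = FALSE
  )
}

N_FRAME_FEATURES <- 72L
N_PROFILE_FEATURES <- 1083L
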