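# Texture features: first-order intensity statistics and grey-level
# co-occurrence (GLCM) statistics, each computed at three spatial scales of
# the cropped cell patch (original, 2x and 4x block-mean downsampled).
#
# Quantisation for the GLCM is per-cell min-max to 16 levels, so all
# co-occurrence statistics are invariant under positive affine rescaling of
# the intensities (illumination invariance). The four distance-1 offsets
# (0, 45, 90, 135 degrees) are each accumulated symmetrically, the 10
# statistics computed per offset, and averaged over the offsets that contain
# at least one valid (both-inside-the-mask) pixel pair.

GLCM_LEVELS <- 16L

# Block-mean downsample of an intensity patch; the mask survives where at
# least half the block is foreground. Edges are padded by replication
# (intensity) and background (mask).
block_downsample <- function(patch, mask, k) {
  nr <- nrow(patch); nc <- ncol(patch)
  NR <- ceiling(nr / k) * k; NC <- ceiling(nc / k) * k
  ri <- pmin(seq_len(NR), nr); ci <- pmin(seq_len(NC), nc)
  p <- patch[ri, ci, drop = FALSE]
  m <- matrix(FALSE, NR, NC)
  m[seq_len(nr), seq_len(nc)] <- mask
  br <- (seq_len(NR) - 1) %/% k
  bc <- (seq_len(NC) - 1) %/% k
  grp <- outer(br, bc * (NR %/% k), "+") + 1
  pm <- matrix(tapply(p, grp, mean), NR %/% k, NC %/% k)
  mm <- matrix(tapply(m, grp, sum), NR %/% k, NC %/% k) >= (k * k / 2)
  list(patch = pm, mask = mm)
}

quantise_levels <- function(values, levels = GLCM_LEVELS) {
  rng <- max(values) - min(values)
  if (rng <= 0) return(rep(0L, length(values)))
  pmin(as.integer(floor((values - min(values)) / rng * levels)), levels - 1L)
}

# 10 Haralick-style statistics from a symmetric co-occurrence probability
# matrix over levels 0..L-1. Zero marginal variance => Correlation 0.
glcm_stats <- function(P) {
  L <- nrow(P)
  lev <- 0:(L - 1)
  ii <- matrix(lev, L, L)
  jj <- t(ii)
  px <- rowSums(P)
  mu <- sum(lev * px)
  sig2 <- sum((lev - mu)^2 * px)
  corr <- if (sig2 <= .Machine$double.eps) 0 else
    (sum(ii * jj * P) - mu^2) / sig2
  # distribution of i + j
  k <- 0:(2 * L - 2)
  pxy <- as.numeric(rowsum(as.vector(P), as.vector(ii + jj)))
  sum_avg <- sum(k * pxy)
  nzP <- P[P > 0]
  nzS <- pxy[pxy > 0]
  c(ASM = sum(P^2),
    Contrast = sum(P * (ii - jj)^2),
    Correlation = corr,
    GLCMVariance = sig2,
    Homogeneity = sum(P / (1 + (ii - jj)^2)),
    SumAverage = sum_avg,
    SumEntropy = -sum(nzS * log(nzS)),
    GLCMEntropy = -sum(nzP * log(nzP)),
    Dissimilarity = sum(P * abs(ii - jj)),
    SumVariance = sum((k - sum_avg)^2 * pxy))
}

# Co-occurrence statistics of a quantised patch (integer matrix, NA outside
# the mask): per-offset symmetric GLCMs averaged over offsets with pairs.
glcm_features <- function(q) {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nr <- nrow(q); nc <- ncol(q)
  acc <- NULL
  n_used <- 0
  for (of in offsets) {
    dr <- of[1]; dc <- of[2]
    rlo <- max(1, 1 - dr); rhi <- min(nr, nr - dr)
    clo <- max(1, 1 - dc); chi <- min(nc, nc - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi
    c1 <- clo:chi
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] * GLCM_LEVELS + b[ok] + 1
    M <- matrix(tabulate(code, nbins = GLCM_LEVELS^2),
                GLCM_LEVELS, GLCM_LEVELS, byrow = TRUE)
    M <- M + t(M)
    P <- M / sum(M)
    st <- glcm_stats(P)
    acc <- if (is.null(acc)) st else acc + st
    n_used <- n_used + 1
  }
  if (n_used == 0) {
    # no valid pixel pair at this scale: zero-information convention
    st <- glcm_stats(matrix(0, GLCM_LEVELS, GLCM_LEVELS))
    st[] <- 0
    return(st)
  }
  acc / n_used
}

first_order_stats <- function(values) {
  if (length(values) == 0) {
    return(c(IntensityMean = 0, IntensitySD = 0, IntensitySkewness = 0,
             IntensityKurtosis = 0, IntensityRange = 0, IntensityEntropy = 0))
  }
  rng <- max(values) - min(values)
  if (rng <= 0) {
    ent <- 0
  } else {
    h <- tabulate(pmin(floor((values - min(values)) / rng * 16), 15) + 1,
                  nbins = 16)
    p <- h[h > 0] / length(values)
    ent <- -sum(p * log2(p))
  }
  c(IntensityMean = mean(values),
    IntensitySD = if (length(values) > 1) stats::sd(values) else 0,
    IntensitySkewness = moment_skewness(values),
    IntensityKurtosis = moment_kurtosis(values),
    IntensityRange = rng,
    IntensityEntropy = ent)
}

#' Texture features of one cell instance
#'
#' 16 statistics (6 first-order on the masked intensities, 10 co-occurrence)
#' at each of three scales: the original crop (`s1`) and 2x / 4x block-mean
#' downsamples (`s2`, `s4`).
#'
#' @param instance a `cell_instance` with at least 4 interior pixels.
#' @return named numeric vector of 48 texture features.
#' @export
texture_features <- function(instance) {
  out <- numeric(0)
  for (sc in TEXTURE_SCALES) {
    k <- c(s1 = 1, s2 = 2, s4 = 4)[[sc]]
    if (k == 1) {
      patch <- instance$intensity; mask <- instance$mask
    } else {
      ds <- block_downsample(instance$intensity, instance$mask, k)
      patch <- ds$patch; mask <- ds$mask
    }
    vals <- patch[mask]
    fo <- first_order_stats(vals)
    q <- matrix(NA_integer_, nrow(patch), ncol(patch))
    if (length(vals) > 0) q[mask] <- quantise_levels(vals)
    gl <- glcm_features(q)
    stats16 <- c(fo, gl)
    names(stats16) <- paste0(names(stats16), "_", sc)
    out <- c(out, stats16)
  }
  out
}
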