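#' @keywords internal
"_PACKAGE"

# Timestamped, levelled logging to console (message stream) and optionally a file.
pt_log <- function(msg, level = "INFO", logfile = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}

#' Natural sort order for filenames
#'
#' Orders strings so that runs of digits compare numerically: `t2.tif` sorts
#' before `t10.tif`. The ordering is total and deterministic for any set of
#' names (ties broken by plain lexicographic order).
#'
#' @param x character vector.
#' @return integer permutation such that `x[natural_order(x)]` is sorted.
#' @export
#' @examples
#' natural_order(c("t10.tif", "t1.tif", "t2.tif"))
natural_order <- function(x) {
  keys <- vapply(x, function(s) {
    toks <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    num <- grepl("^[0-9]+$", toks)
    toks[num] <- sprintf("%030d", as.numeric(toks[num]))
    paste(toks, collapse = "")
  }, character(1))
  order(keys, x, method = "radix")
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# Population moment skewness / excess kurtosis with the zero-variance
# convention: constant data scores 0 for both.
moment_skewness <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  n <- length(x)
  if (n == 0) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

# Deterministic substream seed derived from a master seed and one or more
# integer keys; stays below 2^31 - 1 so it is a valid R seed everywhere.
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.numeric(k) * 65537 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Shoelace area of a polygon given x/y vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((x[i2] - x)^2 + (y[i2] - y)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
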