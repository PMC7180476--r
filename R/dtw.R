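#' z-normalise a series
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor `N`), so the output has mean 0 and population variance 1.  This
#' is the renormalisation built into the pointwise distance used by
#' [dtw_align()]: comparisons become invariant to affine amplitude changes
#' `a * x + b` with `a > 0`.
#'
#' @param series Numeric vector, length >= 2, all values finite.
#'
#' @return Numeric vector of the same length with mean 0 and population
#'   variance 1.
#'
#' @examples
#' znorm(c(1, 3))           # -1, 1
#' mean(znorm(0:3))         # 0
#' @export
znorm <- function(series) {
  check_series(series, min_len = 2L)
  mu <- mean(series)
  s <- sqrt(mean((series - mu)^2))
  if (s == 0) {
    abort(
      "Cannot z-normalise a constant series (standard deviation is zero).",
      class = "gaitwarp_error_degenerate"
    )
  }
  (series - mu) / s
}

#' Banded dynamic time warping between two series
#'
#' Aligns two univariate series with classic symmetric-step dynamic time
#' warping under a Sakoe-Chiba-style band `|i - j| <= maxsamp`.  Both series
#' are first z-normalised over their whole length ([znorm()]), and the
#' pointwise cost of matching `u[i]` with `v[j]` is the squared difference of
#' the z-scores.  The DTW distance is the cumulative (not length-normalised)
#' cost along the optimal path.
#'
#' The warping path starts at `(1, 1)`, ends at `(length(u), length(v))`,
#' moves by `(1,1)`, `(1,0)` or `(0,1)`, and stays inside the band.  When
#' several predecessors tie, the diagonal is preferred, then the vertical
#' move (advance in `u`), then the horizontal one, so the returned path is
#' deterministic.
#'
#' @param u,v Numeric vectors, length >= 2, non-constant.
#' @param maxsamp Band half-width in samples (positive integer or `Inf` for
#'   unconstrained alignment).  The alignment is infeasible when
#'   `abs(length(u) - length(v)) > maxsamp`; this raises an error of class
#'   `"gaitwarp_error_band_infeasible"`.
#'
#' @return An object of class `"dtw_alignment"`: a list with elements
#'   `distance` (non-negative scalar), `path` (tibble with columns `i`, `j`),
#'   `n_u`, `n_v` and `maxsamp`.  `tidy()` returns the path tibble.
#'
#' @examples
#' a <- sin(seq(0, 2 * pi, length.out = 40))
#' dtw_align(a, a)$distance                 # 0
#' dtw_align(2 * a + 5, a)$distance         # 0: z-normalisation invariance
#' @export
dtw_align <- function(u, v, maxsamp = 20) {
  band <- prepare_band(u, v, maxsamp)
  uz <- znorm(u)
  vz <- znorm(v)
  res <- dtw_band_cpp(uz, vz, band, TRUE)
  structure(
    list(
      distance = res$distance,
      path = tibble(i = res$path[, 1], j = res$path[, 2]),
      n_u = length(u),
      n_v = length(v),
      maxsamp = maxsamp
    ),
    class = "dtw_alignment"
  )
}

#' DTW distance only
#'
#' Same computation as [dtw_align()] without materialising the path.
#'
#' @inheritParams dtw_align
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(u, v, maxsamp = 20) {
  band <- prepare_band(u, v, maxsamp)
  dtw_band_cpp(znorm(u), znorm(v), band, FALSE)$distance
}

# distance for series that are already z-normalised (refinement inner loop)
dtw_distance_znormed <- function(uz, vz, band) {
  dtw_band_cpp(uz, vz, band, FALSE)$distance
}

#' Brute-force DTW by path enumeration
#'
#' Testing oracle: computes the minimum cumulative cost over *all* warping
#' paths satisfying the boundary, monotonicity and band constraints by plain
#' recursive enumeration, with no dynamic-programming table.  Exponential in
#' the series lengths, hence restricted to very short series; it exists so
#' the production DP in [dtw_align()] can be checked against an independent
#' computation.
#'
#' @inheritParams dtw_align
#' @return Scalar distance, identical in definition to
#'   `dtw_align(u, v, maxsamp)$distance`.
#' @export
dtw_bruteforce <- function(u, v, maxsamp = 20) {
  if (length(u) > 10 || length(v) > 10) {
    abort("dtw_bruteforce() enumerates all paths; series must have length <= 10.")
  }
  band <- prepare_band(u, v, maxsamp)
  uz <- znorm(u)
  vz <- znorm(v)
  n <- length(uz)
  m <- length(vz)
  dmat <- outer(uz, vz, function(a, b) (a - b)^2)
  rec <- function(i, j) {
    if (i == n && j == m) {
      return(0)
    }
    best <- Inf
    for (mv in list(c(1L, 1L), c(1L, 0L), c(0L, 1L))) {
      i2 <- i + mv[[1]]
      j2 <- j + mv[[2]]
      if (i2 <= n && j2 <= m && abs(i2 - j2) <= band) {
        cand <- dmat[i2, j2] + rec(i2, j2)
        if (cand < best) best <- cand
      }
    }
    best
  }
  if (n == 1 && m == 1) {
    return(dmat[1, 1])
  }
  dmat[1, 1] + rec(1L, 1L)
}

#' @export
tidy.dtw_alignment <- function(x, ...) {
  x$path
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(
    sprintf(
      "<dtw_alignment> %d x %d series, band %s\n  distance: %.6g, path length: %d\n",
      x$n_u, x$n_v, format(x$maxsamp), x$distance, nrow(x$path)
    )
  )
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

check_series <- function(x, min_len = 2L, arg = deparse(substitute(x))) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", arg))
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have length >= %d.", arg, min_len))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(x)
}

# validate inputs + band, return the integer band used by the C++ kernel
prepare_band <- function(u, v, maxsamp) {
  check_series(u, arg = "u")
  check_series(v, arg = "v")
  if (length(maxsamp) != 1 || is.na(maxsamp) || maxsamp < 0) {
    abort("`maxsamp` must be a single non-negative number (or Inf).")
  }
  if (abs(length(u) - length(v)) > maxsamp) {
    abort(
      sprintf(
        "No warping path exists: length difference %d exceeds band maxsamp = %s.",
        abs(length(u) - length(v)), format(maxsamp)
      ),
      class = "gaitwarp_error_band_infeasible"
    )
  }
  if (is.infinite(maxsamp)) {
    return(max(length(u), length(v)))
  }
  as.integer(maxsamp)
}
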