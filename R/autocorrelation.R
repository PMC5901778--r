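#' Radially averaged spatial autocorrelation of a two-colour pattern
#'
#' Computes the two-point autocorrelation of the lineage-colour field
#' \deqn{C(r) = \frac{\langle c(R)\,c(R+r)\rangle - \langle c(R)\rangle
#'   \langle c(R+r)\rangle}{\langle c^2(R)\rangle - \langle c(R)\rangle^2}}
#' where the colour variable c is 1 (blue) or 2 (red) on occupied sites and
#' empty sites are excluded from every average. Pairs are radially averaged
#' into unit-width annular bins `[k - 0.5, k + 0.5)` of Euclidean pair
#' distance; the r = 0 bin contains only self pairs, so C(0) = 1 by the
#' normalisation. In `"periodic"` boundary mode pair distances use the
#' minimal-image convention; in `"bounded"` mode (the default for finite
#' fields of view) pairs are taken within the frame as-is.
#'
#' @param pattern A `color_pattern` containing both colours.
#' @param r_max Largest bin centre to report, in grid units; defaults to
#'   half the smaller lattice dimension (longer bins are dominated by few
#'   pairs).
#' @return A `correlation_profile`: a data frame with columns `r` (bin
#'   centre, grid units), `C`, and `n_pairs` (ordered pair count), keeping
#'   only bins with at least one pair; attributes `unit` and `r_max`.
#' @examples
#' p <- generate_reference_pattern("checkerboard", L = 20,
#'                                 boundary = "periodic")
#' autocorrelation(p, r_max = 5)
#' @seealso [correlation_length()], [autocorrelation_reference()]
#' @export
autocorrelation <- function(pattern, r_max = NULL) {
  grid <- as_pattern_matrix(pattern)
  check_two_colors(grid)
  r_max <- default_r_max(grid, r_max)
  periodic <- identical(attr(pattern, "boundary"), "periodic")
  res <- autocorr_bins_cpp(grid, as.integer(r_max), periodic)
  profile_from_bins(res$r, res$C, res$n, r_max,
                    unit = attr(pattern, "unit") %||% 1)
}

#' Brute-force reference autocorrelation
#'
#' Same contract as [autocorrelation()], computed by direct enumeration of
#' all ordered pairs of occupied sites in plain R. Quadratic in the number
#' of occupied sites; intended as the independent oracle for small patterns
#' (up to roughly 40 x 40).
#'
#' @inheritParams autocorrelation
#' @return A `correlation_profile` (see [autocorrelation()]).
#' @export
autocorrelation_reference <- function(pattern, r_max = NULL) {
  grid <- as_pattern_matrix(pattern)
  check_two_colors(grid)
  r_max <- default_r_max(grid, r_max)
  periodic <- identical(attr(pattern, "boundary"), "periodic")
  occ <- which(grid != 0, arr.ind = TRUE)
  cc <- as.numeric(grid[grid != 0])
  denom <- mean(cc^2) - mean(cc)^2
  nb <- r_max + 1L
  n_pairs <- numeric(nb); s_xy <- numeric(nb); s_x <- numeric(nb)
  n <- nrow(occ)
  # all ordered pairs (self pairs included: they fall in bin 0)
  for (i in seq_len(n)) {
    dr <- abs(occ[, 1] - occ[i, 1])
    dc <- abs(occ[, 2] - occ[i, 2])
    if (periodic) {
      dr <- pmin(dr, nrow(grid) - dr)
      dc <- pmin(dc, ncol(grid) - dc)
    }
    k <- floor(sqrt(dr^2 + dc^2) + 0.5)
    keep <- k <= r_max
    kk <- k[keep] + 1L
    counts <- tabulate(kk, nb)
    n_pairs <- n_pairs + counts
    sums <- rowsum(cc[i] * cc[keep], kk)
    idx <- as.integer(rownames(sums))
    s_xy[idx] <- s_xy[idx] + sums[, 1]
    s_x <- s_x + cc[i] * counts
  }
  C <- (s_xy / n_pairs - (s_x / n_pairs)^2) / denom
  profile_from_bins(0:r_max, C, n_pairs, r_max,
                    unit = attr(pattern, "unit") %||% 1)
}

check_two_colors <- function(grid) {
  stop_unless(any(grid == 1L) && any(grid == 2L),
              "zero variance: pattern must contain both colours")
}

default_r_max <- function(grid, r_max) {
  if (is.null(r_max)) r_max <- floor(min(dim(grid)) / 2)
  stop_unless(length(r_max) == 1 && r_max >= 1, "r_max must be >= 1")
  as.integer(r_max)
}

profile_from_bins <- function(r, C, n_pairs, r_max, unit) {
  keep <- n_pairs > 0
  out <- data.frame(r = as.numeric(r[keep]), C = as.numeric(C[keep]),
                    n_pairs = as.numeric(n_pairs[keep]))
  structure(out, unit = unit, r_max = as.numeric(r_max),
            class = c("correlation_profile", "data.frame"))
}

#' Clonal correlation length: first zero of C(r)
#'
#' The correlation length xi is the first zero of the radially averaged
#' autocorrelation function, located by linear interpolation between the
#' last positive bin and the first bin with C <= 0. Profiles that never
#' cross zero within `r_max` are censored at `xi = r_max`.
#'
#' @param profile A `correlation_profile` from [autocorrelation()] (at
#'   least two bins).
#' @return A list of class `correlation_length` with `xi` (grid units) and
#'   `censored`.
#' @examples
#' p <- generate_reference_pattern("stripes", L = 60, w = 5)
#' correlation_length(autocorrelation(p))
#' @export
correlation_length <- function(profile) {
  stop_unless(inherits(profile, "correlation_profile") || is.data.frame(profile),
              "profile must be a correlation_profile")
  stop_unless(nrow(profile) >= 2, "profile needs at least two bins")
  r <- profile$r
  C <- profile$C
  r_max <- attr(profile, "r_max") %||% max(r)
  for (k in 2:length(C)) {
    if (C[k] <= 0 && C[k - 1] > 0) {
      xi <- r[k - 1] + C[k - 1] * (r[k] - r[k - 1]) / (C[k - 1] - C[k])
      return(structure(list(xi = xi, censored = FALSE),
                       class = "correlation_length"))
    }
  }
  structure(list(xi = as.numeric(r_max), censored = TRUE),
            class = "correlation_length")
}

#' @export
print.correlation_length <- function(x, ...) {
  cat(sprintf("correlation length xi = %.3f%s\n", x$xi,
              if (x$censored) " (censored at r_max)" else ""))
  invisible(x)
}
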