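#' Two-colour occupation pattern
#'
#' A `color_pattern` is an integer matrix with values 0 (empty), 1 (blue)
#' and 2 (red), carrying the physical size of one grid cell (`unit`, in
#' microns: 1 for simulation lattices, 0.065 for microscopy pixels) and the
#' boundary convention used when measuring pair distances (`"bounded"` or
#' `"periodic"`). Rows are the transverse coordinate; columns follow the
#' flow axis (left to right).
#'
#' @param grid Integer matrix with values in \{0, 1, 2\}.
#' @param unit Physical length of one grid cell in microns (> 0).
#' @param boundary `"bounded"` or `"periodic"`.
#' @return The classed matrix.
#' @export
color_pattern <- function(grid, unit = 1, boundary = c("bounded", "periodic")) {
  boundary <- match.arg(boundary)
  stop_unless(is.matrix(grid), "grid must be a matrix")
  stop_unless(all(grid %in% c(0L, 1L, 2L)),
              "grid values must be 0 (empty), 1 (blue) or 2 (red)")
  stop_unless(length(unit) == 1 && is.finite(unit) && unit > 0,
              "unit must be a positive length")
  storage.mode(grid) <- "integer"
  structure(grid, unit = as.numeric(unit), boundary = boundary,
            class = c("color_pattern", "matrix", "array"))
}

as_pattern_matrix <- function(x) {
  stop_unless(is.matrix(x), "expected a matrix pattern")
  m <- unclass(x)
  attributes(m) <- list(dim = dim(x))
  storage.mode(m) <- "integer"
  m
}

# carry unit/boundary metadata from a template pattern onto a raw grid
rewrap_pattern <- function(grid, template) {
  color_pattern(grid,
                unit = attr(template, "unit") %||% 1,
                boundary = attr(template, "boundary") %||% "bounded")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.color_pattern <- function(x, ...) {
  n_occ <- sum(x != 0)
  cat(sprintf(
    "color_pattern %dx%d | %d occupied (%.1f%%) | blue %d, red %d | unit %g um, %s\n",
    nrow(x), ncol(x), n_occ, 100 * n_occ / length(x), sum(x == 1),
    sum(x == 2), attr(x, "unit"), attr(x, "boundary")))
  invisible(x)
}

#' Generate a reference pattern with known correlation structure
#'
#' Deterministic (given `seed`) fixtures used to calibrate the correlation
#' analysis: fully mixed random fields, single-site checkerboards,
#' alternating stripes and blocks with a prescribed length scale `w`, and
#' Voronoi tessellations of random founders that emulate the ideal limit in
#' which each founder claims the territory around it.
#'
#' @param kind One of `"random"`, `"checkerboard"`, `"stripes"`, `"blocks"`,
#'   `"voronoi"`.
#' @param L Lattice lateral length.
#' @param w Stripe/block width in sites (`"stripes"`, `"blocks"` only).
#' @param n_seeds Number of founders (`"voronoi"` only).
#' @param ratio Probability that a site is blue (`"random"` only).
#' @param seed Optional RNG seed for the stochastic kinds.
#' @param boundary Boundary mode recorded on the pattern.
#' @return A fully occupied `color_pattern`.
#' @examples
#' generate_reference_pattern("stripes", L = 60, w = 5)
#' @export
generate_reference_pattern <- function(kind = c("random", "checkerboard",
                                                "stripes", "blocks",
                                                "voronoi"),
                                       L = 60, w = 5, n_seeds = 36,
                                       ratio = 0.5, seed = NULL,
                                       boundary = "bounded") {
  kind <- match.arg(kind)
  stop_unless(L >= 2 && L == as.integer(L), "L must be an integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  grid <- switch(kind,
    random = {
      stop_unless(ratio > 0 && ratio < 1, "ratio must be in (0, 1)")
      matrix(sample(c(1L, 2L), L * L, replace = TRUE,
                    prob = c(ratio, 1 - ratio)), L, L)
    },
    checkerboard = outer(seq_len(L), seq_len(L),
                         function(i, j) 1L + (i + j) %% 2L),
    stripes = {
      stop_unless(w >= 1 && w == as.integer(w), "w must be a positive integer")
      matrix(rep(1L + (floor((seq_len(L) - 1) / w) %% 2L), each = L), L, L)
    },
    blocks = {
      stop_unless(w >= 1 && w == as.integer(w), "w must be a positive integer")
      bi <- floor((seq_len(L) - 1) / w)
      outer(bi, bi, function(a, b) 1L + (a + b) %% 2L)
    },
    voronoi = {
      stop_unless(n_seeds >= 1 && n_seeds <= L * L,
                  "n_seeds must be in [1, L^2]")
      sites <- sample.int(L * L, n_seeds)
      sr <- (sites - 1) %% L + 1
      sc <- (sites - 1) %/% L + 1
      cols <- sample(c(1L, 2L), n_seeds, replace = TRUE)
      g <- matrix(0L, L, L)
      for (i in seq_len(L)) {
        for (j in seq_len(L)) {
          d2 <- (sr - i)^2 + (sc - j)^2
          g[i, j] <- cols[which.min(d2)]  # which.min: lowest index on ties
        }
      }
      g
    })
  storage.mode(grid) <- "integer"
  color_pattern(grid, unit = 1, boundary = boundary)
}

#' Save / load a pattern as a plain-text grid
#'
#' Grids are written as comma-separated integers (0/1/2), no header, one
#' line per lattice row (row index = transverse coordinate, column = flow
#' axis). A JSON sidecar `<path>.json` stores the physical unit and
#' boundary mode so `load_pattern(save_pattern(x))` is the identity.
#'
#' @param pattern A `color_pattern`.
#' @param path File path for the CSV grid.
#' @return `save_pattern` returns `path` invisibly; `load_pattern` returns
#'   the `color_pattern`.
#' @export
save_pattern <- function(pattern, path) {
  grid <- as_pattern_matrix(pattern)
  write.table(grid, path, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(unit = attr(pattern, "unit") %||% 1,
               boundary = attr(pattern, "boundary") %||% "bounded")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pattern
#' @export
load_pattern <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1)
    stop(sprintf("format error: ragged rows (row %d has %d columns, expected %d)",
                 which(lengths(rows) != ncols[1])[1],
                 lengths(rows)[lengths(rows) != ncols[1]][1], ncols[1]),
         call. = FALSE)
  vals <- suppressWarnings(as.integer(unlist(rows)))
  grid <- matrix(vals, nrow = length(rows), ncol = ncols, byrow = TRUE)
  bad <- which(is.na(grid) | !(grid %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("format error: invalid value at row %d, column %d (must be 0, 1 or 2)",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(unit = 1, boundary = "bounded")
  color_pattern(grid, unit = meta$unit, boundary = meta$boundary)
}

#' Build a pattern from a two-channel fluorescence image
#'
#' Minimal segmentation for co-registered red/blue channel images: each
#' pixel is assigned the colour of the channel with the larger
#' above-threshold intensity, and left empty when both channels are below
#' threshold.
#'
#' @param blue,red Numeric intensity matrices of identical shape, or paths
#'   to single-channel TIFF files (read with the `tiff` package).
#' @param threshold_blue,threshold_red Per-channel intensity thresholds.
#' @param unit Pixel size in microns (default 0.065, the microscopy pixel).
#' @return A `color_pattern` in bounded mode.
#' @export
pattern_from_image <- function(blue, red, threshold_blue = 0.5,
                               threshold_red = 0.5, unit = 0.065) {
  read_channel <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF files requires the 'tiff' package", call. = FALSE)
      x <- tiff::readTIFF(x)
      if (length(dim(x)) == 3) x <- x[, , 1]
    }
    stop_unless(is.matrix(x) && is.numeric(x),
                "channels must be numeric matrices or TIFF paths")
    x
  }
  blue <- read_channel(blue)
  red <- read_channel(red)
  stop_unless(all(dim(blue) == dim(red)),
              "channel shape mismatch: blue and red must be co-registered")
  b_on <- blue >= threshold_blue
  r_on <- red >= threshold_red
  grid <- matrix(0L, nrow(blue), ncol(blue))
  grid[b_on & (!r_on | blue >= red)] <- 1L
  grid[r_on & (!b_on | red > blue)] <- 2L
  if (all(grid == 0L))
    stop("all pixels below threshold: empty pattern", call. = FALSE)
  color_pattern(grid, unit = unit, boundary = "bounded")
}
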