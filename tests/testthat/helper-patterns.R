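# Shared fixture builders for the analysis tests.

# random two-colour pattern with controllable occupancy and colour balance
random_pattern <- function(L, density = 1, ratio = 0.5, seed = NULL,
                           boundary = "bounded") {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(0L, L, L)
  n_occ <- max(2L, round(density * L * L))
  sites <- sample.int(L * L, n_occ)
  g[sites] <- sample(c(1L, 2L), n_occ, replace = TRUE,
                     prob = c(ratio, 1 - ratio))
  # guarantee both colours for correlation analysis
  g[sites[1]] <- 1L
  g[sites[2]] <- 2L
  color_pattern(g, boundary = boundary)
}

swap_colors <- function(pattern) {
  g <- unclass(pattern)
  g2 <- g
  g2[g == 1L] <- 2L
  g2[g == 2L] <- 1L
  color_pattern(matrix(g2, nrow(pattern)), unit = attr(pattern, "unit"),
                boundary = attr(pattern, "boundary"))
}

fully_occupied <- function(L, seed = 1) {
  set.seed(seed)
  color_pattern(matrix(sample(c(1L, 2L), L * L, TRUE), L, L),
                boundary = "periodic")
}
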