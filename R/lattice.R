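#' Shove-displacement probability
#'
#' Probability that a resident cell loses a shoving contest against a
#' newborn, \eqn{p_s = (1 - \sigma)/2}. Weakly adhesive residents
#' (`sigma = 0`) are displaced half the time; fully adhesive residents
#' (`sigma = 1`) never.
#'
#' @param sigma Adhesiveness in \[0, 1\].
#' @return The displacement probability, in \[0, 0.5\].
#' @examples
#' shove_probability(0)    # 0.5
#' shove_probability(1)    # 0
#' @export
shove_probability <- function(sigma) {
  stop_unless(all(is.finite(sigma)) && all(sigma >= 0) && all(sigma <= 1),
              "sigma must be in [0, 1]")
  (1 - sigma) / 2
}

#' Flow-detachment probability
#'
#' Probability that a surface cell is detached by flow,
#' \eqn{p_d = f (1 - \sigma)}, with drafting protection: the probability is
#' zero whenever the directly adjacent upstream site is occupied.
#'
#' @param sigma Adhesiveness in \[0, 1\].
#' @param f Flow intensity in \[0, 1\].
#' @param upstream_empty Is the directly upstream neighbour site empty?
#' @return The detachment probability in \[0, 1\].
#' @examples
#' detachment_probability(0, 0.5, TRUE)   # 0.5
#' detachment_probability(0, 1, FALSE)    # 0: drafting protection
#' @export
detachment_probability <- function(sigma, f, upstream_empty = TRUE) {
  stop_unless(all(is.finite(sigma)) && all(sigma >= 0) && all(sigma <= 1),
              "sigma must be in [0, 1]")
  stop_unless(all(is.finite(f)) && all(f >= 0) && all(f <= 1),
              "f must be in [0, 1]")
  ifelse(upstream_empty, f * (1 - sigma), 0)
}

#' Initialize a founder lattice
#'
#' Places `round(rho0 * L^2)` founder cells (half-up rounding) on distinct
#' uniformly chosen sites of an empty L x L lattice; each founder is
#' independently blue (1) or red (2) with probability 1/2, giving a 1:1
#' mixture on average.
#'
#' @param config A [simulation_config()]. Its `seed` is NOT applied here;
#'   seed the RNG with `set.seed()` or use [run_to_confluence()].
#' @return An integer matrix of class `color_pattern` (0 empty, 1 blue,
#'   2 red), periodic boundary, unit 1 micron; rows are the transverse
#'   coordinate, columns the flow axis.
#' @examples
#' set.seed(1)
#' lat <- initialize_lattice(simulation_config(rho0 = 0.01))
#' sum(lat != 0)  # 36 founders
#' @export
initialize_lattice <- function(config) {
  config <- as_config(config)
  L <- config$L
  n_founders <- floor(config$rho0 * L * L + 0.5)
  grid <- matrix(0L, L, L)
  if (n_founders > 0) {
    sites <- sample.int(L * L, n_founders)
    grid[sites] <- sample(c(1L, 2L), n_founders, replace = TRUE)
  }
  color_pattern(grid, unit = 1, boundary = "periodic")
}

birth_events <- c("none", "birth", "shove_resident_displaced",
                  "shove_resident_removed", "shove_newborn_displaced",
                  "shove_newborn_removed")
detach_events <- c("none", "eligible_no_detach", "relocated", "removed")

#' Single birth attempt
#'
#' With probability `p_b`, a uniformly chosen occupied cell divides. The
#' newborn (same colour as the parent) lands on a random empty Moore
#' neighbour; if the neighbourhood is full, a single shove against a random
#' resident neighbour is resolved with displacement probability
#' [shove_probability()] and the losing cell moves into the resident's
#' neighbourhood or is removed with the outflow. Shoves never cascade.
#'
#' @param lattice A `color_pattern` lattice with at least one occupied site.
#' @param config A [simulation_config()] (only `sigma` and `p_b` are used).
#' @return A list with the updated `lattice` and the `event` string, one of
#'   `"none"`, `"birth"`, `"shove_resident_displaced"`,
#'   `"shove_resident_removed"`, `"shove_newborn_displaced"`,
#'   `"shove_newborn_removed"`.
#' @export
attempt_birth <- function(lattice, config) {
  config <- as_config(config)
  grid <- as_pattern_matrix(lattice)
  stop_unless(sum(grid != 0) > 0, "no population: lattice is empty")
  res <- ca_birth_cpp(grid, config$sigma, config$p_b)
  list(lattice = rewrap_pattern(res$grid, lattice),
       event = birth_events[res$event + 1L])
}

#' Single flow-detachment attempt
#'
#' A uniformly chosen occupied cell is tested: if its directly upstream
#' neighbour (periodic wrap) is empty it detaches with probability
#' [detachment_probability()] and a relocation draw (see
#' [sample_relocation()]) decides where it lands, or whether it is lost
#' with the outflow.
#'
#' @inheritParams attempt_birth
#' @return A list with the updated `lattice` and the `event` string, one of
#'   `"none"`, `"eligible_no_detach"`, `"relocated"`, `"removed"`
#'   (`"none"` covers drafting-protected picks).
#' @export
attempt_detachment <- function(lattice, config) {
  config <- as_config(config)
  grid <- as_pattern_matrix(lattice)
  stop_unless(sum(grid != 0) > 0, "no population: lattice is empty")
  res <- ca_detach_cpp(grid, config$sigma, config$f)
  list(lattice = rewrap_pattern(res$grid, lattice),
       event = detach_events[res$event + 1L])
}

#' Draw a flow relocation for a detached cell
#'
#' The downstream displacement `dx` is a uniform integer on
#' `{0, ..., floor(f * L)}` and the transverse displacement `dy` a uniform
#' integer on `{-dx, ..., dx}`; the landing site is evaluated with periodic
#' wrap after the origin has been vacated, so a `dx = dy = 0` draw lands the
#' cell back on its own site. An occupied landing site means the cell is
#' removed with the outflow.
#'
#' @param origin Occupied site as `c(row, col)` (1-based; col = flow axis).
#' @param f Flow intensity in \[0, 1\].
#' @param lattice A `color_pattern` lattice.
#' @return A list with `dx`, `dy`, `landing` (`c(row, col)`), and `outcome`
#'   (`"LANDED"` or `"REMOVED"`).
#' @export
sample_relocation <- function(origin, f, lattice) {
  grid <- as_pattern_matrix(lattice)
  stop_unless(length(origin) == 2 && all(origin >= 1) &&
                origin[1] <= nrow(grid) && origin[2] <= ncol(grid),
              "origin out of bounds")
  stop_unless(grid[origin[1], origin[2]] != 0,
              "invalid state: origin site is empty")
  stop_unless(f >= 0 && f <= 1, "f must be in [0, 1]")
  L <- ncol(grid)
  dx <- sample.int(floor(f * L) + 1L, 1L) - 1L
  dy <- sample.int(2L * dx + 1L, 1L) - dx - 1L
  land_row <- ((origin[1] - 1 + dy) %% nrow(grid)) + 1
  land_col <- ((origin[2] - 1 + dx) %% L) + 1
  occupied_after_vacating <-
    grid[land_row, land_col] != 0 &&
    !(land_row == origin[1] && land_col == origin[2])
  list(dx = dx, dy = dy, landing = c(land_row, land_col),
       outcome = if (occupied_after_vacating) "REMOVED" else "LANDED")
}

#' Advance the automaton by one step
#'
#' One birth attempt followed by one detachment attempt, each on an
#' independently chosen occupied cell. The net occupancy change of a step
#' is in \{-1, 0, +1\}.
#'
#' @inheritParams attempt_birth
#' @return A list with the updated `lattice`, `birth_event` and
#'   `detach_event` strings.
#' @export
step_lattice <- function(lattice, config) {
  config <- as_config(config)
  grid <- as_pattern_matrix(lattice)
  stop_unless(sum(grid != 0) > 0, "no population: lattice is empty")
  res <- ca_step_cpp(grid, config$sigma, config$f, config$p_b)
  list(lattice = rewrap_pattern(res$grid, lattice),
       birth_event = birth_events[res$birth_event + 1L],
       detach_event = detach_events[res$detach_event + 1L])
}

#' Run a colonization to confluence
#'
#' Initializes a founder lattice (unless one is supplied) and iterates
#' [step_lattice()] dynamics until the occupied fraction reaches
#' `occupancy_threshold` (default 95%), the step budget is exhausted, or
#' the population goes extinct.
#'
#' @param config A [simulation_config()]; `config$seed`, when set, seeds the
#'   RNG so the run is exactly reproducible.
#' @param lattice Optional initial `color_pattern`; by default one is drawn
#'   with [initialize_lattice()].
#' @return A list of class `colonization_run` with elements `lattice` (the
#'   final `color_pattern`) and `record`, a list holding `steps`, `births`,
#'   `shove_removals`, `detachments`, `relocation_removals`,
#'   `final_fraction`, and `terminated` (`"THRESHOLD"`, `"MAX_STEPS"` or
#'   `"EXTINCT"`).
#' @examples
#' run <- run_to_confluence(simulation_config(sigma = 1, rho0 = 0.01,
#'                                            f = 1, seed = 7))
#' run$record$final_fraction >= 0.95
#' @export
run_to_confluence <- function(config, lattice = NULL) {
  config <- as_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(lattice)) {
    stop_unless(config$rho0 > 0, "rho0 must be > 0 to seed a run")
    lattice <- initialize_lattice(config)
  }
  grid <- as_pattern_matrix(lattice)
  res <- ca_run_cpp(grid, config$sigma, config$f, config$p_b,
                    config$occupancy_threshold, config$max_steps)
  record <- list(steps = res$steps, births = res$births,
                 shove_removals = res$shove_removals,
                 detachments = res$detachments,
                 relocation_removals = res$relocation_removals,
                 final_fraction = res$final_fraction,
                 terminated = res$terminated)
  if (res$terminated == "EXTINCT")
    warning("population went extinct before confluence", call. = FALSE)
  structure(list(lattice = rewrap_pattern(res$grid, lattice),
                 record = record, config = config),
            class = "colonization_run")
}

#' @export
print.colonization_run <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "colonization_run: %s after %g steps | occupancy %.3f | births %g, shove removals %g, detachments %g, relocation removals %g\n",
    r$terminated, r$steps, r$final_fraction, r$births, r$shove_removals,
    r$detachments, r$relocation_removals))
  invisible(x)
}
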