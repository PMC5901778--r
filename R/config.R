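#' Simulation configuration
#'
#' Bundles and validates all parameters of the colonization automaton.
#'
#' @param L Lateral lattice length in sites (one site is 1 micron across,
#'   matching a single-cell footprint); default 60, the size of one
#'   microscope field of view.
#' @param sigma Cell adhesiveness, dimensionless in \[0, 1\]. `sigma = 1`
#'   mimics a constitutive matrix (EPS) producer that can be neither shoved
#'   nor detached; `sigma = 0` a non-producer.
#' @param rho0 Founder density: fraction of lattice sites occupied at t = 0.
#' @param f Flow intensity, dimensionless in \[0, 1\]. Sets both the
#'   detachment pressure and the maximum downstream relocation distance
#'   `f * L`.
#' @param p_b Per-step birth-attempt probability in (0, 1\]. One detachment
#'   test accompanies every step regardless, so `p_b` sets the ratio of
#'   detachment tests to birth attempts: lowering it strengthens
#'   flow-driven effects on the final pattern. The default of one
#'   guaranteed birth attempt per step is the fastest choice.
#' @param occupancy_threshold Stopping fraction of occupied sites; default
#'   0.95, which avoids the flood of late inconsequential shoves near full
#'   coverage.
#' @param seed RNG seed for the run (integer), or `NULL` to use the current
#'   RNG state.
#' @param max_steps Safety bound on the number of steps; default 1e7.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' simulation_config(sigma = 1, rho0 = 0.01, f = 1, seed = 1)
#' @export
simulation_config <- function(L = 60, sigma = 1, rho0 = 0.01, f = 1,
                              p_b = 1, occupancy_threshold = 0.95,
                              seed = NULL, max_steps = 1e7) {
  stop_unless(length(L) == 1 && L >= 2 && L == as.integer(L),
              "L must be a single integer >= 2")
  for (nm in c("sigma", "rho0", "f")) {
    v <- get(nm)
    stop_unless(length(v) == 1 && is.finite(v) && v >= 0 && v <= 1,
                sprintf("%s must be a single value in [0, 1]", nm))
  }
  stop_unless(length(p_b) == 1 && p_b > 0 && p_b <= 1,
              "p_b must be in (0, 1]")
  stop_unless(length(occupancy_threshold) == 1 && occupancy_threshold > 0 &&
                occupancy_threshold <= 1,
              "occupancy_threshold must be in (0, 1]")
  stop_unless(length(max_steps) == 1 && max_steps >= 1,
              "max_steps must be a positive number")
  if (!is.null(seed))
    stop_unless(length(seed) == 1 && is.finite(seed),
                "seed must be a single number or NULL")
  structure(list(L = as.integer(L), sigma = sigma, rho0 = rho0, f = f,
                 p_b = p_b, occupancy_threshold = occupancy_threshold,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 max_steps = max_steps),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: L=%d sigma=%g rho0=%g f=%g p_b=%g threshold=%g seed=%s\n",
    x$L, x$sigma, x$rho0, x$f, x$p_b, x$occupancy_threshold,
    if (is.null(x$seed)) "<current RNG>" else as.character(x$seed)))
  invisible(x)
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

as_config <- function(config) {
  if (inherits(config, "simulation_config")) return(config)
  stop_unless(is.list(config), "config must be a simulation_config")
  do.call(simulation_config, config)
}
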