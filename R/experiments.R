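# Ensemble runner and parameter sweeps over (sigma, rho0, f).

# Deterministic per-replicate seed below 2^31, decorrelated across grid
# points via a Weyl-style integer mix of the base seed and a point index.
derive_seed <- function(base_seed, index) {
  s <- (as.numeric(base_seed) %% 2147483647) * 2654435761 +
    as.numeric(index) * 40503 + 12345
  as.integer(s %% 2147483629 + 1)
}

#' Run an ensemble of colonizations and measure correlation lengths
#'
#' Executes `n_reps` independent [run_to_confluence()] realizations with
#' per-replicate seeds derived from `base_seed`, computes the clonal
#' correlation length of each final pattern, and flags extinct runs and
#' censored measurements (profiles with no zero crossing within `r_max`,
#' including monoclonal patterns, which are perfectly correlated at all
#' distances).
#'
#' @param config A [simulation_config()]; its own `seed` entry is ignored
#'   in favour of the derived per-replicate seeds.
#' @param n_reps Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param r_max Profile range for the xi measurement; default `L / 2`.
#' @param boundary Boundary mode used for the pair distances of the
#'   analysis (the final field of view is treated as a bounded frame by
#'   default).
#' @return A data frame with one row per replicate: `rep`, `seed`, `xi`,
#'   `censored`, `extinct`, `steps`, `final_fraction`.
#' @examples
#' cfg <- simulation_config(sigma = 1, rho0 = 0.03, f = 1, L = 30)
#' xi <- run_ensemble(cfg, n_reps = 5, base_seed = 1)
#' ensemble_summary(xi)
#' @export
run_ensemble <- function(config, n_reps, base_seed = 1,
                         r_max = NULL, boundary = "bounded") {
  config <- as_config(config)
  stop_unless(length(n_reps) == 1 && n_reps >= 1,
              "invalid ensemble size: n_reps must be >= 1")
  if (is.null(r_max)) r_max <- floor(config$L / 2)
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(base_seed, i)
    run <- withCallingHandlers(
      run_to_confluence(cfg_i),
      warning = function(w) invokeRestart("muffleWarning"))
    extinct <- run$record$terminated == "EXTINCT"
    final <- run$lattice
    attr(final, "boundary") <- boundary
    if (extinct) {
      xi <- NA_real_; censored <- NA
    } else if (!any(final == 1L) || !any(final == 2L)) {
      # monoclonal confluence: C(r) = 1 everywhere, never crosses zero
      xi <- r_max; censored <- TRUE
    } else {
      cl <- correlation_length(autocorrelation(final, r_max = r_max))
      xi <- cl$xi; censored <- cl$censored
    }
    out[[i]] <- data.frame(rep = i, seed = cfg_i$seed, xi = xi,
                           censored = censored, extinct = extinct,
                           steps = run$record$steps,
                           final_fraction = run$record$final_fraction)
  }
  do.call(rbind, out)
}

#' Sweep colonization strategies across flow and density conditions
#'
#' Fills a full (f, rho0, sigma) grid with xi ensembles and, wherever both
#' sigma endpoints 0 and 1 were run, reports the adhesion payoff
#' `delta_xi = mean xi(sigma = 1) - mean xi(sigma = 0)` per (f, rho0).
#' Deterministic given `base_seed`.
#'
#' @param f_values,rho0_values,sigma_values Grids of parameter values.
#' @param n_reps Replicates per grid point.
#' @param L Lattice lateral length.
#' @param base_seed Integer base seed.
#' @param ... Passed to [run_ensemble()] (e.g. `r_max`, `boundary`).
#' @return A list of class `sweep_result` with `summary` (one row per grid
#'   point: parameters, n, mean, sd, median, skewness, censored/extinct
#'   counts) and `delta_xi` (one row per (f, rho0) with both endpoints).
#' @export
run_sweep <- function(f_values, rho0_values, sigma_values = c(0, 1),
                      n_reps = 200, L = 60, base_seed = 1, ...) {
  grid <- expand.grid(f = f_values, rho0 = rho0_values,
                      sigma = sigma_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- simulation_config(L = L, sigma = grid$sigma[g],
                             rho0 = grid$rho0[g], f = grid$f[g])
    xis <- run_ensemble(cfg, n_reps = n_reps,
                        base_seed = derive_seed(base_seed, g * 1000003),
                        ...)
    s <- ensemble_summary(xis)
    rows[[g]] <- data.frame(f = grid$f[g], rho0 = grid$rho0[g],
                            sigma = grid$sigma[g], n = s$n,
                            mean_xi = s$mean, sd_xi = s$sd,
                            median_xi = s$median, skewness = s$skewness,
                            n_censored = s$n_censored,
                            n_extinct = s$n_extinct)
  }
  summary <- do.call(rbind, rows)
  delta <- NULL
  if (all(c(0, 1) %in% sigma_values)) {
    s1 <- summary[summary$sigma == 1, ]
    s0 <- summary[summary$sigma == 0, ]
    m <- merge(s1[, c("f", "rho0", "mean_xi")],
               s0[, c("f", "rho0", "mean_xi")],
               by = c("f", "rho0"), suffixes = c("_sigma1", "_sigma0"))
    m$delta_xi <- m$mean_xi_sigma1 - m$mean_xi_sigma0
    delta <- m
  }
  structure(list(summary = summary, delta_xi = delta,
                 base_seed = base_seed, n_reps = n_reps, L = L),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d grid points, n_reps=%d, L=%d\n",
              nrow(x$summary), x$n_reps, x$L))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Variability of the correlation length across conditions
#'
#' Per grid point the standard deviation of xi (a proxy for lineage
#' segregation variability) with a percentile bootstrap confidence
#' interval.
#'
#' @inheritParams run_sweep
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Confidence level.
#' @return A data frame with `f`, `rho0`, `sigma`, `n`, `sd_xi`,
#'   `sd_lo`, `sd_hi`.
#' @export
variability_surface <- function(f_values, rho0_values,
                                sigma_values = c(0, 1), n_reps = 200,
                                L = 60, base_seed = 1, n_boot = 1000,
                                conf = 0.95, ...) {
  grid <- expand.grid(f = f_values, rho0 = rho0_values,
                      sigma = sigma_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- simulation_config(L = L, sigma = grid$sigma[g],
                             rho0 = grid$rho0[g], f = grid$f[g])
    xis <- run_ensemble(cfg, n_reps = n_reps,
                        base_seed = derive_seed(base_seed, g * 1000003),
                        ...)
    x <- xis$xi[!xis$extinct & !xis$censored]
    set.seed(derive_seed(base_seed, g * 1000003 + 1))
    boots <- vapply(seq_len(n_boot),
                    function(b) sd(sample(x, replace = TRUE)),
                    numeric(1))
    ci <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE)
    rows[[g]] <- data.frame(f = grid$f[g], rho0 = grid$rho0[g],
                            sigma = grid$sigma[g], n = length(x),
                            sd_xi = sd(x), sd_lo = ci[[1]],
                            sd_hi = ci[[2]])
  }
  do.call(rbind, rows)
}

#' Compare correlation-length distributions across density groups
#'
#' Adaptive KDE per sample group plus the matrix of pairwise overlap
#' coefficients, mirroring the comparison of xi distributions across
#' founder-density anchors (1e-1, 1e-2, 2.15e-2, 1e-3, 2.15e-3 cells per
#' square micron).
#'
#' @param xi_samples_by_group Named list of positive xi sample vectors
#'   (>= 5 samples each).
#' @param grid Common KDE evaluation grid; default spans all samples.
#' @return A list of class `distribution_comparison` with `kde` (named list
#'   of `density_estimate`) and `overlap` (named matrix).
#' @export
compare_distributions <- function(xi_samples_by_group, grid = NULL) {
  stop_unless(is.list(xi_samples_by_group) &&
                length(xi_samples_by_group) >= 1 &&
                !is.null(names(xi_samples_by_group)),
              "xi_samples_by_group must be a named list")
  for (nm in names(xi_samples_by_group))
    stop_unless(length(xi_samples_by_group[[nm]]) >= 5,
                sprintf("insufficient samples in group '%s' (need >= 5)", nm))
  if (is.null(grid)) {
    top <- max(unlist(xi_samples_by_group))
    grid <- seq(0, top * 1.5, length.out = 512)
  }
  kdes <- lapply(xi_samples_by_group, adaptive_kde, grid = grid)
  k <- length(kdes)
  ov <- matrix(1, k, k, dimnames = list(names(kdes), names(kdes)))
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ov[i, j] <- ov[j, i] <- overlap_coefficient(kdes[[i]], kdes[[j]],
                                                  grid = grid)
    }
  structure(list(kde = kdes, overlap = ov),
            class = "distribution_comparison")
}
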