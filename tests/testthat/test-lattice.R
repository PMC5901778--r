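test_that("founder initialization places round(rho0 L^2) cells of two colours", {
  set.seed(1)
  empty <- initialize_lattice(simulation_config(rho0 = 0))
  expect_identical(sum(empty != 0), 0L)

  lat <- initialize_lattice(simulation_config(rho0 = 0.01))
  expect_identical(sum(lat != 0), 36L)  # round(0.01 * 3600)
  expect_true(all(lat[lat != 0] %in% c(1L, 2L)))

  full <- initialize_lattice(simulation_config(rho0 = 1))
  expect_identical(sum(full != 0), 3600L)
})

test_that("a parent with empty neighbours births a same-colour cell", {
  g <- matrix(0L, 9, 9)
  g[5, 5] <- 2L
  lat <- color_pattern(g, boundary = "periodic")
  cfg <- simulation_config(sigma = 0.5, rho0 = 0.01, p_b = 1)
  for (i in 1:20) {
    out <- attempt_birth(lat, cfg)
    expect_identical(out$event, "birth")
    expect_identical(sum(out$lattice != 0), 2L)
    expect_true(all(out$lattice[out$lattice != 0] == 2L))
  }
})

test_that("on a full lattice, sigma=1 shoves always remove the newborn", {
  lat <- fully_occupied(8)
  cfg <- simulation_config(sigma = 1, rho0 = 1)
  set.seed(3)
  for (i in 1:50) {
    out <- attempt_birth(lat, cfg)
    expect_identical(out$event, "shove_newborn_removed")
    expect_identical(unclass(out$lattice), unclass(lat))
  }
})

test_that("on a full lattice at sigma=0 the resident loses about half of shoves", {
  lat <- fully_occupied(8)
  cfg <- simulation_config(sigma = 0, rho0 = 1)
  set.seed(4)
  n <- 4000
  resident_lost <- 0
  for (i in seq_len(n)) {
    out <- attempt_birth(lat, cfg)
    expect_match(out$event, "^shove_")
    if (out$event == "shove_resident_removed") resident_lost <- resident_lost + 1
  }
  se <- sqrt(0.25 / n)
  expect_lt(abs(resident_lost / n - 0.5), 3 * se)
})

test_that("relocation draws respect the downstream cone and uniformity", {
  lat <- fully_occupied(8)
  # f = 0: degenerate draw lands the cell back on its own vacated site
  set.seed(5)
  d0 <- sample_relocation(c(3, 3), 0, lat)
  expect_identical(d0$dx, 0L)
  expect_identical(d0$dy, 0L)
  expect_identical(d0$outcome, "LANDED")
  expect_identical(d0$landing, c(3, 3))

  # landing on any occupied site means removal with the outflow; a draw
  # that wraps a full period back onto the vacated origin self-lands
  set.seed(6)
  outcomes <- replicate(200, {
    d <- sample_relocation(c(1, 1), 1, lat)
    c(d$dx, d$dy, d$landing, d$outcome == "REMOVED")
  })
  dx <- as.integer(outcomes[1, ]); dy <- as.integer(outcomes[2, ])
  at_origin <- outcomes[3, ] == 1 & outcomes[4, ] == 1
  removed <- as.logical(as.integer(outcomes[5, ]))
  expect_true(all(dx >= 0 & dx <= 8))
  expect_true(all(abs(dy) <= dx))
  expect_identical(removed, !at_origin)

  # dx ~ uniform on {0, ..., floor(f L)}
  set.seed(7)
  L <- 12
  lat2 <- fully_occupied(L)
  draws <- replicate(20000, sample_relocation(c(1, 1), 1, lat2)$dx)
  tab <- tabulate(draws + 1L, L + 1)
  gof <- chisq.test(tab, p = rep(1 / (L + 1), L + 1))
  expect_gt(gof$p.value, 0.001)

  expect_error(sample_relocation(c(1, 1),
                                 0.5, color_pattern(matrix(0L, 4, 4))),
               "empty")
})

test_that("detachment never fires at sigma=1 or f=0 and always fires for an exposed lone cell", {
  lat <- fully_occupied(10)
  set.seed(8)
  for (i in 1:30) {
    o1 <- attempt_detachment(lat, simulation_config(sigma = 1, f = 1))
    expect_identical(unclass(o1$lattice), unclass(lat))
    expect_true(o1$event %in% c("none", "eligible_no_detach"))
    o2 <- attempt_detachment(lat, simulation_config(sigma = 0.3, f = 0))
    expect_identical(unclass(o2$lattice), unclass(lat))
  }
  # isolated weakly adhesive cell under full flow: p_d = 1, always relocates
  g <- matrix(0L, 10, 10); g[4, 4] <- 1L
  lone <- color_pattern(g, boundary = "periodic")
  set.seed(9)
  for (i in 1:30) {
    out <- attempt_detachment(lone, simulation_config(sigma = 0, f = 1))
    expect_identical(out$event, "relocated")
    expect_identical(sum(out$lattice != 0), 1L)
  }
})

test_that("a single step changes occupancy by at most one cell", {
  set.seed(10)
  for (i in 1:40) {
    cfg <- simulation_config(sigma = runif(1), f = runif(1),
                             rho0 = runif(1, 0.05, 0.9), L = 12)
    lat <- initialize_lattice(cfg)
    out <- step_lattice(lat, cfg)
    delta <- sum(out$lattice != 0) - sum(lat != 0)
    expect_true(delta %in% c(-1L, 0L, 1L))
  }
})

test_that("sigma=1 steps never alter the lattice through the detachment sub-step", {
  cfg <- simulation_config(sigma = 1, f = 1, rho0 = 0.3, L = 12)
  set.seed(11)
  lat <- initialize_lattice(cfg)
  for (i in 1:200) {
    out <- step_lattice(lat, cfg)
    expect_true(out$detach_event %in% c("none", "eligible_no_detach"))
    lat <- out$lattice
  }
})

test_that("runs stop at the occupancy threshold and keep event telemetry", {
  run <- run_to_confluence(simulation_config(sigma = 0.5, rho0 = 0.02,
                                             f = 0.5, seed = 42))
  expect_identical(run$record$terminated, "THRESHOLD")
  expect_gte(run$record$final_fraction, 0.95)
  expect_gte(run$record$births, run$record$final_fraction * 3600 - 72)

  # already-saturated initialization returns untouched after zero steps
  cfg <- simulation_config(sigma = 1, rho0 = 0.97, f = 1, seed = 43)
  set.seed(43)
  init <- initialize_lattice(cfg)
  run2 <- run_to_confluence(cfg, lattice = init)
  expect_identical(run2$record$steps, 0)
  expect_identical(unclass(run2$lattice), unclass(init))
})

test_that("no-flow runs record zero detachments", {
  for (sigma in c(0, 0.5)) {
    run <- run_to_confluence(simulation_config(sigma = sigma, rho0 = 0.05,
                                               f = 0, seed = 44))
    expect_identical(run$record$detachments, 0)
    expect_identical(run$record$relocation_removals, 0)
  }
})

test_that("fully adhesive founders keep their site and colour to confluence", {
  for (seed in c(101, 102, 103)) {
    cfg <- simulation_config(sigma = 1, rho0 = 0.03, f = 1, seed = seed)
    set.seed(seed)
    init <- initialize_lattice(cfg)
    run <- run_to_confluence(cfg, lattice = init)
    founders <- which(init != 0)
    expect_identical(unclass(run$lattice)[founders],
                     unclass(init)[founders])
  }
})

test_that("dynamics are colour-blind: label swap commutes with the run", {
  cfg <- simulation_config(sigma = 0.4, rho0 = 0.05, f = 0.7, L = 20,
                           seed = 77)
  set.seed(77)
  init <- initialize_lattice(cfg)
  run_a <- run_to_confluence(cfg, lattice = init)
  run_b <- run_to_confluence(cfg, lattice = swap_colors(init))
  expect_identical(unclass(swap_colors(run_a$lattice)),
                   unclass(run_b$lattice))
})
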