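test_that("leeward self-propulsion follows the wind unit vector", {
  expect_equal(leeward_velocity(4, 3, 3), list(sx = 2.4, sy = 1.8))
  expect_equal(leeward_velocity(0, 0, 3), list(sx = 0, sy = 0))
  s <- leeward_velocity(10, 0, 3)
  expect_equal(s$sx, 3)
  expect_equal(s$sy, 0)
  # vectorised, magnitude always flight_speed in moving air
  set.seed(3)
  u <- rnorm(50); v <- rnorm(50)
  s <- leeward_velocity(u, v, 3)
  expect_equal(sqrt(s$sx^2 + s$sy^2), rep(3, 50))
})

test_that("vertical increment combines ascent, drift and random walk", {
  cfg <- sim_config()
  # all-zero fields, post-ascent: no movement
  expect_equal(vertical_increment(0, 0, 0, cfg, ascending = FALSE), 0)
  # ascent phase in still air with no diffusion: 0.75 m/s * 120 s = 90 m
  expect_equal(vertical_increment(0, 0, 0, cfg, ascending = TRUE), 90)
  # gradient term alone
  expect_equal(vertical_increment(0, 0, 0.01, cfg, FALSE), 0.01 * 120)
  # random-walk step: sd of one step is sqrt(2 Kz dt) (~49 m at Kz = 10)
  set.seed(99)
  dz <- vertical_increment(rep(0, 1e5), rep(10, 1e5), rep(0, 1e5), cfg,
                           FALSE)
  expect_equal(sd(dz), sqrt(2 * 10 * 120), tolerance = 0.01)
  expect_lte(max(abs(dz)), sqrt(24 * 10 * 120) / 2)  # bounded support
})

test_that("boundaries reflect the ground, cap the top and honour the
          temperature ceiling", {
  met <- calm_met(surface_c = 25, lapse = 5)   # 13 degC at 2400 m
  cfg <- sim_config()
  t <- run_start()
  # below-ground candidate reflects
  b <- apply_boundaries(met, cfg, t, 30, 120, z_old = 10, z_cand = -30)
  expect_equal(b$zstar, 30)
  # top-level candidate clamps (warm column so the ceiling stays silent)
  warm <- calm_met(surface_c = 25, lapse = 1)
  b <- apply_boundaries(warm, cfg, t, 30, 120, z_old = 2900, z_cand = 3300)
  expect_equal(b$zstar, 3000)
  # ... but if the clamped level is too cold the ceiling still wins
  b <- apply_boundaries(met, cfg, t, 30, 120, z_old = 2350, z_cand = 3300)
  expect_equal(b$zstar, 2350)
  # candidate in air at <= 13 degC: vertical move cancelled
  b <- apply_boundaries(met, cfg, t, 30, 120, z_old = 2350, z_cand = 2450)
  expect_equal(b$zstar, 2350)
  # warm candidate accepted
  b <- apply_boundaries(met, cfg, t, 30, 120, z_old = 2200, z_cand = 2300)
  expect_equal(b$zstar, 2300)
  # horizontal exit deactivates
  b <- apply_boundaries(met, cfg, t, 30, 123, z_old = 100, z_cand = 120)
  expect_true(b$exited)
})

test_that("one step of advance moves with wind + self-speed and leaves
          grounded or future particles alone", {
  met <- calm_met(u = 10, v = 0, kz = 0, lapse = 2)
  cfg <- sim_config(ascent_end = 0)
  p <- one_particle(zstar = 1000)
  p$active <- TRUE; p$exited <- FALSE
  p2 <- advance(p, met, cfg, run_start())
  # 13 m/s east for 120 s = 1560 m
  dx_m <- (p2$lon - p$lon) * 111320 * cos(p$lat * pi / 180)
  expect_equal(dx_m, 13 * 120, tolerance = 1e-9)
  expect_equal(p2$lat, p$lat)
  expect_equal(p2$zstar, p$zstar)
  # zero wind, zero diffusion, post-ascent: nothing moves
  met0 <- calm_met(u = 0, v = 0, kz = 0)
  q <- advance(p, met0, cfg, run_start())
  expect_equal(q$lon, p$lon)
  expect_equal(q$lat, p$lat)
  # future take-off: unmoved even in wind
  f <- p; f$takeoff_utc <- run_start() + 7200
  f2 <- advance(f, met, cfg, run_start())
  expect_identical(f2$lon, f$lon)
  expect_identical(f2$zstar, f$zstar)
})

test_that("simulation conserves particles, records every step and is
          seed-reproducible", {
  met <- calm_met(u = 2, v = 1, kz = 5, duration_h = 3)
  src <- unit_square_source(lat0 = 30, lon0 = 120, half = 0.3)
  set.seed(4)
  rel <- build_release(src, run_start(), n_per_source = 20)
  cfg <- sim_config(horizon_h = 2)
  traj <- run_simulation(rel, met, cfg)
  expect_equal(length(unique(traj$time_utc)), 2 * 3600 / 120 + 1)
  expect_equal(nrow(traj), 20 * 61)
  # conservation: every particle present at every snapshot
  expect_true(all(table(traj$id) == 61))
  set.seed(4)
  rel2 <- build_release(src, run_start(), n_per_source = 20)
  traj2 <- run_simulation(rel2, met, cfg)
  expect_identical(traj$lat, traj2$lat)
  expect_identical(traj$lon, traj2$lon)
  expect_identical(traj$zstar, traj2$zstar)
  expect_error(run_simulation(rel, met, sim_config(horizon_h = 48)),
               "coverage")
})

test_that("still-air ascent follows the closed form and is monotone", {
  met <- calm_met(u = 0, v = 0, kz = 0, surface_c = 30, lapse = 2,
                  duration_h = 3)
  cfg <- sim_config(horizon_h = 2)
  # take-off at 10:30: ascent only until 11:00, i.e. 1800 s -> 1350 m
  rel <- one_particle(takeoff = run_start() + 1800)
  traj <- run_simulation(rel, met, cfg)
  zs <- traj$zstar  # snapshot k is at (k - 1) * 120 s after the start
  expect_true(all(zs[1:16] == 0))              # grounded until 10:30
  expect_equal(diff(zs[16:31]), rep(90, 15))   # strict 90 m/step climb
  expect_equal(zs[31], 0.75 * 1800)            # 1350 m at 11:00
  expect_equal(zs[length(zs)], 1350)           # and it stays there
  # take-off at start: full hour of ascent -> 2700 m, strictly monotone
  traj0 <- run_simulation(one_particle(), met, cfg)
  expect_equal(max(traj0$zstar), 0.75 * 3600)
  expect_true(all(diff(traj0$zstar[1:31]) > 0))
})

test_that("no particle teleports: per-step ground displacement is bounded", {
  met <- calm_met(u = 8, v = -5, kz = 20, duration_h = 2)
  set.seed(12)
  rel <- build_release(unit_square_source(30, 120, 0.4), run_start(),
                       n_per_source = 30)
  traj <- run_simulation(rel, met, sim_config(horizon_h = 1))
  bound_km <- (sqrt(8^2 + 5^2) + 3) * 120 / 1000 * 1.01
  steps <- dplyr::arrange(traj, id, time_utc)
  d <- haversine_km(head(steps$lat, -1), head(steps$lon, -1),
                    tail(steps$lat, -1), tail(steps$lon, -1))
  same <- head(steps$id, -1) == tail(steps$id, -1)
  expect_lte(max(d[same]), bound_km)
})

test_that("diffusion variance grows as 2 K t away from boundaries", {
  met <- calm_met(u = 0, v = 0, kz = 5, lapse = 0, duration_h = 2)
  set.seed(21)
  rel <- point_release(2e4, zstar = 1500)
  cfg <- sim_config(horizon_h = 1, ascent_end = 0)
  traj <- run_simulation(rel, met, cfg, record_every = 30)
  fin <- traj[traj$time_utc == max(traj$time_utc), ]
  expect_equal(var(fin$zstar), 2 * 5 * 3600, tolerance = 0.05)
})

test_that("active particles never occupy air at or below the ceiling
          temperature", {
  # inversion-like scenario: 13 degC at 1500 m (24 - 7.33 z)
  met <- calm_met(u = 0, v = 0, kz = 15, surface_c = 24, lapse = 7.33,
                  levels = seq(0, 3000, 250), duration_h = 3)
  set.seed(8)
  rel <- point_release(200)
  cfg <- sim_config(horizon_h = 2)
  traj <- run_simulation(rel, met, cfg)
  fly <- traj[traj$airborne, ]
  temps <- met_interp(met, run_start(), fly$lat, fly$lon, fly$zstar)$temp
  expect_true(all(temps > 13))
  # and the ceiling is actually binding: particles accumulate below 1500 m
  expect_gt(max(fly$zstar), 1200)
  expect_lte(max(fly$zstar), ceiling_height(24, 7.33))
})
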