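# Colony simulator: treatments, foraging, colony dynamics, experiment table
# and bootstrap contrasts.

test_that("treatments transform only the garden curve as specified", {
  pool <- gen_species_pool(seed = 1)
  curves <- lapply(pool, habitat_true_curve)
  same <- apply_treatment(curves, "garden")
  expect_identical(same, curves)
  ng <- apply_treatment(curves, "no_garden")
  expect_true(all(ng$garden$value == 0))
  expect_identical(ng$pasture, curves$pasture)
  pr <- apply_treatment(curves, "pasture_replacement")
  expect_equal(pr$garden$value, curves$pasture$value)
  eq <- apply_treatment(curves, "garden_with_pasture_phenology")
  # equal total quantity, pasture timing
  expect_equal(curve_integral(eq$garden), curve_integral(curves$garden),
               tolerance = 1e-3)
  expect_equal(which.max(eq$garden$value), which.max(curves$pasture$value))
  for (tr in c("no_garden", "pasture_replacement",
               "garden_with_pasture_phenology")) {
    out <- apply_treatment(curves, tr)
    for (h in setdiff(names(curves), "garden"))
      expect_identical(out[[h]], curves[[h]])
  }
  zero <- curves
  zero$pasture <- flat_curve("pasture", 0)
  expect_error(apply_treatment(zero, "garden_with_pasture_phenology"),
               "zero annual integral")
})

# A controllable one-colony world: one worker colony at the origin.
small_world <- function(patches, curves, cfg = abm_config(), workers = 1,
                        day = 180) {
  w <- build_world(patches, curves, cfg)
  w <- init_year_entities(w, 1)
  w$entities$state[1] <- 3L
  w$entities$workers[1] <- workers
  w$entities$x[1] <- 0; w$entities$y[1] <- 0
  w$entities$dist[1, ] <- sqrt(patches$x_m^2 + patches$y_m^2)
  w$entities$det[1, ] <- exp(-w$entities$dist[1, ] / cfg$detection_scale_m)
  w$entities$energy[1] <- 1
  replenish(w, day)
}

test_that("foraging conserves sugar and fills crops at a rich near patch", {
  cfg <- abm_config()
  patches <- one_patch_landscape(area = 100, habitat = "garden")
  curves <- list(garden = flat_curve("garden", 10))  # 1000 g/day standing
  w <- small_world(patches, curves, cfg)
  stock0 <- sum(w$stock)
  set.seed(1)
  w <- daily_forage(w)
  gross <- w$last_forage[1, 1]
  expect_equal(stock0 - sum(w$stock), gross, tolerance = 1e-9)
  # dense stock at distance 0: every trip comes back with a full crop
  expect_equal(gross, cfg$trips_per_forager * cfg$crop_capacity_g,
               tolerance = 1e-9)
})

test_that("with zero stocks a colony pays maintenance and can starve", {
  cfg <- abm_config()
  patches <- one_patch_landscape(area = 100, habitat = "garden")
  curves <- list(garden = flat_curve("garden", 0))
  w <- small_world(patches, curves, cfg, workers = 5)
  e0 <- w$entities$energy[1]
  set.seed(1)
  for (i in 1:3) {
    w <- daily_forage(w)
    w <- daily_colony_update(w)
  }
  expect_lt(w$entities$energy[1], e0)
  # keep starving: dies after the configured run of empty days
  for (i in 1:30) {
    w <- replenish(w, 180 + i)
    w <- daily_forage(w)
    w <- daily_colony_update(w)
    if (w$entities$state[1] == 0L) break
  }
  expect_equal(w$entities$state[1], 0L)
  expect_equal(w$entities$workers[1], 0)
  expect_gte(w$entities$energy[1], 0)
})

test_that("nearer of two equal patches receives more visits, as the kernel
           predicts", {
  cfg <- abm_config()
  patches <- data.frame(patch_id = c("near", "far"), x_m = c(100, 900),
                        y_m = 0, area_m2 = 10, habitat = "garden",
                        stringsAsFactors = FALSE)
  curves <- list(garden = flat_curve("garden", 1e4))  # inexhaustible
  w <- small_world(patches, curves, cfg, workers = 1)
  expected_ratio <- exp(-100 / cfg$detection_scale_m) /
    exp(-900 / cfg$detection_scale_m)
  set.seed(42)
  near <- far <- 0
  for (i in 1:200) {
    w2 <- replenish(w, 180)
    w2 <- daily_forage(w2)
    dep <- w$production[180, ] - w2$stock  # sugar taken per patch
    near <- near + dep[1]; far <- far + dep[2]
  }
  expect_gt(near, far)
  expect_equal(near / far, expected_ratio, tolerance = 0.25)
})

test_that("with unlimited food a colony grows to its worker cap", {
  cfg <- abm_config(max_workers = 40, dev_days = 5L)
  patches <- one_patch_landscape(area = 1000, habitat = "garden")
  curves <- list(garden = flat_curve("garden", 10))
  w <- small_world(patches, curves, cfg, workers = 1, day = 100)
  set.seed(3)
  for (i in 0:120) {
    w <- replenish(w, 100 + i)
    w <- daily_forage(w)
    w <- daily_colony_update(w)
  }
  expect_equal(w$entities$workers[1], 40)
  expect_true(all(w$entities$brood >= 0))
  expect_gte(w$entities$energy[1], 0)
})

test_that("zero-nectar landscapes kill queens and colonies", {
  ls <- gen_landscapes(n = 1, seed = 4)[[1]]
  habs <- unique(ls$patches$habitat)
  curves <- stats::setNames(lapply(habs, function(h) flat_curve(h, 0)), habs)
  cfg <- abm_config(init_queens = 30L, years = 2L)
  r <- run_simulation(ls, curves, "garden", cfg, seed = 7)
  expect_equal(r$spring_queen_survival, c(0, 0))
  expect_equal(r$max_colonies_per_year, c(0, 0))
  expect_equal(r$total_bees_per_year, c(0, 0))
})

test_that("simulations are deterministic given a seed", {
  pool <- gen_species_pool(seed = 1)
  curves <- lapply(pool, habitat_true_curve)
  ls <- gen_landscapes(n = 1, seed = 5)[[1]]
  cfg <- abm_config(init_queens = 40L, years = 2L)
  r1 <- run_simulation(ls, curves, "garden", cfg, seed = 10)
  r2 <- run_simulation(ls, curves, "garden", cfg, seed = 10)
  expect_identical(r1, r2)
  r3 <- run_simulation(ls, curves, "garden", cfg, seed = 11)
  expect_false(identical(r1$summary, r3$summary))
})

test_that("experiment tables have full-factorial shape and reproduce", {
  pool <- gen_species_pool(seed = 1)
  curves <- lapply(pool, habitat_true_curve)
  ls <- gen_landscapes(n = 2, seed = 6)
  cfg <- abm_config(init_queens = 20L, years = 1L)
  tab <- run_experiment(ls, curves, treatments = c("garden", "no_garden"),
                        reps = 1, config = cfg, seed = 3)
  expect_equal(nrow(tab), 4)
  expect_equal(sort(unique(tab$treatment)), c("garden", "no_garden"))
  tab2 <- run_experiment(ls, curves, treatments = c("garden", "no_garden"),
                         reps = 1, config = cfg, seed = 3)
  expect_identical(tab, tab2)
})

test_that("doubling all curves does not decrease total bees (paired seeds)", {
  pool <- gen_species_pool(seed = 2)
  curves <- lapply(pool, habitat_true_curve)
  doubled <- lapply(curves, function(cv)
    phenology_curve(cv$habitat, cv$day, cv$value * 2))
  ls <- gen_landscapes(n = 1, seed = 7)[[1]]
  cfg <- abm_config(init_queens = 25L, years = 1L)
  base <- dbl <- numeric(10)
  for (s in 1:10) {
    base[s] <- run_simulation(ls, curves, "garden", cfg,
                              seed = s)$summary[["total_bees"]]
    dbl[s] <- run_simulation(ls, doubled, "garden", cfg,
                             seed = s)$summary[["total_bees"]]
  }
  expect_gte(mean(dbl), mean(base))
})

test_that("state stays physical through a simulated season", {
  pool <- gen_species_pool(seed = 3)
  curves <- lapply(pool, habitat_true_curve)
  ls <- gen_landscapes(n = 1, seed = 8)[[1]]
  cfg <- abm_config(init_queens = 20L)
  w <- build_world(ls, curves, cfg)
  set.seed(5)
  w <- init_year_entities(w, cfg$init_queens)
  ent <- w$entities
  for (day in 60:304) {
    wake <- ent$state == 1L & ent$emergence_day <= day
    ent$state[wake] <- 2L
    w$entities <- ent
    w <- replenish(w, day)
    w <- daily_forage(w)
    w <- daily_colony_update(w)
    ent <- w$entities
    expect_true(all(ent$energy >= 0))
    expect_true(all(ent$workers >= 0))
    expect_true(all(ent$brood >= 0))
    expect_true(all(w$stock >= 0))
    # dead colonies are inert
    expect_true(all(ent$workers[ent$state == 0L] == 0))
  }
})

test_that("bootstrap contrasts recover known effects", {
  set.seed(31)
  lsn <- sprintf("L%02d", 1:12)
  baseline <- data.frame(landscape = rep(lsn, each = 5), treatment = "garden",
                         rep = 1:5, max_colonies = rep(stats::runif(12, 50, 150),
                                                       each = 5))
  same <- baseline; same$treatment <- "same"
  tab0 <- rbind(baseline, same)
  ct0 <- treatment_contrasts(tab0, "garden", "max_colonies", n_boot = 500)
  expect_equal(ct0$pct_change, 0)
  expect_true(ct0$lower <= 0 & ct0$upper >= 0)
  expect_false(ct0$excludes_zero)
  # exact -20%: degenerate CI at -20
  down <- baseline; down$treatment <- "down"
  down$max_colonies <- 0.8 * down$max_colonies
  ct1 <- treatment_contrasts(rbind(baseline, down), "garden",
                             "max_colonies", n_boot = 500)
  expect_equal(ct1$pct_change, -20, tolerance = 1e-9)
  expect_equal(ct1$lower, -20, tolerance = 1e-9)
  expect_equal(ct1$upper, -20, tolerance = 1e-9)
  # injected -15% mean effect with between-landscape spread and replicate
  # noise: recovered within the 95% CI
  set.seed(1)
  eff <- 0.85 + stats::rnorm(12, 0, 0.03)
  noisy <- baseline; noisy$treatment <- "noisy"
  noisy$max_colonies <- rep(eff, each = 5) * noisy$max_colonies *
    (1 + stats::rnorm(nrow(noisy), 0, 0.03))
  ct2 <- treatment_contrasts(rbind(baseline, noisy), "garden",
                             "max_colonies", n_boot = 2000)
  expect_gte(-15, ct2$lower)
  expect_lte(-15, ct2$upper)
  expect_error(treatment_contrasts(tab0, "garden", "not_an_endpoint"),
               "endpoint")
  expect_error(treatment_contrasts(baseline, "missing_baseline",
                                   "max_colonies"), "baseline")
})
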