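# Landscape aggregation, garden fraction, per-bee supply and deficit scan.

make_two_hab <- function(gval = 2, pval = 1, g_area = 100, p_area = 100) {
  curves <- list(garden = flat_curve("garden", gval),
                 pasture = flat_curve("pasture", pval))
  comp <- landscape_composition("L1", c(garden = g_area, pasture = p_area),
                                cell_area = 1e6)
  list(curves = curves, comp = comp)
}

test_that("aggregation is the area-weighted pointwise sum", {
  x <- make_two_hab()
  one <- landscape_composition("L1", c(pasture = 1), cell_area = 1e6)
  s1 <- aggregate_landscape(x$curves, one)
  expect_equal(s1$supply, x$curves$pasture$value)
  s <- aggregate_landscape(x$curves, x$comp)
  comp2 <- landscape_composition("L2", x$comp$areas * 2, cell_area = 1e6)
  s2 <- aggregate_landscape(x$curves, comp2)
  expect_equal(s2$supply, 2 * s$supply)
  # missing curve for a habitat with positive area
  badcomp <- landscape_composition("L3", c(pasture = 1, woodland = 5),
                                   cell_area = 1e6)
  expect_error(aggregate_landscape(x$curves, badcomp), "woodland")
})

test_that("aggregation commutes with quadrature (integral linearity)", {
  pool <- gen_species_pool(seed = 2)
  curves <- lapply(pool, habitat_true_curve)
  comp <- gen_landscapes(n = 1, seed = 2)[[1]]$composition
  s <- aggregate_landscape(curves, comp)
  lhs <- trapz_test(s$day, s$supply)
  rhs <- sum(vapply(names(curves), function(h) {
    a <- if (h %in% names(comp$areas)) comp$areas[[h]] else 0
    a * curve_integral(curves[[h]])
  }, numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("removing gardens never increases supply", {
  for (seed in 1:5) {
    pool <- gen_species_pool(seed = seed)
    curves <- lapply(pool, habitat_true_curve)
    comp <- gen_landscapes(n = 1, seed = seed)[[1]]$composition
    w <- aggregate_landscape(curves, comp, include_gardens = TRUE)
    wo <- aggregate_landscape(curves, comp, include_gardens = FALSE)
    expect_true(all(wo$supply <= w$supply + 1e-12))
  }
})

test_that("garden fraction is bounded, symmetric and missing when undefined", {
  x <- make_two_hab(gval = 1, pval = 1, g_area = 50, p_area = 50)
  gf <- garden_fraction(x$curves, x$comp)
  expect_equal(gf$fraction, rep(0.5, nrow(gf)))
  nog <- landscape_composition("L1", c(pasture = 100), cell_area = 1e6)
  gf0 <- garden_fraction(x$curves, nog)
  expect_equal(gf0$fraction, rep(0, nrow(gf0)))
  # zero total supply on some days -> NA, never 0
  zc <- list(garden = phenology_curve("garden", 1:10, c(rep(0, 5), rep(1, 5))),
             pasture = phenology_curve("pasture", 1:10, rep(0, 10)))
  gfz <- garden_fraction(zc, x$comp)
  expect_true(all(is.na(gfz$fraction[1:5])))
  expect_equal(gfz$fraction[6:10], rep(1, 5))
  pool <- gen_species_pool(seed = 1)
  curves <- lapply(pool, habitat_true_curve)
  comp <- gen_landscapes(n = 1, seed = 1)[[1]]$composition
  gfr <- garden_fraction(curves, comp)
  ok <- !is.na(gfr$fraction)
  expect_true(all(gfr$fraction[ok] >= 0 & gfr$fraction[ok] <= 1))
  # the designed contrast: garden share peaks in the shoulders, not mid-summer
  shoulders <- mean(gfr$fraction[gfr$day %in% c(60:90, 280:304)], na.rm = TRUE)
  midsummer <- mean(gfr$fraction[gfr$day %in% 170:210], na.rm = TRUE)
  expect_gt(shoulders, midsummer)
})

test_that("bee population follows monthly step weights", {
  m1 <- bee_population_model("sp1", 10, 100,
                             c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 0, 0))
  bp <- bee_population(list(m1), cell_area_km2 = 1)
  expect_equal(bp$bees[bp$day == 70], 1000)   # March
  expect_equal(bp$bees[bp$day == 40], 0)      # February
  flat <- bee_population_model("sp2", 5, 200, rep(1, 12))
  bpf <- bee_population(list(flat), cell_area_km2 = 2)
  expect_true(all(bpf$bees == 2000))
  # hand-summed value on day 135 (May) for three species
  ms <- list(bee_population_model("a", 10, 100,
                                  c(0,0,.1,.2,.5,.8,1,.8,.4,.1,0,0)),
             bee_population_model("b", 20, 50,
                                  c(0,0,.2,.4,.6,.9,1,.9,.5,.2,0,0)),
             bee_population_model("c", 5, 300,
                                  c(0,0,0,.3,.4,.7,1,.7,.3,0,0,0)))
  bp3 <- bee_population(ms, cell_area_km2 = 1)
  expect_equal(bp3$bees[bp3$day == 135],
               10 * 100 * 0.5 + 20 * 50 * 0.6 + 5 * 300 * 0.4)
})

test_that("per-bee supply divides pointwise and flags zero-bee days", {
  sup <- data.frame(day = 1:10, supply = rep(100, 10), se = rep(0, 10))
  bees <- data.frame(day = 1:10, bees = c(rep(0, 2), rep(1000, 8)))
  pb <- per_bee_supply(sup, bees)
  expect_equal(nrow(pb), 8)
  expect_equal(pb$per_bee, rep(0.1, 8))
  expect_equal(attr(pb, "excluded_days"), 1:2)
  bees2 <- bees; bees2$bees <- bees2$bees * 2
  pb2 <- per_bee_supply(sup, bees2)
  expect_equal(pb2$per_bee, pb$per_bee / 2)
  expect_error(per_bee_supply(sup, bees[1:5, ]), "grid")
})

test_that("full chain matches a hand computation on one day", {
  x <- make_two_hab(gval = 2, pval = 1, g_area = 300, p_area = 700)
  sup <- aggregate_landscape(x$curves, x$comp)
  bees <- bee_population(list(bee_population_model("sp", 10, 100,
                                                   rep(1, 12))),
                         cell_area_km2 = 1)
  pb <- per_bee_supply(sup, bees)
  # day 90: (300*2 + 700*1) / (10*100)
  expect_equal(pb$per_bee[pb$day == 90], 1300 / 1000)
})

test_that("deficit intervals match the brute-force daily scan", {
  # crafted curve crossing the requirement at days 60 and 250
  day <- 30:330
  dem <- demand_curve(grid = day, base_requirement = 1,
                      spring_queen_multiplier = 1)
  v <- ifelse(day > 60 & day <= 250, 2, 0.5)
  pb <- data.frame(day = day, per_bee = v)
  rep1 <- find_deficits(pb, dem)
  expect_equal(rep1$start, c(30, 251))
  expect_equal(rep1$end, c(60, 330))
  expect_equal(rep1$max_shortfall, c(0.5, 0.5))
  # everywhere above / everywhere below
  above <- data.frame(day = day, per_bee = rep(2, length(day)))
  expect_equal(nrow(find_deficits(above, dem)), 0)
  below <- data.frame(day = day, per_bee = rep(0.1, length(day)))
  rb <- find_deficits(below, dem)
  expect_equal(nrow(rb), 1)
  expect_equal(c(rb$start, rb$end), c(30, 330))
  # randomized curves: exact oracle equivalence
  set.seed(99)
  for (i in 1:25) {
    v <- pmax(0, stats::rnorm(length(day), 1, 0.5))
    pbr <- data.frame(day = day, per_bee = v)
    got <- find_deficits(pbr, dem)
    want <- brute_deficits(pbr, dem)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$max_shortfall, want$max_shortfall)
  }
  expect_error(find_deficits(pb, demand_curve(grid = 1:10)), "grid")
})

test_that("gardens shrink the designed landscape's deficit", {
  pool <- gen_species_pool(seed = 1)
  curves <- lapply(pool, habitat_true_curve)
  comp <- gen_landscapes(n = 1, seed = 1)[[1]]$composition  # ~2% garden
  bees <- bee_population(default_bee_models(), comp$cell_area / 1e6,
                         grid = 60:304)
  grid_use <- bees$day[bees$bees > 0]
  bees <- bees[bees$bees > 0, ]
  gsub <- function(include) {
    s <- aggregate_landscape(curves, comp, include_gardens = include)
    per_bee_supply(s[s$day %in% grid_use, ], bees)
  }
  dem <- demand_curve(grid = grid_use)
  d_with <- find_deficits(gsub(TRUE), dem, "with_gardens")
  d_without <- find_deficits(gsub(FALSE), dem, "without_gardens")
  days <- function(d) if (nrow(d)) sum(d$end - d$start + 1) else 0
  expect_lt(days(d_with), days(d_without))
})
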