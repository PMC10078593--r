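test_that("degenerate mosaics and invalid proportions are handled", {
  L <- tiny_landscape(proportions = c(forest = 1, woodland = 0, nonforest = 0))
  expect_true(all(L$vegetation$values == 1L))
  expect_true(all(L$dist_forest$values == 0))
  expect_error(tiny_landscape(proportions = c(forest = 0.5, woodland = 0.5, nonforest = 0.1)),
               "sum to 1")
  expect_error(generate_landscape(nx = 5, ny = 5), "at least 10 x 10")
})

test_that("realized vegetation shares match targets within 3 points", {
  L <- generate_landscape(nx = 100, ny = 100, seed = 1)
  share <- tabulate(L$vegetation$values, 3) / 1e4
  expect_lt(abs(share[1] - 0.06), 0.03)
  expect_lt(abs(share[2] - 0.71), 0.03)
  expect_lt(abs(share[3] - 0.23), 0.03)
})

test_that("landscape generation is seed-deterministic", {
  L1 <- tiny_landscape(seed = 9)
  L2 <- tiny_landscape(seed = 9)
  expect_identical(L1$vegetation$values, L2$vegetation$values)
  expect_identical(L1$elevation$values, L2$elevation$values)
  expect_identical(L1$hpd$values, L2$hpd$values)
  expect_false(identical(tiny_landscape(seed = 10)$elevation$values,
                         L1$elevation$values))
})

test_that("nest field expectation equals density x production x lifetime x area", {
  # uniform truth: D = 0.86 ind/km2, t = 1.09, r = 100 d over a 100 km2 grid
  # => E[nests] = 0.86 * 1.09 * 100 * 100 = 9374
  L <- tiny_landscape(nx = 10, ny = 10, seed = 3)
  decay <- synthetic_decay_table(lakeshore = c(forest = 100, woodland = 100, nonforest = 100),
                                 inland = c(forest = 100, woodland = 100, nonforest = 100))
  tp <- truth_params(baseline_density = c(forest = 0.86, woodland = 0.86, nonforest = 0.86),
                     annual_change = c(forest = 1, woodland = 1, nonforest = 1),
                     decay_table = decay, years = 2010)
  counts <- vapply(1:200, function(s) nrow(simulate_nest_field(L, tp, 2010, seed = s)), 0)
  expected <- 0.86 * 1.09 * 100 * 100
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 2 * se + 1e-9)
  # zero density -> empty point set
  tp0 <- truth_params(baseline_density = c(forest = 0, woodland = 0, nonforest = 0),
                      years = 2010)
  expect_equal(nrow(simulate_nest_field(L, tp0, 2010, seed = 1)), 0)
})

test_that("expected totals decline at the configured annual rate", {
  # annual change 0.9759 => log-linear slope on expected totals = -2.41 %/yr
  L <- tiny_landscape(seed = 4)
  tp <- truth_params(annual_change = c(forest = 0.9759, woodland = 0.9759, nonforest = 0.9759),
                     years = 2010:2019)
  totals <- vapply(tp$years, function(y) true_abundance(L, tp, y), 0)
  tr <- annual_trend(data.frame(year = tp$years, abundance = totals))
  expect_equal(tr$annual_rate_pct, -2.41, tolerance = 1e-6)
})

test_that("survey detection is a half-normal thinning of in-strip nests", {
  L <- tiny_landscape(nx = 10, ny = 10, seed = 5)
  tp <- truth_params(baseline_density = c(forest = 3, woodland = 3, nonforest = 3),
                     annual_change = c(forest = 1, woodland = 1, nonforest = 1),
                     years = 2010)
  # certain detection: every nest within the strip is recorded, distances <= w
  nests <- simulate_nest_field(L, tp, 2010, seed = 1)
  sv_inf <- simulate_survey(L, nests, "parallel", w = 50, sigma = Inf,
                            block_km = 8, n_blocks = 1, seed = 2)
  expect_true(all(sv_inf$observations$distance_m >= 0))
  expect_true(all(sv_inf$observations$distance_m <= 50))
  # sigma = 20 m, w = 50 m: detected fraction of in-strip nests ~ 0.495
  ratios <- vapply(1:100, function(s) {
    nests_s <- simulate_nest_field(L, tp, 2010, seed = 100 + s)
    all_in <- simulate_survey(L, nests_s, "parallel", w = 50, sigma = Inf,
                              block_km = 8, n_blocks = 1, seed = 200 + s)
    det <- simulate_survey(L, nests_s, "parallel", w = 50, sigma = 20,
                           block_km = 8, n_blocks = 1, seed = 200 + s)
    nrow(det$observations) / nrow(all_in$observations)
  }, 0)
  p_true <- hn_average_p(20, 50)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - p_true), 2 * se + 1e-9)
})

test_that("parallel design lays ~20 lines per 10 km at 0.5 km spacing", {
  L <- tiny_landscape(nx = 10, ny = 10, seed = 6)
  nests <- data.frame(x = numeric(0), y = numeric(0),
                      vegetation = factor(character(0), veg_levels()),
                      year = numeric(0))
  sv <- simulate_survey(L, nests, "parallel", spacing = 500, block_km = 10,
                        n_blocks = 1, seed = 3)
  expect_true(nrow(sv$transects) %in% 19:21)
  # surveys are seed-deterministic
  tp <- truth_params(years = 2010)
  nests2 <- simulate_nest_field(L, tp, 2010, seed = 7)
  a <- simulate_survey(L, nests2, "parallel", sigma = 20, seed = 11)
  b <- simulate_survey(L, nests2, "parallel", sigma = 20, seed = 11)
  expect_identical(a$transects, b$transects)
  expect_identical(a$observations, b$observations)
})

test_that("impossible designs and out-of-span years error", {
  L <- tiny_landscape(seed = 8)
  tp <- truth_params(years = 2010:2012)
  expect_error(simulate_nest_field(L, tp, 2030, seed = 1), "span")
  nests <- simulate_nest_field(L, tp, 2010, seed = 1)
  # systematic design whose transects cannot fit the grid -> zero transects
  expect_error(simulate_survey(L, nests, "systematic", grid_spacing = 1e6,
                               transect_km = 1e3, seed = 1),
               "zero transects")
})

test_that("one-way habitat loss conserves cells and only grows nonforest", {
  L <- tiny_landscape(nx = 40, ny = 40, seed = 12)
  years <- 2010:2019
  vr <- apply_habitat_loss(L, years, rates = c(forest = 0.05, woodland = 0.02), seed = 1)
  n_cells <- length(L$vegetation$values)
  counts <- sapply(vr, function(r) tabulate(r$values, 3))
  expect_true(all(colSums(counts) == n_cells))        # cell-for-cell conservation
  expect_true(all(diff(counts[1, ]) <= 0))            # forest never increases
  expect_true(all(diff(counts[2, ]) <= 0))            # woodland never increases
  expect_true(all(diff(counts[3, ]) >= 0))            # nonforest never shrinks
})

test_that("radial and systematic designs produce the advertised geometry", {
  L <- tiny_landscape(seed = 20)
  rd <- survey_design(L, "radial", n_centers = 3, arm_km = 1.5, seed = 4)
  expect_equal(nrow(rd), 12)                     # four cardinal arms per centre
  expect_equal(unique(round(rd$length_km, 9)), 1.5)
  expect_equal(as.integer(table(rd$site)), rep(4L, 3))
  sys <- survey_design(L, "systematic", grid_spacing = 5000, transect_km = 0.7,
                       seed = 5)
  expect_gt(nrow(sys), 4)
  expect_equal(unique(round(sys$length_km, 9)), 0.7)
  # distances recorded by any design stay within the strip
  tp <- truth_params(years = 2010)
  nests <- simulate_nest_field(L, tp, 2010, seed = 6)
  sv <- simulate_survey(L, nests, "radial", w = 40, sigma = tp$sigma,
                        n_centers = 4, arm_km = 2, seed = 7)
  expect_true(all(sv$observations$distance_m <= 40))
  expect_true(all(sv$observations$chainage_km >= 0 &
                  sv$observations$chainage_km <= 2 + 1e-9))
})

test_that("a survey run round-trips through the on-disk format", {
  L <- tiny_landscape(nx = 12, ny = 12, seed = 21)
  tp <- truth_params(years = 2010)
  nests <- simulate_nest_field(L, tp, 2010, seed = 1)
  sv <- simulate_survey(L, nests, "parallel", sigma = tp$sigma, n_blocks = 2,
                        block_km = 6, seed = 2)
  dir <- withr::local_tempdir()
  write_survey_run(dir, sv$transects, sv$observations, L, tp, seed = 2)
  tr <- read.csv(file.path(dir, "transects.csv"))
  expect_equal(nrow(tr), nrow(sv$transects))
  veg <- read_asc(file.path(dir, "vegetation.asc"), levels = veg_levels())
  expect_equal(veg$values, matrix(as.numeric(L$vegetation$values), 12, 12))
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$seed, 2)
})
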