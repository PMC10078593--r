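# landscape + intercept-only model shared by the prediction tests
pred_fixture <- local({
  L <- NULL; m <- NULL
  function() {
    if (is.null(L)) {
      L <<- tiny_landscape(seed = 17)
      seg <- toy_segments(n = 200, seed = 17, beta0 = log(6))
      seg$x <- runif(200, 0, 2e4); seg$y <- runif(200, 0, 2e4)
      m <<- fit_dsm(seg, family = "nb", formula = count ~ 1 + offset(log_area))
    }
    list(L = L, m = m)
  }
})

test_that("intercept-only prediction is a constant surface with constant SD", {
  fx <- pred_fixture()
  s <- predict_surface(fx$m, fx$L, 2015)
  mu <- exp(coef(fx$m$gam)[["(Intercept)"]])
  expect_equal(unique(round(as.vector(s$mean$values), 10)), round(mu, 10))
  expect_equal(length(unique(round(as.vector(s$sd$values), 12))), 1L)
  expect_true(all(s$sd$values > 0))
  expect_equal(s$unit, "nests/km2")
})

test_that("nest-to-individual conversion divides by production x lifetime", {
  fx <- pred_fixture()
  s <- predict_surface(fx$m, fx$L, 2015)
  # uniform decay of 100 days everywhere: D = 109 nests/km2 -> 1 ind/km2
  decay100 <- synthetic_decay_table(
    lakeshore = c(forest = 100, woodland = 100, nonforest = 100),
    inland = c(forest = 100, woodland = 100, nonforest = 100))
  ind <- nests_to_individuals(s, fx$L, production = 1.09, decay = decay100)
  expect_equal(ind$mean$values, s$mean$values / 109, tolerance = 1e-12)
  expect_equal(ind$sd$values, s$sd$values / 109, tolerance = 1e-12)
  expect_equal(ind$unit, "individuals/km2")
  # doubling r halves individual density
  decay200 <- synthetic_decay_table(
    lakeshore = c(forest = 200, woodland = 200, nonforest = 200),
    inland = c(forest = 200, woodland = 200, nonforest = 200))
  ind2 <- nests_to_individuals(s, fx$L, production = 1.09, decay = decay200)
  expect_equal(ind2$mean$values, ind$mean$values / 2, tolerance = 1e-12)
  # a missing region x vegetation cell is an error naming the cell
  broken <- synthetic_decay_table()[-1, ]
  expect_error(nests_to_individuals(s, fx$L, decay = broken), "lakeshore forest")
})

test_that("stratum abundance integrates density and respects additivity", {
  fx <- pred_fixture()
  s <- predict_surface(fx$m, fx$L, 2015)
  # single-cell mask: N equals that cell's density (1 km2 cells)
  mask1 <- matrix(FALSE, 20, 20); mask1[4, 7] <- TRUE
  a1 <- stratum_abundance(s, mask1)
  expect_equal(a1$abundance, s$mean$values[4, 7])
  # disjoint masks: abundances add exactly
  maskA <- matrix(FALSE, 20, 20); maskA[1:10, ] <- TRUE
  maskB <- !maskA
  aA <- stratum_abundance(s, maskA); aB <- stratum_abundance(s, maskB)
  aAll <- stratum_abundance(s, NULL)
  expect_equal(aA$abundance + aB$abundance, aAll$abundance, tolerance = 1e-9)
  # uniform 0.86 ind/km2 over 894 km2 -> N = 769 (lognormal CI brackets it)
  expect_equal(0.86 * 894, 768.84, tolerance = 1e-9)
  expect_warning(a0 <- stratum_abundance(s, matrix(FALSE, 20, 20)), "empty")
  expect_equal(a0$abundance, 0)
})

test_that("unit conversion commutes with stratum aggregation", {
  fx <- pred_fixture()
  s <- predict_surface(fx$m, fx$L, 2015)
  decay100 <- synthetic_decay_table(
    lakeshore = c(forest = 100, woodland = 100, nonforest = 100),
    inland = c(forest = 100, woodland = 100, nonforest = 100))
  ind <- nests_to_individuals(s, fx$L, production = 1.09, decay = decay100)
  mask <- stratum_mask(fx$L, "woodland")
  a_nest <- stratum_abundance(s, mask)
  a_ind <- stratum_abundance(ind, mask)
  expect_equal(a_ind$abundance, a_nest$abundance / (1.09 * 100), tolerance = 1e-9)
  expect_equal(a_ind$cv_gam, a_nest$cv_gam, tolerance = 1e-9)
})

test_that("uncertainty propagation is the root-sum-of-squares", {
  expect_equal(propagate_uncertainty(0.19, 0), 0.19)
  expect_equal(propagate_uncertainty(0.19, 0.01), sqrt(1e-4 + 0.0361))
  expect_equal(propagate_uncertainty(0.19, 0.01), 0.19026, tolerance = 1e-4)
  expect_equal(propagate_uncertainty(0.3, 0.4), propagate_uncertainty(0.4, 0.3))
})

test_that("annual trend recovers geometric declines exactly and under noise", {
  # constructed geometric series at -2.41 %/yr
  yrs <- 2010:2019
  N <- 5000 * 0.9759^(yrs - 2010)
  tr <- annual_trend(data.frame(year = yrs, abundance = N))
  expect_equal(tr$annual_rate_pct, -2.41, tolerance = 1e-9)
  expect_equal(tr$total_change_pct, (0.9759^9 - 1) * 100, tolerance = 1e-6)
  expect_equal(tr$method, "loglinear")
  # constant series: 0 %/yr under both methods
  cst <- data.frame(year = yrs, abundance = rep(100, 10))
  expect_equal(annual_trend(cst)$annual_rate_pct, 0)
  expect_equal(annual_trend(cst, method = "meanchange")$annual_rate_pct, 0)
  # mean year-over-year change handles gap years geometrically
  gap <- data.frame(year = c(2010, 2011, 2013), abundance = 100 * 0.9^c(0, 1, 3))
  expect_equal(annual_trend(gap, method = "meanchange")$annual_rate_pct, -10,
               tolerance = 1e-9)
  # noisy decline: recovered within 0.5 points (median over seeds)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    Nn <- N * exp(rnorm(10, 0, 0.05))
    abs(annual_trend(data.frame(year = yrs, abundance = Nn))$annual_rate_pct + 2.41)
  }, 0)
  expect_lt(median(errs), 0.5)
  expect_error(annual_trend(data.frame(year = yrs[1:3], abundance = c(1, -1, 2))),
               "nonpositive")
})

test_that("habitat trends track one-way vegetation loss", {
  # grid large enough that whole-cell rounding barely quantizes the rates
  L <- tiny_landscape(nx = 100, ny = 100, seed = 18)
  years <- 2010:2019
  # no loss: all classes flat
  vr0 <- apply_habitat_loss(L, years, rates = c(forest = 0, woodland = 0), seed = 1)
  ht0 <- habitat_trend(vr0)
  expect_equal(ht0$trends$forest$annual_rate_pct, 0)
  expect_equal(ht0$trends$woodland$annual_rate_pct, 0)
  # removing 1.36%/yr of remaining forest: rate ~ -1.36, total ~ -12.8% per
  # geometric composition (cell rounding adds discreteness noise)
  vr <- apply_habitat_loss(L, years, rates = c(forest = 0.0136, woodland = 0.0032),
                           seed = 2)
  ht <- habitat_trend(vr)
  expect_equal(ht$trends$forest$annual_rate_pct, -1.36, tolerance = 0.15)
  expect_equal(ht$trends$forest$total_change_pct, (0.9864^9 - 1) * 100,
               tolerance = 1.5)
  # cell-for-cell conservation: forest+woodland loss = nonforest gain
  ar <- ht$areas
  expect_equal(ar$forest + ar$woodland + ar$nonforest,
               rep(sum(ar[1, -1]), nrow(ar)))
  # a regrowth series violates the one-way consistency check
  vr_bad <- vr
  vr_bad[[length(vr_bad)]] <- vr[[1]]
  expect_error(habitat_trend(vr_bad), "increases")
})

test_that("planning-area summaries average the right cells", {
  fx <- pred_fixture()
  s <- predict_surface(fx$m, fx$L, 2015)
  surfaces <- list("2015" = s)
  # polygon covering exactly one cell centre
  one <- data.frame(x = c(3100, 3900, 3900, 3100), y = c(5100, 5100, 5900, 5900))
  # polygon covering the whole grid
  all_p <- data.frame(x = c(-1, 20001, 20001, -1), y = c(-1, -1, 20001, 20001))
  cs <- cap_area_summary(surfaces, list(one_cell = one, whole = all_p))
  r1 <- cs[cs$area == "one_cell", ]
  expect_equal(r1$n_cells, 1)
  expect_equal(r1$mean_density, s$mean$values[6, 4])
  r2 <- cs[cs$area == "whole", ]
  expect_equal(r2$n_cells, 400)
  expect_equal(r2$mean_density, mean(s$mean$values))
  expect_warning(cap_area_summary(surfaces, list(off = data.frame(
    x = c(-5000, -4000, -4000), y = c(0, 0, 1000)))), "no grid cell")
})

test_that("GeoJSON planning areas round-trip through the reader", {
  poly <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "core-range"),
      geometry = list(type = "Polygon",
                      coordinates = list(list(list(0, 0), list(8000, 0),
                                              list(8000, 6000), list(0, 6000),
                                              list(0, 0))))
    ))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(poly, path, auto_unbox = TRUE)
  caps <- read_cap_geojson(path)
  expect_named(caps, "core-range")
  expect_equal(nrow(caps$`core-range`), 5)
  expect_equal(caps$`core-range`$x[2], 8000)
})

test_that("high-density subregions rank above their complement", {
  # direct simulation of surfaces with a hot subregion
  set.seed(19)
  hits <- vapply(1:40, function(s) {
    vals <- matrix(rgamma(400, 2, 2), 20, 20)
    vals[5:10, 5:10] <- vals[5:10, 5:10] + 2    # hot CAP area
    mean(vals[5:10, 5:10]) > mean(vals[-(5:10), ])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
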