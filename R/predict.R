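#' Prediction frame for a landscape grid
#'
#' One row per grid cell with every model covariate, cell-centre coordinates,
#' the requested year and a log offset equal to the log cell area (km^2), so
#' predicted responses are expected nest counts per cell and, divided by cell
#' area, nest densities per km^2.
#'
#' @param landscape a `nest_landscape`.
#' @param year prediction year.
#' @param vegetation optional replacement vegetation raster (e.g. a
#'   habitat-loss year from [apply_habitat_loss()]).
#' @return data.frame with one row per cell (column-major cell order).
#' @export
prediction_frame <- function(landscape, year, vegetation = NULL) {
  veg <- if (is.null(vegetation)) landscape$vegetation else vegetation
  xy <- raster_xy(veg)
  cell_km2 <- (landscape$cellsize / 1000)^2
  data.frame(
    x = xy$x, y = xy$y, year = year,
    vegetation = factor(veg_levels()[as.vector(veg$values)], veg_levels()),
    region = factor(region_levels()[as.vector(landscape$region$values)], region_levels()),
    temp_range = as.vector(landscape$temp_range$values),
    elevation = as.vector(landscape$elevation$values),
    dist_slope = as.vector(landscape$dist_slope$values),
    dist_forest = as.vector(landscape$dist_forest$values),
    hpd = as.vector(landscape$hpd$values),
    area_km2 = cell_km2, log_area = log(cell_km2)
  )
}

#' Predict a density surface on the landscape grid
#'
#' Per-cell mean nest density from the fitted GAM and per-cell standard
#' deviation propagated from the coefficient covariance by the delta method
#' on the linear predictor (SD of the mean surface, not of new counts).
#' Cells whose covariates fall outside the training range are still predicted
#' but flagged in an extrapolation mask.
#'
#' @param model a `dsm_model`.
#' @param landscape a `nest_landscape`.
#' @param year prediction year.
#' @param vegetation optional replacement vegetation raster for that year.
#' @return object of class `density_surface`: `mean` and `sd` rasters
#'   (nests/km^2), `unit`, `year`, extrapolation mask, and the pieces needed
#'   for stratum variance (model reference, prediction frame, cell weights).
#' @export
predict_surface <- function(model, landscape, year, vegetation = NULL) {
  nd <- prediction_frame(landscape, year, vegetation)
  pr <- stats::predict(model$gam, newdata = nd, type = "link", se.fit = TRUE)
  cell_km2 <- nd$area_km2[1]
  dens <- exp(as.numeric(pr$fit)) / cell_km2
  sdv <- dens * as.numeric(pr$se.fit)          # delta method on the log link
  d <- c(landscape$ny, landscape$nx)

  tr <- model$gam$model
  extrap <- rep(FALSE, nrow(nd))
  for (v in c("temp_range", "elevation", "dist_slope", "dist_forest", "x", "y", "year")) {
    if (!is.null(tr[[v]]))
      extrap <- extrap | nd[[v]] < min(tr[[v]]) | nd[[v]] > max(tr[[v]])
  }
  structure(list(
    mean = grid_raster(matrix(dens, d[1], d[2]), landscape$origin, landscape$cellsize),
    sd = grid_raster(matrix(sdv, d[1], d[2]), landscape$origin, landscape$cellsize),
    unit = "nests/km2", year = year,
    extrapolated = grid_raster(matrix(extrap, d[1], d[2]),
                               landscape$origin, landscape$cellsize),
    model = model, frame = nd,
    conversion = rep(1, nrow(nd)), cell_km2 = cell_km2,
    cache = new.env(parent = emptyenv())
  ), class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %s, year %s\n", x$unit, x$year))
  cat(sprintf("  mean density %.4g (range %.4g - %.4g), %.1f%% cells extrapolated\n",
              mean(x$mean$values), min(x$mean$values), max(x$mean$values),
              100 * mean(x$extrapolated$values)))
  invisible(x)
}

#' Convert a nest surface to a weaned-individual surface
#'
#' Standing-crop conversion D_individuals = D_nests / (t * r): nest density
#' divided by the nest production rate t (nests per individual per day) and
#' the mean nest lifetime r (days), with r looked up cell-wise from the decay
#' table by region and vegetation class. The per-cell SD is scaled by the
#' same factor.
#'
#' @param surface a nests/km^2 `density_surface`.
#' @param landscape the `nest_landscape` the surface was predicted on.
#' @param production nest production rate t (default 1.09 nests/ind/day).
#' @param decay decay table (`region`, `vegetation`, `r_days`); an error names
#'   any missing region x vegetation cell.
#' @param vegetation optional replacement vegetation raster (must match the
#'   one used for prediction).
#' @return a `density_surface` in individuals/km^2.
#' @export
nests_to_individuals <- function(surface, landscape,
                                 production = 1.09,
                                 decay = synthetic_decay_table(),
                                 vegetation = NULL) {
  stopifnot(surface$unit == "nests/km2", production > 0, all(decay$r_days > 0))
  key <- paste(as.character(surface$frame$region), as.character(surface$frame$vegetation))
  idx <- match(key, paste(decay$region, decay$vegetation))
  if (anyNA(idx))
    stop("decay table is missing region x vegetation cell(s): ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  f <- 1 / (production * decay$r_days[idx])
  d <- dim(surface$mean$values)
  out <- surface
  out$mean <- grid_raster(matrix(as.vector(surface$mean$values) * f, d[1], d[2]),
                          surface$mean$origin, surface$mean$cellsize)
  out$sd <- grid_raster(matrix(as.vector(surface$sd$values) * f, d[1], d[2]),
                        surface$sd$origin, surface$sd$cellsize)
  out$conversion <- surface$conversion * f
  out$unit <- "individuals/km2"
  out
}

#' Combine detection and spatial-model uncertainty
#'
#' First-order (delta method) combination of independent coefficients of
#' variation: CV_total = sqrt(CV_detection^2 + CV_gam^2).
#'
#' @param cv_gam,cv_detection non-negative CVs.
#' @return combined CV.
#' @export
propagate_uncertainty <- function(cv_gam, cv_detection = 0) {
  stopifnot(all(cv_gam >= 0), all(cv_detection >= 0))
  sqrt(cv_gam^2 + cv_detection^2)
}

# delta-method variance of sum(weights * area * exp(eta)) over masked cells;
# the full-grid lp matrix is computed once per surface and cached
abundance_variance <- function(surface, cells) {
  g <- surface$model$gam
  if (is.null(surface$cache$X))
    surface$cache$X <- stats::predict(g, newdata = surface$frame, type = "lpmatrix")
  X <- surface$cache$X[cells, , drop = FALSE]
  mu <- as.vector(surface$mean$values)[cells] * surface$cell_km2  # cell totals
  dNdb <- drop(mu %*% X)
  drop(dNdb %*% g$Vp %*% dNdb)
}

#' Stratum abundance with a lognormal confidence interval
#'
#' Abundance is the sum of cell density times cell area over the stratum
#' mask. The GAM CV comes from the delta method on the summed surface using
#' the coefficient covariance; detection uncertainty is folded in via
#' [propagate_uncertainty()] and the interval is lognormal on the total
#' (standard distance-sampling practice).
#'
#' @param surface a `density_surface` (either unit).
#' @param mask logical matrix/`grid_raster` selecting stratum cells; `NULL`
#'   for the whole grid.
#' @param cv_detection detection-function CV to fold in (default 0).
#' @param level confidence level (default 0.95).
#' @return list: `abundance`, `cv_gam`, `cv_total`, `lower`, `upper`,
#'   `area_km2`, `density` (mean over the stratum).
#' @export
stratum_abundance <- function(surface, mask = NULL, cv_detection = 0, level = 0.95) {
  vals <- as.vector(surface$mean$values)
  if (is.null(mask)) {
    cells <- seq_along(vals)
  } else {
    mv <- if (inherits(mask, "grid_raster")) mask$values else mask
    cells <- which(as.vector(mv) != 0)
  }
  if (!length(cells)) {
    warning("empty stratum mask")
    return(list(abundance = 0, cv_gam = NA_real_, cv_total = NA_real_,
                lower = 0, upper = 0, area_km2 = 0, density = NA_real_))
  }
  area <- length(cells) * surface$cell_km2
  N <- sum(vals[cells]) * surface$cell_km2
  v <- abundance_variance(surface, cells)
  cv_gam <- if (N > 0) sqrt(v) / N else NA_real_
  cv_tot <- propagate_uncertainty(cv_gam, cv_detection)
  z <- stats::qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log(1 + cv_tot^2)))
  list(abundance = N, cv_gam = cv_gam, cv_total = cv_tot,
       lower = N / C, upper = N * C, area_km2 = area, density = N / area)
}

#' Annual multiplicative trend from a yearly abundance series
#'
#' Default method: least-squares slope b of log N on year, annual rate
#' (e^b - 1) * 100%, total change over the span by geometric composition.
#' Alternative: mean year-over-year change (gap years enter as the geometric
#' per-year mean across the gap). The method tag is always recorded.
#'
#' @param abundance data.frame with `year` and `abundance` (>= 3 years, > 0).
#' @param method `"loglinear"` (default) or `"meanchange"`.
#' @param level confidence level for the loglinear rate CI.
#' @return list of class `trend_estimate`: `annual_rate_pct`,
#'   `total_change_pct`, `span_years`, `method`, and for the default method a
#'   CI on the annual rate.
#' @export
annual_trend <- function(abundance, method = c("loglinear", "meanchange"),
                         level = 0.95) {
  method <- match.arg(method)
  stopifnot(nrow(abundance) >= 3)
  if (any(abundance$abundance <= 0)) stop("nonpositive abundance in trend series")
  yr <- abundance$year
  span <- max(yr) - min(yr)
  if (method == "loglinear") {
    fit <- stats::lm(log(abundance$abundance) ~ yr)
    b <- stats::coef(fit)[[2]]
    # exactly geometric series fit perfectly; the summary warning is benign
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    z <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
    rate <- (exp(b) - 1) * 100
    ci <- (exp(b + c(-1, 1) * z * se) - 1) * 100
  } else {
    o <- order(yr)
    yr_o <- yr[o]; n_o <- abundance$abundance[o]
    per_yr <- (n_o[-1] / n_o[-length(n_o)])^(1 / diff(yr_o)) - 1
    rate <- mean(per_yr) * 100
    b <- log(1 + rate / 100)
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(
    annual_rate_pct = rate,
    total_change_pct = (exp(b * span) - 1) * 100,
    ci_pct = ci, span_years = span, method = method
  ), class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("<trend_estimate> %+.2f%% / yr (%s), %+.2f%% over %d yr\n",
              x$annual_rate_pct, x$method, x$total_change_pct, x$span_years))
  if (!anyNA(x$ci_pct))
    cat(sprintf("  CI: %+.2f%% to %+.2f%% / yr\n", x$ci_pct[1], x$ci_pct[2]))
  invisible(x)
}

#' Habitat trend from a yearly series of vegetation rasters
#'
#' Class areas per year, with the annual rate per class estimated by
#' [annual_trend()]. Under one-way tree-cover-loss inputs, an increase in
#' forest or woodland area between consecutive years is a consistency error.
#'
#' @param veg_rasters named list (by year) of categorical vegetation rasters
#'   on a shared grid.
#' @param one_way enforce the one-way loss consistency check (default TRUE).
#' @param method trend method, see [annual_trend()].
#' @return list with `areas` (data.frame year x class areas, km^2) and
#'   `trends` (list of `trend_estimate` per class).
#' @export
habitat_trend <- function(veg_rasters, one_way = TRUE, method = "loglinear") {
  years <- as.numeric(names(veg_rasters))
  stopifnot(!anyNA(years))
  d1 <- dim(veg_rasters[[1]]$values)
  cell_km2 <- (veg_rasters[[1]]$cellsize / 1000)^2
  areas <- do.call(rbind, lapply(seq_along(years), function(i) {
    v <- veg_rasters[[i]]
    stopifnot(identical(dim(v$values), d1))
    counts <- tabulate(as.vector(v$values), nbins = 3)
    data.frame(year = years[i], forest = counts[1] * cell_km2,
               woodland = counts[2] * cell_km2, nonforest = counts[3] * cell_km2)
  }))
  if (one_way) {
    for (cls in c("forest", "woodland")) {
      if (any(diff(areas[[cls]][order(areas$year)]) > 1e-9))
        stop(cls, " area increases between consecutive years: inconsistent with one-way loss inputs")
    }
  }
  trends <- lapply(c("forest", "woodland", "nonforest"), function(cls) {
    a <- data.frame(year = areas$year, abundance = areas[[cls]])
    if (all(a$abundance > 0)) annual_trend(a, method = method) else NULL
  })
  names(trends) <- c("forest", "woodland", "nonforest")
  list(areas = areas, trends = trends)
}

#' Read conservation-planning polygons from GeoJSON
#'
#' Minimal reader for Polygon / MultiPolygon features in the grid's projected
#' CRS; only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file.
#' @return named list of data.frames with columns `x`, `y`.
#' @export
read_cap_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    nm <- f$properties$name
    if (is.null(nm)) nm <- paste0("area_", i)
    geom <- f$geometry
    ring <- switch(geom$type,
                   Polygon = geom$coordinates[[1]],
                   MultiPolygon = geom$coordinates[[1]][[1]],
                   stop("unsupported geometry type: ", geom$type))
    out[[nm]] <- data.frame(
      x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
      y = vapply(ring, function(p) as.numeric(p[[2]]), 0)
    )
  }
  out
}

#' Summarize predicted density within planning areas over time
#'
#' For each polygon and each year's surface: the mean of cell mean densities
#' and the mean of cell SDs over the cells whose centres fall inside the
#' polygon. Polygons containing no cell centre yield an empty (NA) summary
#' with a warning.
#'
#' @param surfaces named list (by year) of `density_surface`s on one grid.
#' @param polygons named list of polygon data.frames (`x`, `y`), e.g. from
#'   [read_cap_geojson()].
#' @return data.frame with columns `area`, `year`, `mean_density`, `mean_sd`,
#'   `n_cells`.
#' @export
cap_area_summary <- function(surfaces, polygons) {
  xy <- raster_xy(surfaces[[1]]$mean)
  out <- list()
  for (nm in names(polygons)) {
    poly <- polygons[[nm]]
    inside <- pracma::inpolygon(xy$x, xy$y, poly$x, poly$y)
    if (!any(inside)) warning("polygon '", nm, "' contains no grid cell centre")
    for (yr in names(surfaces)) {
      s <- surfaces[[yr]]
      out[[length(out) + 1L]] <- data.frame(
        area = nm, year = as.numeric(yr),
        mean_density = if (any(inside)) mean(as.vector(s$mean$values)[inside]) else NA_real_,
        mean_sd = if (any(inside)) mean(as.vector(s$sd$values)[inside]) else NA_real_,
        n_cells = sum(inside)
      )
    }
  }
  do.call(rbind, out)
}

#' Vegetation stratum mask from a landscape
#'
#' @param landscape a `nest_landscape`.
#' @param class vegetation class name.
#' @param vegetation optional replacement vegetation raster.
#' @return logical matrix mask.
#' @export
stratum_mask <- function(landscape, class, vegetation = NULL) {
  veg <- if (is.null(vegetation)) landscape$vegetation else vegetation
  veg$values == match(class, veg_levels())
}
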