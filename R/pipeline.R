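#' Run the full two-stage density surface pipeline on synthetic surveys
#'
#' Simulates one standing-crop nest survey per year on a common synthetic
#' landscape, then runs the complete analysis: truncation selection (optional),
#' covariate detection-function fitting and AIC selection, segment table
#' construction with detectability offsets, count-GAM fitting (negative
#' binomial by default, optionally compared against Tweedie), per-year grid
#' prediction, conversion to weaned-individual densities, per-stratum
#' abundances with lognormal CIs, and annual population trends.
#'
#' @param truth a `truth_params`.
#' @param landscape a `nest_landscape`; default generates a 50 x 50 km grid.
#' @param w strip half-width used in the field (m).
#' @param select_w run [select_truncation()] over `w_candidates` instead of
#'   using `w` directly for analysis truncation.
#' @param w_candidates candidate truncation distances (m).
#' @param design survey design type, see [simulate_survey()].
#' @param site_pool number of survey sites laid out once per run; sites are
#'   revisited across years (rotating panel), so year effects are identified
#'   from repeated sites while the pool spreads effort over the landscape.
#' @param sites_per_year number of pool sites surveyed in each year.
#' @param block_km edge (km) of each parallel-design survey site.
#' @param forest_sites how many pool sites are centred on forest cells, see
#'   [simulate_survey()].
#' @param compare_tweedie also fit the Tweedie family and select by AIC /
#'   deviance explained (slower; default FALSE uses negative binomial).
#' @param formula optional GAM formula override.
#' @param seed master seed; all per-year simulation seeds derive from it.
#' @return list with every intermediate product: `landscape`, `surveys`,
#'   `detection`, `truncation`, `segments`, `model`, `surfaces`
#'   (individuals/km^2, by year), `abundance` (stratum x year table with CIs),
#'   `trends` (per stratum and landscape-wide `trend_estimate`s).
#' @export
run_dsm_pipeline <- function(truth = truth_params(),
                             landscape = NULL,
                             w = 50, select_w = FALSE,
                             w_candidates = c(30, 40, 50, 60),
                             design = "parallel", site_pool = 24,
                             sites_per_year = 24, block_km = 2,
                             forest_sites = 6,
                             compare_tweedie = FALSE,
                             formula = NULL,
                             seed = 1) {
  if (is.null(landscape))
    landscape <- generate_landscape(nx = 50, ny = 50, cellsize = 1000, seed = seed)

  pool <- survey_design(landscape, design, block_km = block_km,
                        n_blocks = site_pool, forest_sites = forest_sites,
                        seed = seed)
  years <- truth$years
  transects <- list(); observations <- list()
  for (i in seq_along(years)) {
    sy <- seed * 1000L + i
    set.seed(sy)
    sites_y <- sample(unique(pool$site), min(sites_per_year, length(unique(pool$site))))
    tr_y <- pool[pool$site %in% sites_y, , drop = FALSE]
    nests <- simulate_nest_field(landscape, truth, years[i], seed = sy)
    sv <- simulate_survey(landscape, nests, design = design, w = w,
                          sigma = truth$sigma, seed = sy, transects = tr_y)
    sv$transects$transect_id <- paste0(years[i], "-", sv$transects$transect_id)
    if (nrow(sv$observations))
      sv$observations$transect_id <- paste0(years[i], "-", sv$observations$transect_id)
    transects[[i]] <- sv$transects
    observations[[i]] <- sv$observations
  }
  transects <- do.call(rbind, transects)
  observations <- do.call(rbind, observations)

  trunc <- NULL
  w_fit <- w
  if (select_w) {
    trunc <- select_truncation(observations, w_candidates)
    w_fit <- min(trunc$w, w)     # cannot truncate beyond the surveyed strip
  }
  obs_t <- observations[observations$distance_m <= w_fit, , drop = FALSE]

  candidates <- list(
    fit_detection(obs_t, key = "hn", w = w_fit),
    fit_detection(obs_t, key = "hn", covariate = "vegetation", w = w_fit),
    fit_detection(obs_t, key = "hr", w = w_fit),
    fit_detection(obs_t, key = "hn", n_adjustments = 2, w = w_fit)
  )
  detection <- select_detection_model(candidates)

  cv_det <- if (is.finite(detection$cv)) detection$cv else 0
  segments <- build_segment_table(transects, obs_t, landscape, w_fit,
                                  detection = detection)
  if (is.null(formula)) formula <- dsm_formula(segments)
  model_nb <- fit_dsm(segments, family = "nb", formula = formula)
  model <- if (compare_tweedie) {
    model_tw <- tryCatch(fit_dsm(segments, family = "tweedie", formula = formula),
                         error = function(e) NULL)
    select_family(model_nb, model_tw)
  } else model_nb

  surfaces <- list()
  abundance <- list()
  for (i in seq_along(years)) {
    s_nest <- predict_surface(model, landscape, years[i])
    s_ind <- nests_to_individuals(s_nest, landscape,
                                  production = truth$nest_production,
                                  decay = truth$decay_table)
    surfaces[[as.character(years[i])]] <- s_ind
    for (cls in c(veg_levels(), "all")) {
      mask <- if (cls == "all") NULL else stratum_mask(landscape, cls)
      ab <- stratum_abundance(s_ind, mask, cv_detection = cv_det)
      abundance[[length(abundance) + 1L]] <- data.frame(
        year = years[i], stratum = cls, abundance = ab$abundance,
        density = ab$density, cv_gam = ab$cv_gam, cv_total = ab$cv_total,
        lower = ab$lower, upper = ab$upper, area_km2 = ab$area_km2
      )
    }
  }
  abundance <- do.call(rbind, abundance)

  trends <- lapply(c(veg_levels(), "all"), function(cls) {
    a <- abundance[abundance$stratum == cls, c("year", "abundance")]
    if (all(a$abundance > 0)) annual_trend(a) else NULL
  })
  names(trends) <- c(veg_levels(), "all")

  list(landscape = landscape, truth = truth,
       surveys = list(transects = transects, observations = observations),
       truncation = trunc, detection = detection,
       segments = segments, model = model,
       surfaces = surfaces, abundance = abundance, trends = trends,
       w = w_fit, seed = seed)
}

#' True stratum abundance of weaned individuals in a given year
#'
#' Ground truth for recovery checks: the generator's expected individual
#' density summed over the stratum cells.
#'
#' @param landscape a `nest_landscape`.
#' @param truth a `truth_params`.
#' @param year year.
#' @param class vegetation class, or `"all"`.
#' @return abundance (individuals).
#' @export
true_abundance <- function(landscape, truth, year, class = "all") {
  dens <- true_density_raster(landscape, truth, year)
  cell_km2 <- (landscape$cellsize / 1000)^2
  sel <- if (class == "all") TRUE else stratum_mask(landscape, class)
  sum(dens$values[sel]) * cell_km2
}

#' Write a simulated survey run to disk
#'
#' Observation and transect tables as CSV, landscape rasters as ESRI ASCII
#' grids, the truth configuration as JSON, and a manifest recording the seed.
#'
#' @param dir output directory (created if needed).
#' @param transects,observations survey tables.
#' @param landscape a `nest_landscape`.
#' @param truth a `truth_params`.
#' @param seed the master seed of the run.
#' @return `dir`, invisibly.
#' @export
write_survey_run <- function(dir, transects, observations, landscape, truth, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(transects, file.path(dir, "transects.csv"), row.names = FALSE)
  utils::write.csv(observations, file.path(dir, "observations.csv"), row.names = FALSE)
  for (nm in c("vegetation", "region", "temp_range", "elevation", "slope",
               "hpd", "dist_forest", "dist_slope"))
    write_asc(landscape[[nm]], file.path(dir, paste0(nm, ".asc")))
  cfg <- truth
  cfg$decay_table <- as.list(cfg$decay_table)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(
    list(seed = seed, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         n_transects = nrow(transects), n_observations = nrow(observations)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
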