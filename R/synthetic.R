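#' Ground-truth parameters for the synthetic study system
#'
#' Bundles everything the generators need: stratum baseline densities of weaned
#' individuals, the known multiplicative annual decline, vegetation-dependent
#' detection scale, nest production and decay rates, clustering of the nest
#' point process, and annual habitat-loss rates. The defaults describe a
#' savanna--woodland mosaic with a small riparian forest fraction holding most
#' of the density, a 2.4%/yr population decline, and detectability falling
#' with vegetation openness -- the regime the pipeline is designed to recover.
#'
#' @param baseline_density named numeric, weaned individuals / km^2 per
#'   vegetation class in the first year (`forest`, `woodland`, `nonforest`).
#' @param annual_change named numeric, multiplicative change in density per
#'   year per vegetation class (0.976 = -2.4%/yr).
#' @param sigma named numeric, half-normal detection scale (m) per class.
#' @param nest_production nests built per weaned individual per day
#'   (`t` of the nest-count conversion; 1.09 by default).
#' @param decay_table mean nest lifetime table, see [synthetic_decay_table()].
#' @param parent_intensity Thomas-process parent intensity (parents / km^2).
#' @param offspring_sd Thomas-process offspring displacement SD (m).
#' @param years survey years (one standing-crop survey per year; default is a
#'   ten-survey series spanning 2010--2020 with a gap year in 2016).
#' @param habitat_loss named numeric, annual fraction of remaining forest and
#'   woodland reclassified to nonforest (one-way tree-cover loss).
#' @return a list of class `truth_params`.
#' @export
truth_params <- function(baseline_density = c(forest = 0.9, woodland = 0.2, nonforest = 0.15),
                         annual_change = c(forest = 0.976, woodland = 0.976, nonforest = 0.976),
                         sigma = c(forest = 17, woodland = 20, nonforest = 23),
                         nest_production = 1.09,
                         decay_table = synthetic_decay_table(),
                         parent_intensity = 8,
                         offspring_sd = 150,
                         years = c(2010:2015, 2017:2020),
                         habitat_loss = c(forest = 0.0136, woodland = 0.0032)) {
  veg <- veg_levels()
  stopifnot(all(veg %in% names(baseline_density)),
            all(baseline_density >= 0),
            all(sigma > 0), nest_production > 0,
            parent_intensity > 0, offspring_sd > 0)
  structure(list(
    baseline_density = baseline_density[veg],
    annual_change = annual_change[veg],
    sigma = sigma[veg],
    nest_production = nest_production,
    decay_table = decay_table,
    parent_intensity = parent_intensity,
    offspring_sd = offspring_sd,
    years = sort(years),
    habitat_loss = habitat_loss
  ), class = "truth_params")
}

#' Synthetic nest decay table (mean nest lifetime, days)
#'
#' Mean days a nest remains countable, stratified by region (lakeshore vs
#' inland) and vegetation class. These are SYNTHETIC defaults for simulation
#' and worked examples, not field measurements: values sit near the ~100-day
#' leaf-decomposition longevity reported for this ecosystem, with slightly
#' faster decay on the wetter lakeshore. Field analyses should supply their
#' own measured table via the `decay` argument of the conversion functions.
#'
#' @param lakeshore,inland named numeric, days per vegetation class.
#' @return data.frame with columns `region`, `vegetation`, `r_days`, `source`.
#' @export
synthetic_decay_table <- function(lakeshore = c(forest = 90, woodland = 95, nonforest = 105),
                                  inland = c(forest = 106, woodland = 112, nonforest = 124)) {
  veg <- veg_levels()
  data.frame(
    region = rep(region_levels(), each = 3),
    vegetation = rep(veg, 2),
    r_days = c(lakeshore[veg], inland[veg]),
    source = "synthetic-default",
    row.names = NULL
  )
}

# standardized Gaussian random field: white noise blurred by a separable
# Gaussian kernel (edge-replicated), rescaled to mean 0 / sd 1
smooth_field <- function(nrow, ncol, range_cells = 3) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (range_cells > 0) {
    half <- max(1L, ceiling(3 * range_cells))
    k <- stats::dnorm(-half:half, sd = range_cells)
    k <- k / sum(k)
    pad_conv <- function(v) {
      vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
      stats::convolve(vp, rev(k), type = "filter")
    }
    z <- apply(z, 2, pad_conv)
    z <- t(apply(z, 1, pad_conv))
  }
  (z - mean(z)) / stats::sd(z)
}

rescale <- function(z, lo, hi) {
  r <- range(z)
  if (diff(r) == 0) return(rep((lo + hi) / 2, length(z)))
  lo + (z - r[1]) / diff(r) * (hi - lo)
}

#' Generate a synthetic landscape
#'
#' Builds a vegetation mosaic (forest / woodland / nonforest) by thresholding
#' a smoothed Gaussian field at the quantiles implied by the target class
#' proportions, so realized class shares match the targets up to discreteness.
#' Environmental covariates (annual temperature range, elevation, slope, human
#' population density) are independent smooth fields on realistic scales;
#' slope is the rescaled gradient magnitude of elevation. Distance-to-forest
#' and distance-to-steep-slope layers are exact Euclidean distance transforms.
#' The lakeshore region is the band of cells within `lakeshore_width` of the
#' western grid edge (the lake boundary of the study system).
#'
#' @param nx,ny grid dimensions (columns = easting, rows = northing), >= 10.
#' @param cellsize cell size in metres (default 1 km cells).
#' @param proportions target vegetation shares (forest, woodland, nonforest);
#'   must sum to 1 within 1e-9. Defaults 6/71/23%.
#' @param lakeshore_width width of the lakeshore band (m) from the west edge.
#' @param steep_threshold slope (degrees) above which a cell is "steep".
#' @param patch_range correlation range of the vegetation field, in cells.
#' @param seed integer seed; the same seed reproduces the landscape bitwise.
#' @return a list of class `nest_landscape` with `grid_raster` layers
#'   `vegetation`, `region`, `temp_range`, `elevation`, `slope`, `hpd`,
#'   `dist_forest`, `dist_slope`, plus grid metadata.
#' @export
generate_landscape <- function(nx = 50, ny = 50, cellsize = 1000,
                               proportions = c(forest = 0.06, woodland = 0.71, nonforest = 0.23),
                               lakeshore_width = 5000,
                               steep_threshold = 20,
                               patch_range = 3,
                               seed = 1) {
  if (nx < 10 || ny < 10) stop("grid dimensions must be at least 10 x 10")
  veg <- veg_levels()
  proportions <- proportions[veg]
  if (anyNA(proportions) || abs(sum(proportions) - 1) > 1e-9)
    stop("vegetation proportions must be named forest/woodland/nonforest and sum to 1")
  set.seed(seed)

  z <- smooth_field(ny, nx, patch_range)
  # high field values -> forest (riparian strips), low -> nonforest
  q <- stats::quantile(z, c(proportions["nonforest"],
                            proportions["nonforest"] + proportions["woodland"]))
  vm <- matrix(2L, ny, nx)                      # woodland
  vm[z <= q[1]] <- 3L                           # nonforest
  if (proportions["forest"] > 0) vm[z > q[2]] <- 1L  # forest
  if (proportions["forest"] == 1) vm[] <- 1L
  if (proportions["nonforest"] == 1) vm[] <- 3L

  elev <- matrix(rescale(smooth_field(ny, nx, 5), 900, 2500), ny, nx)
  gx <- cbind(elev[, -1] - elev[, -nx], 0) / cellsize
  gy <- rbind(elev[-1, ] - elev[-ny, ], 0) / cellsize
  slope <- matrix(rescale(sqrt(gx^2 + gy^2), 0, 35), ny, nx)
  temp_range <- matrix(rescale(smooth_field(ny, nx, 6), 13, 21), ny, nx)
  hpd <- matrix(exp(rescale(smooth_field(ny, nx, 4), log(0.5), log(300))), ny, nx)

  xy0 <- c(0, 0)
  xs <- xy0[1] + (matrix(rep(seq_len(nx), each = ny), ny, nx) - 0.5) * cellsize
  region <- matrix(ifelse(xs <= xy0[1] + lakeshore_width, 1L, 2L), ny, nx)

  land <- list(
    nx = nx, ny = ny, cellsize = cellsize, origin = xy0,
    steep_threshold = steep_threshold, seed = seed,
    vegetation = grid_raster(vm, xy0, cellsize, veg),
    region = grid_raster(region, xy0, cellsize, region_levels()),
    temp_range = grid_raster(temp_range, xy0, cellsize),
    elevation = grid_raster(elev, xy0, cellsize),
    slope = grid_raster(slope, xy0, cellsize),
    hpd = grid_raster(hpd, xy0, cellsize)
  )
  dl <- compute_distance_layers(land)
  land$dist_forest <- dl$dist_forest
  land$dist_slope <- dl$dist_slope
  class(land) <- "nest_landscape"
  land
}

#' @export
print.nest_landscape <- function(x, ...) {
  cat(sprintf("<nest_landscape> %d x %d cells of %.0f m (%.0f km^2)\n",
              x$ny, x$nx, x$cellsize, x$nx * x$ny * (x$cellsize / 1000)^2))
  sh <- prop.table(table(factor(veg_levels()[x$vegetation$values], veg_levels())))
  cat("  vegetation:", paste(sprintf("%s %.0f%%", names(sh), 100 * sh), collapse = ", "), "\n")
  invisible(x)
}

# per-cell true density of weaned individuals (ind / km^2) in a given year
true_density_raster <- function(landscape, truth, year) {
  dy <- year - truth$years[1]
  d0 <- truth$baseline_density[landscape$vegetation$values]
  ch <- truth$annual_change[landscape$vegetation$values]
  grid_raster(matrix(d0 * ch^dy, landscape$ny, landscape$nx),
              landscape$origin, landscape$cellsize)
}

# mean nest lifetime (days) per cell from a region x vegetation decay table
decay_raster <- function(landscape, decay_table) {
  key <- paste(region_levels()[landscape$region$values],
               veg_levels()[landscape$vegetation$values])
  tab_key <- paste(decay_table$region, decay_table$vegetation)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("decay table is missing region x vegetation cell(s): ",
         paste(miss, collapse = "; "))
  }
  grid_raster(matrix(decay_table$r_days[idx], landscape$ny, landscape$nx),
              landscape$origin, landscape$cellsize)
}

#' Simulate a standing-crop nest field
#'
#' Generates the nests present on the landscape at survey time in a given
#' year. The cell-wise expected nest count is `D_ind * t * r * A`: individual
#' density times nest production rate times mean nest lifetime (region- and
#' vegetation-specific) times cell area. Spatial clustering follows a Thomas
#' process (Poisson parents, Gaussian-displaced offspring) made inhomogeneous
#' by location-dependent thinning, which preserves the cell-wise expectation
#' while producing the overdispersed segment counts seen in real surveys.
#' Parents are generated in a buffered window so the offspring process has no
#' edge deficit.
#'
#' @param landscape a `nest_landscape`.
#' @param truth a `truth_params`.
#' @param year survey year, within `truth$years`.
#' @param seed integer seed.
#' @return data.frame of nests with columns `x`, `y`, `vegetation`, `year`.
#' @export
simulate_nest_field <- function(landscape, truth, year, seed = 1) {
  if (year < min(truth$years) || year > max(truth$years))
    stop("year outside the configured survey span")
  set.seed(seed)
  dens <- true_density_raster(landscape, truth, year)
  r <- decay_raster(landscape, truth$decay_table)
  lambda <- dens$values * truth$nest_production * r$values   # nests / km^2
  lmax <- max(lambda)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      vegetation = factor(character(0), veg_levels()),
                      year = numeric(0))
  if (lmax == 0) return(empty)

  cs <- landscape$cellsize
  buf <- 4 * truth$offspring_sd
  x0 <- landscape$origin[1] - buf; x1 <- landscape$origin[1] + landscape$nx * cs + buf
  y0 <- landscape$origin[2] - buf; y1 <- landscape$origin[2] + landscape$ny * cs + buf
  area_buf <- (x1 - x0) * (y1 - y0) / 1e6                    # km^2
  n_par <- stats::rpois(1, truth$parent_intensity * area_buf)
  if (n_par == 0) return(empty)
  px <- stats::runif(n_par, x0, x1)
  py <- stats::runif(n_par, y0, y1)
  mu <- lmax / truth$parent_intensity                        # offspring per parent
  n_off <- stats::rpois(n_par, mu)
  tot <- sum(n_off)
  if (tot == 0) return(empty)
  ox <- rep(px, n_off) + stats::rnorm(tot, 0, truth$offspring_sd)
  oy <- rep(py, n_off) + stats::rnorm(tot, 0, truth$offspring_sd)
  inside <- ox > landscape$origin[1] & ox < landscape$origin[1] + landscape$nx * cs &
            oy > landscape$origin[2] & oy < landscape$origin[2] + landscape$ny * cs
  ox <- ox[inside]; oy <- oy[inside]
  lam_pt <- raster_extract(grid_raster(lambda, landscape$origin, cs), ox, oy)
  keep <- stats::runif(length(ox)) < lam_pt / lmax
  ox <- ox[keep]; oy <- oy[keep]
  data.frame(
    x = ox, y = oy,
    vegetation = raster_extract(landscape$vegetation, ox, oy),
    year = year
  )
}

# ---- survey designs ----------------------------------------------------

# vertical parallel lines at `spacing` within one or more square blocks;
# the first `forest_sites` blocks are centred on random forest cells
# (surveys target areas of known presence), the rest are uniform
design_parallel <- function(landscape, spacing, block_km, n_blocks,
                            forest_sites = 0) {
  cs <- landscape$cellsize
  W <- landscape$nx * cs; H <- landscape$ny * cs
  bl <- block_km * 1000
  fcells <- which(landscape$vegetation$values == 1L, arr.ind = TRUE)
  forest_sites <- if (nrow(fcells)) min(forest_sites, n_blocks) else 0
  out <- list()
  for (b in seq_len(n_blocks)) {
    if (b <= forest_sites) {
      i <- fcells[sample.int(nrow(fcells), 1), ]
      bx <- min(max((i[["col"]] - 0.5) * cs - bl / 2, 0), W - bl)
      by <- min(max((i[["row"]] - 0.5) * cs - bl / 2, 0), H - bl)
    } else {
      bx <- stats::runif(1, 0, max(W - bl, 0))
      by <- stats::runif(1, 0, max(H - bl, 0))
    }
    off <- stats::runif(1, 0, spacing)
    xs <- seq(bx + off, bx + min(bl, W - bx), by = spacing)
    if (!length(xs)) next
    out[[b]] <- data.frame(site = b, x0 = xs, y0 = by,
                           x1 = xs, y1 = by + min(bl, H - by))
  }
  do.call(rbind, out)
}

# short transects on a systematic grid with a random start
design_systematic <- function(landscape, grid_spacing, transect_km) {
  cs <- landscape$cellsize
  W <- landscape$nx * cs; H <- landscape$ny * cs
  tl <- transect_km * 1000
  sx <- stats::runif(1, 0, grid_spacing); sy <- stats::runif(1, 0, grid_spacing)
  if (sx > W || sy > H) return(NULL)
  g <- expand.grid(x = seq(sx, W, by = grid_spacing),
                   y = seq(sy, H, by = grid_spacing))
  g <- g[g$y + tl <= H, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  data.frame(site = seq_len(nrow(g)), x0 = g$x, y0 = g$y, x1 = g$x, y1 = g$y + tl)
}

# four cardinal arms from random central points
design_radial <- function(landscape, n_centers, arm_km) {
  cs <- landscape$cellsize
  W <- landscape$nx * cs; H <- landscape$ny * cs
  al <- arm_km * 1000
  cx <- stats::runif(n_centers, al, W - al)
  cy <- stats::runif(n_centers, al, H - al)
  do.call(rbind, lapply(seq_len(n_centers), function(i) {
    data.frame(site = i,
               x0 = c(cx[i], cx[i], cx[i], cx[i] - al),
               y0 = c(cy[i], cy[i] - al, cy[i], cy[i]),
               x1 = c(cx[i], cx[i], cx[i] + al, cx[i]),
               y1 = c(cy[i] + al, cy[i], cy[i], cy[i]))
  }))
}

#' Lay out a line-transect survey design
#'
#' Generates transect geometry under one of three designs without simulating
#' any detection: parallel lines spaced `spacing` apart within `n_blocks`
#' random square survey sites; a systematic-random grid of short transects;
#' or radial arms from random central points. The `site` column groups
#' transects belonging to one survey site, so callers can revisit a fixed
#' site pool across years (rotating-panel monitoring).
#'
#' @inheritParams simulate_survey
#' @return data.frame with `transect_id`, `site`, endpoints `x0`,`y0`,`x1`,
#'   `y1` (m) and `length_km`.
#' @export
survey_design <- function(landscape, design = c("parallel", "systematic", "radial"),
                          spacing = 500, block_km = 5, n_blocks = 4,
                          forest_sites = 0,
                          grid_spacing = 4000, transect_km = 0.7,
                          n_centers = 3, arm_km = 2, seed = 1) {
  design <- match.arg(design)
  set.seed(seed)
  tr <- switch(design,
    parallel = design_parallel(landscape, spacing, block_km, n_blocks, forest_sites),
    systematic = design_systematic(landscape, grid_spacing, transect_km),
    radial = design_radial(landscape, n_centers, arm_km))
  if (is.null(tr) || nrow(tr) == 0) stop("survey design produced zero transects")
  tr$transect_id <- sprintf("%s-%03d", design, seq_len(nrow(tr)))
  tr$length_km <- sqrt((tr$x1 - tr$x0)^2 + (tr$y1 - tr$y0)^2) / 1000
  tr[, c("transect_id", "site", "x0", "y0", "x1", "y1", "length_km")]
}

#' Simulate a line-transect survey over a nest field
#'
#' Lays out transects under one of three designs (parallel lines spaced 0.5 km
#' within survey blocks; a systematic-random grid of short transects; radial
#' arms from central points), then detects each nest lying within the strip
#' half-width `w` of a transect independently with half-normal probability
#' `exp(-d^2 / (2 sigma_veg^2))` of its true perpendicular distance `d`.
#' Recorded distances are exact unless a zero-rounding contamination is
#' requested (`round_zero_frac`), which mimics field heaping of near-line
#' detections at distance zero.
#'
#' @param landscape a `nest_landscape`.
#' @param nests nest data.frame from [simulate_nest_field()].
#' @param design `"parallel"`, `"systematic"` or `"radial"`.
#' @param w strip half-width (m).
#' @param sigma detection scale(s) in metres: named per vegetation class, or a
#'   single value; `Inf` gives certain detection within the strip.
#' @param spacing parallel-line spacing (m), default 500.
#' @param block_km,n_blocks parallel design: block edge (km) and block count.
#' @param forest_sites parallel design: how many blocks are centred on random
#'   forest cells instead of placed uniformly (surveys in this system target
#'   areas of known ape presence, so rare riparian forest is represented).
#' @param grid_spacing,transect_km systematic design: grid step (m), length (km).
#' @param n_centers,arm_km radial design: number of centres and arm length (km).
#' @param round_zero_frac fraction of detections whose recorded distance is
#'   rounded to zero (default 0 = exact distances).
#' @param seed integer seed (same seed, same survey).
#' @param design_seed optional separate seed for the transect layout; passing
#'   the same `design_seed` with different `seed`s re-surveys a fixed set of
#'   monitoring sites (the layout is reproduced, detection randomness varies),
#'   as in long-term monitoring programmes.
#' @param transects optional precomputed transect table (from
#'   [survey_design()], possibly subset to this year's sites); when supplied
#'   the design arguments are ignored and only detection is simulated.
#' @return list with `transects` (id, endpoints, length_km, year) and
#'   `observations` (one row per detected nest: `distance_m`, `transect_id`,
#'   `chainage_km` along the transect, coordinates, `vegetation`, `year`).
#' @export
simulate_survey <- function(landscape, nests, design = c("parallel", "systematic", "radial"),
                            w = 50,
                            sigma = c(forest = 17, woodland = 20, nonforest = 23),
                            spacing = 500, block_km = 5, n_blocks = 4,
                            forest_sites = 0,
                            grid_spacing = 4000, transect_km = 0.7,
                            n_centers = 3, arm_km = 2,
                            round_zero_frac = 0, seed = 1, design_seed = NULL,
                            transects = NULL) {
  design <- match.arg(design)
  if (is.null(transects)) {
    tr <- survey_design(landscape, design, spacing = spacing,
                        block_km = block_km, n_blocks = n_blocks,
                        forest_sites = forest_sites,
                        grid_spacing = grid_spacing, transect_km = transect_km,
                        n_centers = n_centers, arm_km = arm_km,
                        seed = if (is.null(design_seed)) seed else design_seed)
  } else {
    tr <- transects
    if (!nrow(tr)) stop("survey design produced zero transects")
  }
  set.seed(seed)
  yr <- if (nrow(nests)) nests$year[1] else NA_real_
  tr$year <- yr

  obs <- data.frame(distance_m = numeric(0), transect_id = character(0),
                    chainage_km = numeric(0), x = numeric(0), y = numeric(0),
                    vegetation = factor(character(0), veg_levels()),
                    year = numeric(0))
  if (nrow(nests)) {
    # nearest transect by perpendicular distance, projection constrained to
    # the segment; a nest can be detected from at most one transect
    best_d <- rep(Inf, nrow(nests)); best_t <- rep(NA_integer_, nrow(nests))
    best_s <- rep(NA_real_, nrow(nests))
    for (i in seq_len(nrow(tr))) {
      dx <- tr$x1[i] - tr$x0[i]; dy <- tr$y1[i] - tr$y0[i]
      L2 <- dx^2 + dy^2
      s <- ((nests$x - tr$x0[i]) * dx + (nests$y - tr$y0[i]) * dy) / L2
      on <- s >= 0 & s <= 1
      px <- tr$x0[i] + s * dx; py <- tr$y0[i] + s * dy
      d <- sqrt((nests$x - px)^2 + (nests$y - py)^2)
      upd <- on & d < best_d
      best_d[upd] <- d[upd]; best_t[upd] <- i
      best_s[upd] <- s[upd] * sqrt(L2) / 1000
    }
    in_strip <- which(best_d <= w)
    if (length(in_strip)) {
      vg <- as.character(nests$vegetation[in_strip])
      sg <- if (length(sigma) == 1 && is.null(names(sigma))) rep(sigma, length(in_strip))
            else unname(sigma[vg])
      p <- ifelse(is.infinite(sg), 1, exp(-best_d[in_strip]^2 / (2 * sg^2)))
      det <- in_strip[stats::runif(length(in_strip)) < p]
      if (length(det)) {
        dist_rec <- best_d[det]
        if (round_zero_frac > 0) {
          z <- stats::runif(length(det)) < round_zero_frac
          dist_rec[z] <- 0
        }
        obs <- data.frame(
          distance_m = dist_rec,
          transect_id = tr$transect_id[best_t[det]],
          chainage_km = best_s[det],
          x = nests$x[det], y = nests$y[det],
          vegetation = nests$vegetation[det],
          year = nests$year[det]
        )
        obs <- obs[order(obs$transect_id, obs$chainage_km), ]
        rownames(obs) <- NULL
      }
    }
  }
  list(transects = tr, observations = obs)
}

#' Apply one-way annual habitat loss to a vegetation raster
#'
#' Each year after the first, a fixed fraction of the *remaining* forest and
#' woodland cells is reclassified to nonforest (tree-cover loss is one-way;
#' no regrowth). Cell counts removed are rounded to the nearest whole cell,
#' locations are chosen at random.
#'
#' @param landscape a `nest_landscape`.
#' @param years vector of years; the first year keeps the original mosaic.
#' @param rates named annual loss fractions for `forest` and `woodland`.
#' @param seed integer seed.
#' @return named list (by year) of categorical vegetation `grid_raster`s.
#' @export
apply_habitat_loss <- function(landscape, years,
                               rates = c(forest = 0.0136, woodland = 0.0032),
                               seed = 1) {
  set.seed(seed)
  v <- landscape$vegetation$values
  out <- stats::setNames(vector("list", length(years)), years)
  for (k in seq_along(years)) {
    if (k > 1) {
      for (cls in c(forest = 1L, woodland = 2L)[c("forest", "woodland")]) {
        lab <- veg_levels()[cls]
        idx <- which(v == cls)
        n_rm <- round(rates[[lab]] * length(idx))
        if (n_rm > 0) v[sample(idx, n_rm)] <- 3L
      }
    }
    out[[k]] <- grid_raster(v, landscape$origin, landscape$cellsize, veg_levels())
  }
  out
}
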