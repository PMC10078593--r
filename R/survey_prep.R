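#' Split transects into equal segments
#'
#' Each transect of length L is divided into k = max(1, round(L / target))
#' equal segments (round-half-to-even, R's default rounding), so segment
#' lengths sit as close as possible to the target while always summing
#' exactly to the transect length. Segment midpoints lie on the transect line.
#'
#' @param transects data.frame with `transect_id`, `year`, `x0`, `y0`, `x1`,
#'   `y1`, `length_km`.
#' @param target_length target segment length (km), default 0.4.
#' @return data.frame, one row per segment: `segment_id`, `transect_id`,
#'   `year`, `length_km`, `start_km`/`end_km` chainage, midpoint `x`, `y`.
#' @export
split_transects <- function(transects, target_length = 0.4) {
  bad <- transects$length_km <= 0
  if (any(bad))
    stop("zero-length transect(s): ",
         paste(transects$transect_id[bad], collapse = ", "))
  out <- lapply(seq_len(nrow(transects)), function(i) {
    tr <- transects[i, ]
    k <- max(1L, round(tr$length_km / target_length))
    sl <- tr$length_km / k
    s0 <- (seq_len(k) - 1) * sl
    mid <- (s0 + sl / 2) / tr$length_km
    data.frame(
      segment_id = sprintf("%s_%02d", tr$transect_id, seq_len(k)),
      transect_id = tr$transect_id,
      year = tr$year,
      length_km = sl,
      start_km = s0, end_km = s0 + sl,
      x = tr$x0 + mid * (tr$x1 - tr$x0),
      y = tr$y0 + mid * (tr$y1 - tr$y0)
    )
  })
  do.call(rbind, out)
}

# assign observations to segments by along-transect chainage;
# boundary ties go to the earlier segment
assign_segments <- function(segments, observations) {
  if (!nrow(observations)) return(character(0))
  ids <- character(nrow(observations))
  for (tid in unique(observations$transect_id)) {
    seg <- segments[segments$transect_id == tid, ]
    if (!nrow(seg)) stop("observations on unknown transect: ", tid)
    oi <- which(observations$transect_id == tid)
    sl <- seg$length_km[1]
    idx <- pmax(1L, ceiling(observations$chainage_km[oi] / sl - 1e-12))
    idx <- pmin(idx, nrow(seg))
    ids[oi] <- seg$segment_id[idx]
  }
  ids
}

#' Compute Euclidean distance layers from a landscape
#'
#' Distance (m) from every cell centre to the nearest forest cell and to the
#' nearest steep-slope cell (slope above the landscape's threshold, 20 degrees
#' by default). Exact Euclidean distance transforms; zero on source cells.
#'
#' @param landscape a `nest_landscape` (needs `vegetation` and `slope`).
#' @return list of `grid_raster`s `dist_forest` and `dist_slope`.
#' @export
compute_distance_layers <- function(landscape) {
  thr <- if (!is.null(landscape$steep_threshold)) landscape$steep_threshold else 20
  list(
    dist_forest = distance_transform(
      grid_raster(landscape$vegetation$values == 1L,
                  landscape$origin, landscape$cellsize)),
    dist_slope = distance_transform(
      grid_raster(landscape$slope$values > thr,
                  landscape$origin, landscape$cellsize))
  )
}

#' Build the segment response frame for the count GAM
#'
#' Splits transects, assigns truncated detections to segments by chainage,
#' counts nests per segment, extracts covariates at each segment midpoint cell
#' (nearest cell, no interpolation) and attaches the detectability offset
#' a = 2 w l p(veg) in km^2 when a detection model is supplied.
#'
#' @param transects transect table (see [split_transects()]).
#' @param observations detections with `distance_m`, `transect_id`,
#'   `chainage_km`; rows beyond `w` are dropped (truncation).
#' @param landscape a `nest_landscape` supplying covariate layers.
#' @param w truncation distance (m).
#' @param detection optional `detection_model`; when supplied the offset
#'   columns `area_km2` and `log_area` are added.
#' @param target_length segment target length (km).
#' @return data.frame of class `segment_table`.
#' @export
build_segment_table <- function(transects, observations, landscape, w,
                                detection = NULL, target_length = 0.4) {
  seg <- split_transects(transects, target_length)
  obs <- observations[observations$distance_m <= w, , drop = FALSE]
  seg$count <- 0L
  if (nrow(obs)) {
    ids <- assign_segments(seg, obs)
    tab <- table(ids)
    seg$count[match(names(tab), seg$segment_id)] <- as.integer(tab)
  }
  seg$vegetation <- raster_extract(landscape$vegetation, seg$x, seg$y)
  seg$region <- raster_extract(landscape$region, seg$x, seg$y)
  seg$temp_range <- raster_extract(landscape$temp_range, seg$x, seg$y)
  seg$elevation <- raster_extract(landscape$elevation, seg$x, seg$y)
  seg$dist_slope <- raster_extract(landscape$dist_slope, seg$x, seg$y)
  seg$dist_forest <- raster_extract(landscape$dist_forest, seg$x, seg$y)
  seg$hpd <- raster_extract(landscape$hpd, seg$x, seg$y)
  if (!is.null(detection)) {
    p <- detection_p(detection, seg$vegetation)
    seg$p_detect <- p
    seg$area_km2 <- segment_offset(seg$length_km, p, w)
    seg$log_area <- log(seg$area_km2)
  }
  class(seg) <- c("segment_table", "data.frame")
  seg
}

#' Variance-inflation-factor screen for collinear covariates
#'
#' VIF of each covariate is 1 / (1 - R^2) from regressing it on all the
#' others. While any VIF exceeds the threshold the worst offender is removed
#' and VIFs are recomputed; perfectly collinear covariates (infinite VIF) are
#' removed first. The removal sequence is recorded.
#'
#' @param covariates data.frame of numeric covariates (>= 2 columns, no
#'   constant columns).
#' @param threshold removal threshold (default 3).
#' @return list with `retained` (names), `vif` (final VIFs of survivors) and
#'   `removed` (data.frame of each removal with the VIF that triggered it).
#' @export
vif_screen <- function(covariates, threshold = 3) {
  covariates <- as.data.frame(covariates)
  num <- vapply(covariates, is.numeric, TRUE)
  stopifnot(sum(num) >= 2)
  covariates <- covariates[num]
  if (any(vapply(covariates, function(v) stats::var(v) == 0, TRUE)))
    stop("constant column(s) in covariate table")
  one_vif <- function(df) {
    vapply(names(df), function(nm) {
      # perfectly collinear columns fit exactly; the summary warning is benign
      r2 <- suppressWarnings(
        summary(stats::lm(stats::reformulate(setdiff(names(df), nm), nm),
                          data = df))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  removed <- data.frame(covariate = character(0), vif = numeric(0))
  while (ncol(covariates) >= 2) {
    v <- one_vif(covariates)
    if (all(v <= threshold)) break
    worst <- names(which.max(v))
    removed <- rbind(removed, data.frame(covariate = worst, vif = unname(v[worst])))
    covariates <- covariates[setdiff(names(covariates), worst)]
  }
  final <- if (ncol(covariates) >= 2) one_vif(covariates)
           else stats::setNames(1, names(covariates))
  list(retained = names(covariates), vif = final, removed = removed)
}
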