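#' Detectability offset: effective searched area of a segment
#'
#' The effective area a = 2 w l p is the area a segment of length l and strip
#' half-width w would cover under certain detection, scaled by the average
#' detection probability of its vegetation class (Horvitz-Thompson logic).
#' Its log is the count GAM's offset, so fitted means are counts per km^2
#' of effectively searched area, i.e. densities.
#'
#' @param length_km segment length (km).
#' @param p average detection probability for the segment's vegetation class.
#' @param w strip half-width (m).
#' @return effective area in km^2.
#' @export
segment_offset <- function(length_km, p, w) {
  if (any(p <= 0)) stop("detection probability of zero makes the offset unidentifiable")
  stopifnot(all(length_km > 0), w > 0)
  2 * (w / 1000) * length_km * p
}

#' Build the spatio-temporal count GAM formula
#'
#' The full model has 1-D thin-plate smooths of annual temperature range,
#' distance to steep slopes, elevation and distance to forests; a penalized
#' random-effect term for vegetation class; a smooth of year (k = 7); an
#' isotropic 2-D smooth of the projected coordinates; tensor-product
#' space-year interactions (x,year), (y,year) and (x,y,year); a linear term
#' in log human population density; and the log effective-area offset.
#' Terms that cannot be identified on the data at hand (fewer than 3 distinct
#' years for the temporal terms, a single vegetation level) are dropped
#' automatically; `spatial`/`temporal`/`environment` switch term blocks off
#' for reduced models.
#'
#' @param segments a `segment_table`.
#' @param k named list overriding basis sizes: `year` (7), `space` (30),
#'   `te2` (4, per margin of the 2-D tensors), `te3` (4), `env` (10).
#' @param spatial,temporal,environment include the corresponding term blocks.
#' @return a formula for [mgcv::gam()].
#' @export
dsm_formula <- function(segments, k = list(),
                        spatial = TRUE, temporal = TRUE, environment = TRUE) {
  kk <- utils::modifyList(list(year = 7, space = 30, te2 = 4, te3 = 4, env = 10), k)
  n_years <- length(unique(segments$year))
  use_year <- temporal && n_years >= 3
  k_year <- min(kk$year, n_years - 1)
  terms <- character(0)
  if (environment) {
    for (v in c("temp_range", "dist_slope", "elevation", "dist_forest"))
      terms <- c(terms, sprintf("s(%s, k = %d)", v, kk$env))
  }
  if (nlevels(droplevels(segments$vegetation)) >= 2)
    terms <- c(terms, "s(vegetation, bs = 're')")
  if (use_year) terms <- c(terms, sprintf("s(year, k = %d)", k_year))
  if (spatial) terms <- c(terms, sprintf("s(x, y, k = %d)", kk$space))
  if (spatial && use_year) {
    kt <- min(kk$te2, n_years - 1)
    terms <- c(terms,
               sprintf("te(x, year, k = c(%d, %d))", kk$te2, kt),
               sprintf("te(y, year, k = c(%d, %d))", kk$te2, kt),
               sprintf("te(x, y, year, k = c(%d, %d, %d))", kk$te3, kk$te3, min(kk$te3, n_years - 1)))
  }
  terms <- c(terms, "log(hpd)", "offset(log_area)")
  stats::as.formula(paste("count ~", paste(terms, collapse = " + ")))
}

#' Fit the density surface count GAM
#'
#' Penalized-likelihood fit of segment nest counts with a log link and the
#' log effective-area offset, smoothing parameters by REML (default). The
#' negative binomial overdispersion or Tweedie power parameter is estimated
#' alongside. Returns the coefficient covariance needed for prediction
#' variance.
#'
#' @param segments a `segment_table` with offset columns (`log_area`).
#' @param family `"nb"` (negative binomial), `"tweedie"` or `"poisson"`.
#' @param formula model formula; default [dsm_formula()] on `segments`.
#' @param method smoothing-parameter criterion (`"REML"` default, or `"GCV.Cp"`).
#' @param select add a shrinkage penalty on each smooth's null space
#'   ([mgcv::gam()] `select`), letting smooths be penalized entirely out of
#'   the model; off by default.
#' @return object of class `dsm_model` wrapping the `mgcv::gam` fit with
#'   `family`, `aic`, `deviance_explained`, `dispersion` and the formula.
#' @export
fit_dsm <- function(segments, family = c("nb", "tweedie", "poisson"),
                    formula = NULL, method = "REML", select = FALSE) {
  family <- match.arg(family)
  stopifnot(nrow(segments) >= 50 || !is.null(formula))
  if (is.null(formula)) formula <- dsm_formula(segments)
  fam <- switch(family,
                nb = mgcv::nb(),
                tweedie = mgcv::tw(),
                poisson = stats::poisson())
  dat <- as.data.frame(segments)
  if (!is.null(dat$vegetation))
    dat$vegetation <- droplevels(factor(dat$vegetation))
  fit <- mgcv::gam(formula, family = fam, data = dat, method = method,
                   select = select)
  if (!fit$converged) warning("GAM fit did not fully converge")
  dev_expl <- (fit$null.deviance - fit$deviance) / fit$null.deviance
  disp <- switch(family,
                 nb = fit$family$getTheta(TRUE),
                 tweedie = fit$family$getTheta(TRUE),
                 poisson = 1)
  structure(list(
    gam = fit, family = family, formula = formula,
    aic = stats::AIC(fit), deviance_explained = dev_expl,
    dispersion = disp, n = nrow(dat), method = method
  ), class = "dsm_model")
}

#' @export
print.dsm_model <- function(x, ...) {
  cat(sprintf("<dsm_model> family = %s, n = %d segments\n", x$family, x$n))
  cat(sprintf("  AIC = %.2f, deviance explained = %.1f%%, %s = %.4g\n",
              x$aic, 100 * x$deviance_explained,
              if (x$family == "nb") "theta" else if (x$family == "tweedie") "power" else "scale",
              x$dispersion))
  invisible(x)
}

#' Choose between the negative binomial and Tweedie fits
#'
#' Lowest AIC wins; when the AICs are within 2 of each other the model with
#' the higher deviance explained is preferred. If one fit is `NULL` (failed),
#' the other is returned with a note.
#'
#' @param nb_model,tw_model `dsm_model` fits on identical data.
#' @return the selected `dsm_model` with a `selection` attribute recording
#'   the decision.
#' @export
select_family <- function(nb_model, tw_model) {
  if (is.null(nb_model) || is.null(tw_model)) {
    out <- if (is.null(nb_model)) tw_model else nb_model
    attr(out, "selection") <- "only one candidate converged"
    return(out)
  }
  d_aic <- nb_model$aic - tw_model$aic
  if (abs(d_aic) < 2) {
    pick_nb <- nb_model$deviance_explained >= tw_model$deviance_explained
    why <- sprintf("delta-AIC %.2f < 2: higher deviance explained (%s)",
                   abs(d_aic), if (pick_nb) "nb" else "tweedie")
    if (nb_model$deviance_explained == tw_model$deviance_explained)
      why <- paste(why, "[tie]")
  } else {
    pick_nb <- d_aic < 0
    why <- sprintf("lower AIC (%s by %.2f)", if (pick_nb) "nb" else "tweedie", abs(d_aic))
  }
  out <- if (pick_nb) nb_model else tw_model
  attr(out, "selection") <- why
  out
}

# pooled and per-fold prediction metrics
cv_metrics <- function(observed, predicted) {
  r2 <- if (stats::var(observed) == 0 || stats::var(predicted) == 0) NA_real_
        else stats::cor(observed, predicted)^2
  c(rmse = sqrt(mean((predicted - observed)^2)),
    mae = mean(abs(predicted - observed)),
    r2 = r2)
}

#' K-fold cross-validation of a density surface model
#'
#' Random fold assignment (seeded), refit on each training split, response
#' predictions on the held-out fold. Reports per-fold RMSE, MAE and R^2
#' (squared Pearson correlation of predicted vs observed counts; undefined
#' for a fold whose counts have zero variance) and their averages, plus the
#' pooled metrics over all held-out predictions.
#'
#' @param segments a `segment_table`.
#' @param family,formula,method as in [fit_dsm()].
#' @param folds number of folds (default 10).
#' @param seed integer seed fixing the fold assignment.
#' @return list with `summary` (averaged fold metrics), `pooled`, and
#'   `by_fold` data.frame.
#' @export
cross_validate <- function(segments, family = "nb", formula = NULL,
                           folds = 10, seed = 1, method = "REML") {
  n <- nrow(segments)
  stopifnot(n >= folds)
  if (is.null(formula)) formula <- dsm_formula(segments)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  pred <- numeric(n)
  by_fold <- matrix(NA_real_, folds, 3, dimnames = list(NULL, c("rmse", "mae", "r2")))
  for (f in seq_len(folds)) {
    test <- fold == f
    m <- fit_dsm(segments[!test, , drop = FALSE], family = family,
                 formula = formula, method = method)
    pred[test] <- as.numeric(stats::predict(m$gam,
                                            newdata = as.data.frame(segments[test, , drop = FALSE]),
                                            type = "response"))
    by_fold[f, ] <- cv_metrics(segments$count[test], pred[test])
  }
  list(
    summary = colMeans(by_fold, na.rm = TRUE),
    pooled = cv_metrics(segments$count, pred),
    by_fold = data.frame(fold = seq_len(folds), by_fold)
  )
}

#' Residual diagnostics for a fitted density surface model
#'
#' Deviance residuals with standard-normal theoretical quantiles for QQ
#' inspection, the slope of the QQ relation, a Pearson dispersion ratio
#' (residual variance relative to the assumed mean-variance relation), and
#' optionally randomized-quantile residuals for count data. Degenerate
#' residual sets (all equal, e.g. all-zero counts) are flagged.
#'
#' @param model a `dsm_model`.
#' @param randomized also compute randomized-quantile residuals (NB only).
#' @param seed seed for the randomized residuals.
#' @return list with `qq` (data.frame `theoretical`, `observed`), `qq_slope`,
#'   `dispersion_ratio`, `degenerate`, and optionally `rq_residuals`.
#' @export
residual_diagnostics <- function(model, randomized = FALSE, seed = 1) {
  g <- model$gam
  r <- sort(stats::residuals(g, type = "deviance"))
  n <- length(r)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  degenerate <- stats::var(r) < 1e-12
  slope <- if (degenerate) NA_real_ else unname(stats::coef(stats::lm(r ~ theo))[2])
  pearson <- stats::residuals(g, type = "pearson")
  disp <- sum(pearson^2) / stats::df.residual(g)
  out <- list(qq = data.frame(theoretical = theo, observed = r),
              qq_slope = slope, dispersion_ratio = disp, degenerate = degenerate)
  if (randomized && model$family == "nb") {
    set.seed(seed)
    mu <- stats::fitted(g)
    y <- g$y
    theta <- model$dispersion
    lo <- stats::pnbinom(y - 1, size = theta, mu = mu)
    hi <- stats::pnbinom(y, size = theta, mu = mu)
    out$rq_residuals <- stats::qnorm(stats::runif(n, lo, hi))
  }
  out
}

#' Write a DSM model card as JSON
#'
#' @param model a `dsm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dsm_card <- function(model, path) {
  sm <- summary(model$gam)
  card <- list(
    family = model$family, method = model$method,
    formula = deparse(model$formula),
    n = model$n, aic = model$aic,
    deviance_explained = model$deviance_explained,
    dispersion = model$dispersion,
    edf = as.list(stats::setNames(round(sm$edf, 4), rownames(sm$s.table))),
    smoothing_parameters = as.list(model$gam$sp),
    linear_coefficients = as.list(sm$p.coeff)
  )
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
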