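#' Detection function machinery for line-transect distance sampling
#'
#' The detection function g(x) is the probability of detecting a nest at
#' perpendicular distance x from the line, with g(0) = 1. Supported keys:
#' half-normal exp(-x^2 / 2 sigma^2), hazard-rate 1 - exp(-(x/sigma)^-b),
#' and uniform. Cosine adjustment terms of order up to five multiply the key,
#' renormalized so g(0) = 1. Covariates (vegetation type) enter the scale on
#' the log link: log sigma = beta0 + beta_veg.
#'
#' @name detection
NULL

# g(x) for one parameter set; adj = cosine coefficients (may be empty)
detfun_g <- function(x, key, sigma = NULL, shape = NULL, adj = numeric(0), w) {
  k <- switch(key,
    hn = exp(-x^2 / (2 * sigma^2)),
    hr = 1 - exp(-(x / sigma)^(-shape)),
    unif = rep(1, length(x)))
  if (length(adj)) {
    series <- 1 + colSums(adj * t(outer(x, seq_along(adj), function(xx, j) cos(j * pi * xx / w))))
    k0 <- 1 + sum(adj)           # cos(0) = 1 for every order
    k <- k * series / k0
  }
  k
}

#' Half-normal average detection probability (closed form)
#'
#' For a half-normal detection function with scale `sigma` truncated at `w`,
#' the average detection probability p = integral of g over (0, w) divided by
#' w has the closed form `sigma * sqrt(pi/2) * erf(w / (sigma * sqrt(2))) / w`.
#'
#' @param sigma half-normal scale (m).
#' @param w truncation distance (m).
#' @return average detection probability in (0, 1].
#' @export
hn_average_p <- function(sigma, w) {
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  sigma * sqrt(pi / 2) * erf(w / (sigma * sqrt(2))) / w
}

# integral of g over (0, w) by adaptive quadrature
detfun_mu <- function(key, sigma = NULL, shape = NULL, adj = numeric(0), w) {
  if (key == "unif" && !length(adj)) return(w)
  stats::integrate(function(x) detfun_g(x, key, sigma, shape, adj, w),
                   0, w, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' Numerically integrated average detection probability
#'
#' `integrate`-based counterpart of [hn_average_p()], valid for any key and
#' adjustment series; agrees with the closed form to ~1e-10 for the plain
#' half-normal.
#'
#' @inheritParams hn_average_p
#' @param key,shape,adj detection-function specification, see [fit_detection()].
#' @export
average_p <- function(sigma = NULL, w, key = "hn", shape = NULL, adj = numeric(0)) {
  detfun_mu(key, sigma, shape, adj, w) / w
}

# unpack the optimizer parameter vector for a given model structure
unpack_par <- function(par, key, n_adj, levels) {
  out <- list(adj = numeric(0), shape = NULL, beta = NULL)
  i <- 0
  if (key %in% c("hn", "hr")) {
    nb <- 1 + length(levels)      # intercept + offsets (levels may be empty)
    out$beta <- par[seq_len(if (length(levels)) nb else 1)]
    i <- if (length(levels)) nb else 1
  }
  if (key == "hr") { out$shape <- exp(par[i + 1]); i <- i + 1 }
  if (n_adj > 0) out$adj <- par[i + seq_len(n_adj)]
  out
}

# per-observation sigma from the scale linear predictor (log link)
obs_sigma <- function(beta, veg, levels, n = length(veg)) {
  if (!length(levels)) return(rep(exp(beta[1]), n))
  off <- c(0, beta[-1])[match(as.character(veg), levels)]
  # first factor level is the reference; `levels` here excludes it
  exp(beta[1] + ifelse(is.na(off), 0, off))
}

#' Fit a detection function by maximum conditional likelihood
#'
#' Maximizes the conditional likelihood of perpendicular distances,
#' f(x) = g(x) / integral of g over (0, w), by bounded quasi-Newton from
#' three starting points. For covariate models the scale is
#' log sigma = beta0 + beta_veg (first vegetation level as reference) and each
#' observation gets its own average detection probability
#' p_i = mu(sigma_i) / w. Models with adjustments are checked for
#' monotone non-increasing, non-negative g on a 100-point grid and flagged
#' invalid on violation. The overall average detection probability is the
#' Horvitz-Thompson form n / sum(1 / p_i), with a delta-method CV from the
#' observed information.
#'
#' @param observations data.frame with columns `distance_m` and (for covariate
#'   models) `vegetation`; distances must already be truncated at `w`.
#' @param key `"hn"` (half-normal), `"hr"` (hazard-rate) or `"unif"`.
#' @param n_adjustments number of cosine adjustment terms (orders 1..n, max 5).
#' @param covariate `NULL` for a pooled fit, or `"vegetation"`.
#' @param w truncation distance (m).
#' @return object of class `detection_model`: parameter estimates, per-level
#'   sigma and p, overall `p_hat` with `cv`, log-likelihood, `aic`,
#'   convergence and monotonicity flags.
#' @export
fit_detection <- function(observations, key = c("hn", "hr", "unif"),
                          n_adjustments = 0, covariate = NULL, w) {
  key <- match.arg(key)
  stopifnot(n_adjustments <= 5, w > 0)
  x <- observations$distance_m
  stopifnot(all(x >= 0))
  x <- pmin(x, w)                       # guard boundary ties
  n <- length(x)
  use_cov <- !is.null(covariate)
  if (use_cov && key == "unif") stop("uniform key has no scale to model covariates on")
  veg <- if (use_cov) factor(as.character(observations[[covariate]])) else NULL
  if (use_cov && nlevels(veg) < 2)
    stop("covariate model needs at least 2 levels present after truncation")
  lev <- if (use_cov) levels(veg) else character(0)
  off_lev <- if (use_cov) lev[-1] else character(0)

  npar <- (key != "unif") * (1 + length(off_lev)) + (key == "hr") + n_adjustments
  nll <- function(par) {
    pp <- unpack_par(par, key, n_adjustments, off_lev)
    val <- tryCatch({
      if (key == "unif") {
        g <- detfun_g(x, key, adj = pp$adj, w = w)
        if (any(g <= 0)) return(1e10)
        mu <- detfun_mu(key, adj = pp$adj, w = w)
        -(sum(log(g)) - n * log(mu))
      } else {
        sig <- obs_sigma(pp$beta, veg, lev, n)
        usig <- unique(sig)
        mu_u <- vapply(usig, function(s) detfun_mu(key, s, pp$shape, pp$adj, w), 0)
        if (any(mu_u <= 0)) return(1e10)
        mu <- mu_u[match(sig, usig)]
        g <- detfun_g(x, key, sig, pp$shape, pp$adj, w)
        if (any(g <= 0)) return(1e10)
        -(sum(log(g)) - sum(log(mu)))
      }
    }, error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }

  if (npar == 0) {                       # uniform, no adjustments: fixed model
    ll <- -n * log(w)
    fit <- list(par = numeric(0), value = -ll, convergence = 0)
    hess <- matrix(0, 0, 0)
  } else {
    s0 <- log(max(stats::sd(x), w / 20))
    starts <- lapply(c(0, -0.7, 0.7), function(d) {
      p0 <- numeric(npar)
      if (key != "unif") p0[1] <- s0 + d
      if (key == "hr") p0[1 + length(off_lev) + 1] <- log(2) + d / 2
      p0
    })
    fits <- lapply(starts, function(p0)
      tryCatch(stats::optim(p0, nll, method = "L-BFGS-B",
                            lower = rep(-15, npar), upper = rep(15, npar),
                            control = list(maxit = 500)),
               error = function(e) list(value = Inf, convergence = 99)))
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    hess <- tryCatch(stats::optimHess(fit$par, nll), error = function(e) NULL)
  }
  converged <- is.finite(fit$value) && fit$value < 1e9 && fit$convergence %in% c(0, 1)
  pp <- unpack_par(fit$par, key, n_adjustments, off_lev)

  # monotonicity / positivity screen on a 100-point grid
  grid <- seq(0, w, length.out = 100)
  sig_chk <- if (key == "unif") NULL else exp(pp$beta[1])
  mono_ok <- TRUE
  if (n_adjustments > 0) {
    sigs <- if (use_cov) obs_sigma(pp$beta, factor(lev, lev), lev) else sig_chk
    for (s in if (is.null(sigs)) list(NULL) else sigs) {
      gg <- detfun_g(grid, key, s, pp$shape, pp$adj, w)
      if (any(gg < -1e-9) || any(diff(gg) > 1e-6)) mono_ok <- FALSE
    }
  }

  # per-level sigma and p; per-observation p for the HT average
  if (key == "unif") {
    mu_all <- detfun_mu(key, adj = pp$adj, w = w)
    p_obs <- rep(mu_all / w, n)
    level_p <- c(pooled = mu_all / w)
    level_sigma <- NULL
  } else if (use_cov) {
    sig_lev <- obs_sigma(pp$beta, factor(lev, lev), lev)
    names(sig_lev) <- lev
    mu_lev <- vapply(sig_lev, function(s) detfun_mu(key, s, pp$shape, pp$adj, w), 0)
    level_p <- mu_lev / w
    level_sigma <- sig_lev
    p_obs <- level_p[as.character(veg)]
  } else {
    s1 <- exp(pp$beta[1])
    level_p <- c(pooled = detfun_mu(key, s1, pp$shape, pp$adj, w) / w)
    level_sigma <- c(pooled = s1)
    p_obs <- rep(level_p, n)
  }
  p_hat <- n / sum(1 / p_obs)

  # delta-method CV of p_hat from the observed information
  cv <- NA_real_
  if (npar > 0 && !is.null(hess) && converged) {
    V <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(V)) {
      phat_of <- function(par) {
        q <- unpack_par(par, key, n_adjustments, off_lev)
        if (key == "unif") {
          detfun_mu(key, adj = q$adj, w = w) / w
        } else {
          sig <- obs_sigma(q$beta, veg, lev, n)
          usig <- unique(sig)
          mu_u <- vapply(usig, function(s) detfun_mu(key, s, q$shape, q$adj, w), 0)
          pi_ <- mu_u[match(sig, usig)] / w
          n / sum(1 / pi_)
        }
      }
      gr <- tryCatch(numeric_grad(phat_of, fit$par), error = function(e) NULL)
      if (!is.null(gr)) {
        v <- drop(t(gr) %*% V %*% gr)
        if (is.finite(v) && v >= 0) cv <- sqrt(v) / p_hat
      }
    }
  }

  ll <- -fit$value
  structure(list(
    key = key, n_adjustments = n_adjustments, adjustments = pp$adj,
    covariate = covariate, levels = lev, shape = pp$shape,
    beta = pp$beta, sigma = level_sigma, level_p = level_p,
    p_hat = unname(p_hat), cv = cv,
    w = w, n = n, loglik = ll, npar = npar, aic = 2 * npar - 2 * ll,
    converged = converged, monotone = mono_ok,
    observations = observations
  ), class = "detection_model")
}

numeric_grad <- function(f, par, eps = 1e-5) {
  vapply(seq_along(par), function(i) {
    h <- eps * max(1, abs(par[i]))
    p1 <- par; p1[i] <- p1[i] + h
    p2 <- par; p2[i] <- p2[i] - h
    (f(p1) - f(p2)) / (2 * h)
  }, 0)
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> key = %s, %d cosine adj., %s\n",
              x$key, x$n_adjustments,
              if (is.null(x$covariate)) "pooled scale"
              else paste0("scale ~ ", x$covariate)))
  cat(sprintf("  n = %d, w = %g m, logLik = %.2f, AIC = %.2f\n",
              x$n, x$w, x$loglik, x$aic))
  cat(sprintf("  average p = %.3f (CV = %.3f)\n", x$p_hat, x$cv))
  if (!is.null(x$sigma))
    cat("  sigma (m):", paste(sprintf("%s %.1f", names(x$sigma), x$sigma),
                              collapse = ", "), "\n")
  if (!x$converged) cat("  ** fit did not converge **\n")
  if (!x$monotone) cat("  ** non-monotone g(x): model flagged invalid **\n")
  invisible(x)
}

#' Detection probability for new vegetation levels
#'
#' @param model a `detection_model`.
#' @param vegetation character/factor of vegetation classes (ignored for
#'   pooled models).
#' @return vector of average detection probabilities.
#' @export
detection_p <- function(model, vegetation = NULL) {
  if (is.null(model$covariate) || is.null(vegetation))
    return(rep(unname(model$level_p[1]), max(1, length(vegetation))))
  p <- model$level_p[as.character(vegetation)]
  if (anyNA(p)) stop("vegetation level(s) absent from the fitted model: ",
                     paste(unique(vegetation[is.na(p)]), collapse = ", "))
  unname(p)
}

#' Select a truncation distance by the g(w) = 0.15 rule of thumb
#'
#' For each candidate w, fits a covariate-free half-normal detection function
#' to the distances truncated at that candidate and evaluates g(w). The chosen
#' truncation is the smallest candidate at which detection probability has
#' fallen to 0.15 or below (the standard rule of thumb for discarding the
#' unreliable tail). If no candidate satisfies the rule (near-uniform
#' detection), the largest candidate is returned with a warning flag.
#'
#' @param observations data.frame with `distance_m` (>= 30 rows).
#' @param candidates numeric vector of candidate truncation distances (m).
#' @return list with `w` (chosen), `table` (candidate, sigma_hat, g_w),
#'   and `warning` (TRUE when the rule was unsatisfiable).
#' @export
select_truncation <- function(observations, candidates = c(30, 40, 50, 60)) {
  x <- observations$distance_m
  if (length(x) < 30) stop("need at least 30 observations to select truncation")
  candidates <- sort(candidates)
  tab <- do.call(rbind, lapply(candidates, function(w) {
    xi <- x[x <= w]
    f <- fit_detection(data.frame(distance_m = xi), key = "hn", w = w)
    data.frame(w = w, sigma_hat = unname(f$sigma), g_w = exp(-w^2 / (2 * f$sigma^2)))
  }))
  ok <- which(tab$g_w <= 0.15)
  if (length(ok)) {
    list(w = tab$w[ok[1]], table = tab, warning = FALSE)
  } else {
    list(w = max(candidates), table = tab, warning = TRUE)
  }
}

# fitted CDF of perpendicular distances, per observation (PIT values)
detection_pit <- function(model, observations = model$observations) {
  x <- pmin(observations$distance_m, model$w)
  grid <- seq(0, model$w, length.out = 512)
  cdf_for <- function(sigma) {
    g <- detfun_g(grid, model$key, sigma, model$shape, model$adjustments, model$w)
    cum <- pracma::cumtrapz(grid, g)
    cum / cum[length(cum)]
  }
  if (is.null(model$covariate) || model$key == "unif") {
    s <- if (model$key == "unif") NULL else unname(model$sigma[1])
    stats::approx(grid, cdf_for(s), xout = x)$y
  } else {
    veg <- as.character(observations[[model$covariate]])
    u <- numeric(length(x))
    for (lv in unique(veg)) {
      i <- veg == lv
      u[i] <- stats::approx(grid, cdf_for(model$sigma[[lv]]), xout = x[i])$y
    }
    u
  }
}

# asymptotic upper tail of the Cramer-von Mises statistic. The limiting law
# is sum_j Z_j^2 / (j pi)^2; the tail is recovered from its characteristic
# function phi(t) = prod_j (1 - 2it lambda_j)^(-1/2) by Gil-Pelaez inversion
# (small lambda tail of the product enters as a phase shift, since
# sum_j lambda_j = 1/6 exactly)
pcvm_upper <- function(q) {
  if (q <= 1e-3) return(1)
  J <- 400L
  lam <- 1 / ((seq_len(J) * pi)^2)
  phase <- 1 / 6 - sum(lam)
  integrand <- function(t) {
    v <- vapply(t, function(tt) {
      if (tt == 0) return(1 / 6 - q)
      phi <- prod(1 / sqrt(1 - 2i * tt * lam)) * exp(1i * tt * phase)
      Im(phi * exp(-1i * tt * q)) / tt
    }, 0)
    v
  }
  p <- 0.5 + stats::integrate(integrand, 0, 2000, subdivisions = 2000L,
                              rel.tol = 1e-8, abs.tol = 1e-10)$value / pi
  min(max(p, 0), 1)
}

#' Goodness of fit of a detection function
#'
#' Cramer-von Mises and Kolmogorov-Smirnov tests of the fitted distance CDF,
#' computed on probability-integral-transform values (for covariate models,
#' each observation uses its own level's CDF). The CvM p-value uses the
#' asymptotic limiting distribution; the KS p-value comes from
#' [stats::ks.test()] on the PIT values against the uniform.
#'
#' @param model a `detection_model`.
#' @param observations optional data.frame (defaults to the fitting data).
#' @return list with `cvm` (`statistic`, `p`) and `ks` (`statistic`, `p`).
#' @export
goodness_of_fit <- function(model, observations = model$observations) {
  u <- sort(detection_pit(model, observations))
  n <- length(u)
  W2 <- 1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  list(
    cvm = list(statistic = W2, p = pcvm_upper(W2)),
    ks = list(statistic = unname(ks$statistic), p = ks$p.value)
  )
}

#' Select a detection model by AIC among converged, adequate candidates
#'
#' Candidates failing convergence or the monotonicity screen are dropped.
#' Candidates failing the Cramer-von Mises goodness-of-fit test at `alpha`
#' are excluded unless every candidate fails, in which case the minimum-AIC
#' model is returned with `gof_failed = TRUE`. Ties (delta-AIC below 1e-6)
#' are broken in favour of fewer parameters.
#'
#' @param models list of `detection_model` objects fitted to the same data.
#' @param alpha significance level of the goodness-of-fit gate.
#' @return the selected `detection_model`, with attributes `gof_failed` and
#'   `selection_table` attached.
#' @export
select_detection_model <- function(models, alpha = 0.05) {
  stopifnot(length(models) >= 1)
  valid <- vapply(models, function(m) isTRUE(m$converged) && isTRUE(m$monotone), TRUE)
  if (!any(valid)) stop("no candidate detection model converged")
  models <- models[valid]
  gof_p <- vapply(models, function(m) goodness_of_fit(m)$cvm$p, 0)
  aic <- vapply(models, `[[`, 0, "aic")
  npar <- vapply(models, `[[`, 0, "npar")
  tab <- data.frame(key = vapply(models, `[[`, "", "key"),
                    covariate = vapply(models, function(m)
                      if (is.null(m$covariate)) "none" else m$covariate, ""),
                    n_adj = vapply(models, `[[`, 0, "n_adjustments"),
                    npar = npar, aic = aic, cvm_p = gof_p)
  pass <- gof_p > alpha
  pool <- if (any(pass)) which(pass) else seq_along(models)
  # minimum AIC; among ties (delta < 1e-6) prefer fewer parameters
  cand <- pool[aic[pool] - min(aic[pool]) < 1e-6]
  best <- cand[which.min(npar[cand])]
  out <- models[[best]]
  attr(out, "gof_failed") <- !any(pass)
  attr(out, "selection_table") <- tab
  out
}

#' Write a detection model card as JSON
#'
#' @param model a `detection_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detection_card <- function(model, path) {
  card <- list(
    key = model$key, covariate = model$covariate,
    n_adjustments = model$n_adjustments, adjustments = model$adjustments,
    truncation_m = model$w, beta = model$beta, shape = model$shape,
    sigma_m = as.list(model$sigma), level_p = as.list(model$level_p),
    average_p = model$p_hat, cv = model$cv,
    loglik = model$loglik, aic = model$aic, n = model$n,
    converged = model$converged, monotone = model$monotone
  )
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
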