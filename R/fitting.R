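# Shared Levenberg-Marquardt wrapper. `model` maps a parameter vector to
# predicted responses; the fit object carries everything needed for
# covariance and residual-bootstrap uncertainties, including a refit
# closure over replacement response vectors.
.ls_fit <- function(par0, model, y, lower = rep(-Inf, length(par0)),
                    upper = rep(Inf, length(par0)), weights = NULL,
                    maxiter = 200) {
  if (is.null(weights)) weights <- rep(1, length(y))
  w <- sqrt(weights)
  run <- function(yy, start) {
    minpack.lm::nls.lm(par = pmin(pmax(start, lower), upper),
                       fn = function(p) w * (yy - model(p)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = maxiter))
  }
  res <- run(y, par0)
  par <- res$par
  fitted <- model(par)
  resid <- y - fitted
  df <- length(y) - length(par)
  jac <- .num_jacobian(model, par, lower, upper)
  cov_se <- tryCatch({
    jtj <- crossprod(w * jac)
    sigma2 <- sum(weights * resid^2) / max(df, 1)
    sqrt(pmax(diag(sigma2 * solve(jtj)), 0))
  }, error = function(e) rep(NA_real_, length(par)))
  at_bound <- (is.finite(lower) & abs(par - lower) < 1e-10 * pmax(1, abs(lower))) |
              (is.finite(upper) & abs(par - upper) < 1e-10 * pmax(1, abs(upper)))
  list(par = par, fitted = fitted, residuals = resid,
       deviance = sum(weights * resid^2), df = df,
       se = cov_se, converged = res$info %in% 1:3,
       info = res$info, message = res$message,
       at_bound = at_bound, y = y, model = model,
       refit = function(yy, start = par) run(yy, start)$par)
}

# forward-difference Jacobian respecting box bounds
.num_jacobian <- function(model, par, lower, upper) {
  f0 <- model(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- 1e-6 * max(abs(par[j]), 1e-6)
    pj <- par
    if (is.finite(upper[j]) && par[j] + h > upper[j]) h <- -h
    pj[j] <- par[j] + h
    J[, j] <- (model(pj) - f0) / h
  }
  J
}

#' Fit a monoexponential inversion-recovery curve
#'
#' Fits `I(tau) = A - B exp(-R1 tau)` with all three parameters free
#' (`B` free rather than pinned at `2A`, allowing imperfect inversion) and
#' returns the longitudinal rate `R1 = 1/T1` with its standard error.
#'
#' @param series A [relaxation_series()].
#' @return List of class `r1_fit` with `r1`, `se`, `par` (`A`, `B`, `R1`),
#'   `converged`, `flags` and the underlying fit.
#' @export
fit_inversion_recovery <- function(series) {
  stopifnot(inherits(series, "relaxation_series"))
  taus <- series$taus; y <- series$intensities
  flags <- character(0)
  rng <- diff(range(y))
  model <- function(p) p[1] - p[2] * exp(-p[3] * taus)
  a0 <- max(y); b0 <- max(rng, 1e-12); r0 <- 1 / stats::median(taus)
  fit <- .ls_fit(c(a0, b0, r0), model, y,
                 lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 1e4))
  r1 <- fit$par[3]
  if (!fit$converged) flags <- c(flags, "non-convergence")
  if (r1 <= 0 || fit$at_bound[3]) flags <- c(flags, "R1 at bound or non-positive")
  # no measurable decay: signal range indistinguishable from residual scatter
  if (rng < 4 * stats::sd(fit$residuals) || fit$par[2] < 4 * stats::sd(fit$residuals))
    flags <- c(flags, "no detectable recovery; R1 unidentifiable")
  structure(list(r1 = r1, se = fit$se[3],
                 par = stats::setNames(fit$par, c("A", "B", "R1")),
                 converged = fit$converged && length(flags) == 0,
                 flags = flags, fit = fit,
                 resonance = series$resonance, condition = series$condition),
            class = "r1_fit")
}

#' @export
print.r1_fit <- function(x, ...) {
  cat(sprintf("Inversion recovery %s/%s: R1 = %.4g +- %.2g s^-1%s\n",
              x$resonance, x$condition, x$r1, x$se,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Fit the Luz-Meiboom model to a single-field dispersion dataset
#'
#' Converts intensities to effective rates via [r2_effective()] and fits
#' the fast-exchange model. Populations and shift difference cannot be
#' separated in this regime: only the composite `c = p_A p_B domega^2` is
#' reported. A flat dispersion pins `c` at zero and flags `k_app` as
#' unidentifiable.
#'
#' @param dataset A [cpmg_dataset()].
#' @return List of class `luz_meiboom_fit` with `params`
#'   ([luz_meiboom_params()]), `se`, `converged`, `flags`, `r2eff` and the
#'   underlying fit.
#' @export
fit_luz_meiboom <- function(dataset) {
  stopifnot(inherits(dataset, "cpmg_dataset"), length(dataset$nu_cpmg) >= 4)
  nu <- dataset$nu_cpmg
  r2 <- r2_effective(dataset$intensity, dataset$reference_intensity,
                     dataset$constant_time)
  flags <- character(0)
  model <- function(p) luz_meiboom_r2(nu, list(k_app = p[1], c = p[2], r2_0 = p[3]))
  amp <- max(diff(range(r2)), 1)
  best <- NULL
  for (k0 in c(1e2, 1e3, 1e4)) {
    f <- .ls_fit(c(k0, amp * k0, min(r2)), model, r2,
                 lower = c(1e-6, 0, 0), upper = c(1e7, Inf, 1e4))
    if (is.null(best) || f$deviance < best$deviance - 1e-12 ||
        (abs(f$deviance - best$deviance) <= 1e-12 && f$par[1] < best$par[1]))
      best <- f
  }
  fit <- best
  disp_amp <- diff(range(fit$fitted))
  resid_scale <- stats::sd(fit$residuals)
  # flat beyond noise (the absolute floor catches exactly flat data)
  if (disp_amp < 2 * resid_scale + 1e-6 * max(abs(r2), 1)) {
    flat <- .ls_fit(mean(r2), function(p) rep(p[1], length(nu)), r2,
                    lower = 0, upper = 1e4)
    fit <- .ls_fit(c(fit$par[1], 0, flat$par[1]), model, r2,
                   lower = c(1e-6, 0, 0), upper = c(1e7, 0, 1e4))
    flags <- c(flags, "flat dispersion: c pinned at 0, k_app unidentifiable")
  }
  structure(list(params = luz_meiboom_params(fit$par[1], fit$par[2], fit$par[3]),
                 se = stats::setNames(fit$se, c("k_app", "c", "r2_0")),
                 converged = fit$converged, flags = flags,
                 r2eff = r2, fit = fit, dataset = dataset),
            class = "luz_meiboom_fit")
}

#' @export
print.luz_meiboom_fit <- function(x, ...) {
  cat(sprintf("Luz-Meiboom fit (%s/%s, %g MHz): k_app = %.4g +- %.2g s^-1, c = %.4g s^-2, R2,0 = %.4g s^-1%s\n",
              x$dataset$resonance, x$dataset$condition,
              x$dataset$spectrometer_freq,
              x$params$k_app, x$se[["k_app"]], x$params$c, x$params$r2_0,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Global Carver-Richards fit across fields and conditions
#'
#' Single weighted least-squares problem over up to four dispersion
#' datasets of one resonance (2 fields x 2 conditions) with the sharing
#' scheme: `|ddelta|` global across all datasets; `k_i` and the populations
#' shared across fields within a condition but free across conditions;
#' `R2,0` free per dataset. `domega` is computed per dataset from
#' `|ddelta|` and its field. Initialization is multi-start over a grid of
#' exchange rates and minor populations (>= 16 starts); the best objective
#' wins, ties broken towards the smaller `k_i`, and the winner is polished
#' with a longer iteration budget.
#'
#' @param datasets List of [cpmg_dataset()] of a single resonance.
#' @param weights Optional per-dataset list of per-point weights (inverse
#'   variances); uniform by default.
#' @param n_starts_kp Multi-start grid: vectors of starting `k_i` and minor
#'   populations.
#' @return An object of class `global_fit_result` with per-condition
#'   `k_i`/`p_minor` (+ standard errors), shared `delta_delta`,
#'   per-dataset `r2_0`, residuals, convergence metadata and flags.
#' @export
fit_carver_richards_global <- function(datasets, weights = NULL,
                                       n_starts_kp = list(k = c(1e2, 1e3, 1e4),
                                                          p = c(0.01, 0.1, 0.3))) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "cpmg_dataset")))
  resonance <- unique(vapply(datasets, `[[`, character(1), "resonance"))
  if (length(resonance) != 1L)
    stop("all datasets must share one resonance label", call. = FALSE)
  conditions <- unique(vapply(datasets, `[[`, character(1), "condition"))
  fields <- vapply(datasets, `[[`, numeric(1), "spectrometer_freq")
  flags <- character(0)
  if (length(unique(fields)) < 2)
    flags <- c(flags, "single-field data: global sharing degenerates to a single-field fit")

  nd <- length(datasets)
  nc <- length(conditions)
  cond_idx <- match(vapply(datasets, `[[`, character(1), "condition"), conditions)
  r2eff <- lapply(datasets, function(d)
    r2_effective(d$intensity, d$reference_intensity, d$constant_time))
  y <- unlist(r2eff)
  if (is.null(weights)) w <- rep(1, length(y)) else w <- unlist(weights)

  # parameter vector: dd, k[1..nc], p[1..nc], r20[1..nd]
  model <- function(par) {
    dd <- par[1]
    ks <- par[1 + seq_len(nc)]
    ps <- par[1 + nc + seq_len(nc)]
    r20 <- par[1 + 2 * nc + seq_len(nd)]
    unlist(lapply(seq_len(nd), function(i) {
      ci <- cond_idx[i]
      .cr_r2(datasets[[i]]$nu_cpmg, ks[ci], ps[ci],
             delta_omega_from_ppm(dd, fields[i]), r20[i])
    }))
  }
  lower <- c(0, rep(0, nc), rep(0, nc), rep(0, nd))
  upper <- c(20, rep(1e7, nc), rep(0.5, nc), rep(2000, nd))
  r20_start <- vapply(r2eff, min, numeric(1))
  dd_starts <- c(1, 3)
  grid <- expand.grid(k = n_starts_kp$k, p = n_starts_kp$p, dd = dd_starts)
  best <- NULL; best_k <- Inf
  for (i in seq_len(nrow(grid))) {
    par0 <- c(grid$dd[i], rep(grid$k[i], nc), rep(grid$p[i], nc), r20_start)
    # coarse pass: short iteration budget, maxiter warnings are expected
    f <- suppressWarnings(
      .ls_fit(par0, model, y, lower, upper, weights = w, maxiter = 40))
    if (is.null(best) || f$deviance < best$deviance - 1e-10 * (1 + best$deviance) ||
        (abs(f$deviance - best$deviance) <= 1e-10 * (1 + best$deviance) &&
         max(f$par[1 + seq_len(nc)]) < best_k)) {
      best <- f; best_k <- max(f$par[1 + seq_len(nc)])
    }
  }
  fit <- .ls_fit(best$par, model, y, lower, upper, weights = w, maxiter = 400)
  if (!fit$converged) flags <- c(flags, paste0("non-convergence: ", fit$message))
  if (any(fit$at_bound[-(1 + nc + seq_len(nc))]))
    flags <- c(flags, "parameter at bound")
  dd <- fit$par[1]
  ks <- stats::setNames(fit$par[1 + seq_len(nc)], conditions)
  ps <- stats::setNames(fit$par[1 + nc + seq_len(nc)], conditions)
  r20 <- fit$par[1 + 2 * nc + seq_len(nd)]
  se <- fit$se
  # flat dispersion check: fitted exchange contribution below noise
  disp_amp <- max(vapply(seq_len(nd), function(i) {
    ci <- cond_idx[i]
    curve <- .cr_r2(datasets[[i]]$nu_cpmg, ks[ci], ps[ci],
                    delta_omega_from_ppm(dd, fields[i]), r20[i])
    diff(range(curve))
  }, numeric(1)))
  if (disp_amp < 2 * stats::sd(fit$residuals) || dd < 1e-6)
    flags <- c(flags, "flat dispersion: exchange parameters unidentifiable")
  structure(list(resonance = resonance, conditions = conditions,
                 delta_delta = dd, delta_delta_se = se[1],
                 k_i = ks, k_i_se = stats::setNames(se[1 + seq_len(nc)], conditions),
                 p_minor = ps,
                 p_minor_se = stats::setNames(se[1 + nc + seq_len(nc)], conditions),
                 r2_0 = r20, r2_0_se = se[1 + 2 * nc + seq_len(nd)],
                 fields = fields, cond_idx = cond_idx,
                 residuals = fit$residuals, deviance = fit$deviance,
                 converged = fit$converged, flags = flags, fit = fit,
                 datasets = datasets),
            class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat(sprintf("Global Carver-Richards fit, resonance '%s' (%d datasets)\n",
              x$resonance, length(x$datasets)))
  cat(sprintf("  |ddelta| = %.3f +- %.3f ppm (shared)\n",
              x$delta_delta, x$delta_delta_se))
  for (cond in x$conditions)
    cat(sprintf("  %s: k_i = %.4g +- %.2g s^-1, p_minor = %.4g +- %.2g\n",
                cond, x$k_i[[cond]], x$k_i_se[[cond]],
                x$p_minor[[cond]], x$p_minor_se[[cond]]))
  cat(sprintf("  R2,0 per dataset: %s s^-1\n",
              paste(signif(x$r2_0, 4), collapse = ", ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the slow-exchange rate from a saturation-transfer decay
#'
#' Fits the Forsen-Hoffman residual-intensity model with `I_0` and the
#' directed rate out of the observed state free and `R1` fixed at the
#' series' recorded value.
#'
#' @param series A [saturation_series()] with `r1` set.
#' @return List of class `saturation_fit` with `k` (the rate out of the
#'   observed state), `se`, `i0`, `converged`, `flags` and the fit.
#' @export
fit_saturation_transfer <- function(series) {
  stopifnot(inherits(series, "saturation_series"))
  if (is.null(series[["r1"]]) || !is.finite(series[["r1"]]) || series[["r1"]] <= 0)
    stop("`series$r1` must be a positive fixed rate (record its provenance)",
         call. = FALSE)
  taus <- series$taus; y <- series$intensities
  r1 <- series[["r1"]]
  flags <- character(0)
  model <- function(p) slow_exchange_intensity(taus, p[1], p[2], r1)
  fit <- .ls_fit(c(max(y), 1 / stats::median(taus)), model, y,
                 lower = c(1e-12, 0), upper = c(Inf, 1e4))
  k <- fit$par[2]
  if (!fit$converged) flags <- c(flags, "non-convergence")
  decay <- fit$par[1] - min(fit$fitted)
  if (k <= 0 || decay < 2 * stats::sd(fit$residuals))
    flags <- c(flags, "no detectable transfer: k ~ 0")
  structure(list(k = k, se = fit$se[2], i0 = fit$par[1], i0_se = fit$se[1],
                 r1 = r1, r1_provenance = series$r1_provenance,
                 observed = series$observed, saturated = series$saturated,
                 condition = series$condition,
                 converged = fit$converged && length(flags) == 0,
                 flags = flags, fit = fit),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("Saturation transfer %s->%s (%s): k = %.4g +- %.2g s^-1 (R1 = %.3g, %s)%s\n",
              x$observed, x$saturated, x$condition, x$k, x$se, x$r1,
              x$r1_provenance,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Parameter uncertainties by covariance and residual bootstrap
#'
#' The covariance method evaluates the Jacobian at the optimum
#' (`sigma^2 (J'J)^-1`); the bootstrap resamples residuals with a seed,
#' refits, and reports the standard deviation over replicates. Both are
#' reported side by side; a singular Jacobian leaves the covariance column
#' `NA` while the bootstrap still runs.
#'
#' @param fit A fit object from this package (any of the `*_fit` classes or
#'   a `global_fit_result`).
#' @param method Character vector, subset of `c("covariance", "bootstrap")`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap.
#' @return A data frame with one row per parameter and one column per
#'   requested method.
#' @export
estimate_uncertainties <- function(fit, method = c("covariance", "bootstrap"),
                                   n_boot = 200, seed = 1) {
  method <- match.arg(method, c("covariance", "bootstrap"), several.ok = TRUE)
  core <- if (inherits(fit, c("r1_fit", "luz_meiboom_fit", "saturation_fit",
                              "global_fit_result"))) fit$fit else fit
  if (!is.list(core) || is.null(core$refit))
    stop("unsupported fit object", call. = FALSE)
  out <- data.frame(parameter = paste0("p", seq_along(core$par)))
  if ("covariance" %in% method) out$covariance_se <- core$se
  if ("bootstrap" %in% method) {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ystar <- core$fitted + sample(core$residuals, replace = TRUE)
        core$refit(ystar)
      }, numeric(length(core$par)))
    })
    out$bootstrap_se <- apply(matrix(boots, nrow = length(core$par)), 1, stats::sd)
  }
  out
}
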