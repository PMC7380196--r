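#' 1D spectrum container
#'
#' @param ppm Strictly monotone chemical-shift axis (ppm; NMR convention,
#'   values typically decrease left to right and the 19F reporters used here
#'   sit at negative ppm).
#' @param intensity Intensities, one per axis point (arbitrary units).
#' @param spectrometer_freq Spectrometer frequency in MHz (> 0).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, spectrometer_freq) {
  stopifnot(is.numeric(ppm), is.numeric(intensity),
            length(ppm) == length(intensity), length(ppm) >= 2,
            is.numeric(spectrometer_freq), spectrometer_freq > 0)
  d <- diff(ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop("`ppm` must be strictly monotone", call. = FALSE)
  structure(list(ppm = ppm, intensity = intensity,
                 spectrometer_freq = spectrometer_freq),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("1D spectrum: %d points, %.4g to %.4g ppm at %g MHz\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)],
              x$spectrometer_freq))
  invisible(x)
}

#' Lorentzian peak description
#'
#' Unit-height parameterization: the lineshape is
#' `amplitude / (1 + (2 (ppm - center) / fwhm_ppm)^2)` so that
#' `area = amplitude * pi * fwhm / 2`. Widths are stored in Hz (they are
#' field dependent); centers stay in ppm.
#'
#' @param center Peak position in ppm.
#' @param fwhm Full width at half maximum in Hz (> 0).
#' @param amplitude Peak height (a.u.).
#' @return An object of class `lorentzian_peak` with derived element `area`
#'   (a.u. Hz).
#' @export
lorentzian_peak <- function(center, fwhm, amplitude) {
  stopifnot(fwhm > 0)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 area = amplitude * pi * fwhm / 2),
            class = "lorentzian_peak")
}

#' @export
print.lorentzian_peak <- function(x, ...) {
  cat(sprintf("Lorentzian: center %.4f ppm, fwhm %.3g Hz, amplitude %.4g, area %.4g a.u.*Hz\n",
              x$center, x$fwhm, x$amplitude, x$area))
  invisible(x)
}

# Lorentzian evaluated on a ppm axis; width given in ppm.
.lorentz <- function(ppm, center, fwhm_ppm, amplitude) {
  amplitude / (1 + (2 * (ppm - center) / fwhm_ppm)^2)
}

# crude local-maxima picker used for automatic initialization; enforces a
# minimum separation so noise ripples on one peak are not picked twice
.top_maxima <- function(ppm, y, n) {
  k <- max(3L, 2L * (length(y) %/% 100L) + 1L)  # light running-mean smoothing
  ys <- stats::filter(y, rep(1 / k, k), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  idx <- which(diff(sign(diff(ys))) < 0) + 1L
  if (length(idx) < n) idx <- unique(c(idx, order(ys, decreasing = TRUE)[seq_len(n)]))
  idx <- idx[order(ys[idx], decreasing = TRUE)]
  min_sep <- max(3L, length(y) %/% 50L)
  picked <- integer(0)
  for (i in idx) {
    if (!length(picked) || all(abs(i - picked) >= min_sep))
      picked <- c(picked, i)
    if (length(picked) == n) break
  }
  while (length(picked) < n)  # degenerate fallback: evenly spread extras
    picked <- c(picked, round(length(y) * (length(picked) + 1) / (n + 1)))
  picked
}

#' Deconvolute a spectrum into one or two Lorentzians
#'
#' Least-squares fit of a constant baseline plus `n_peaks` Lorentzian lines,
#' as used to separate the overlapping active- and inactive-state
#' resonances. Initial guesses default to the two highest local maxima; if
#' a two-peak fit collapses onto a single position it is automatically
#' re-initialized from those maxima.
#'
#' @param spectrum A [spectrum1d()].
#' @param n_peaks 1 or 2.
#' @param init Optional list of initial guesses, each a list with `center`
#'   (ppm), `fwhm` (Hz) and `amplitude`.
#' @return A list of class `lorentzian_fit` with elements `peaks` (list of
#'   [lorentzian_peak()], sorted by descending ppm), `baseline`,
#'   `converged`, `flags` (character vector of diagnostics), `residuals`
#'   and `rss`.
#' @export
fit_lorentzians <- function(spectrum, n_peaks = 2, init = NULL) {
  stopifnot(inherits(spectrum, "spectrum1d"), n_peaks %in% c(1L, 2L))
  ppm <- spectrum$ppm; y <- spectrum$intensity
  f <- spectrum$spectrometer_freq
  span <- abs(ppm[length(ppm)] - ppm[1])

  auto_init <- function() {
    pk <- .top_maxima(ppm, y, n_peaks)
    lapply(pk, function(i) list(center = ppm[i],
                                fwhm = 0.02 * span * f,
                                amplitude = max(y[i] - stats::median(y), y[i] / 2)))
  }
  if (is.null(init)) init <- auto_init()
  if (length(init) != n_peaks)
    stop("`init` must supply one guess per peak", call. = FALSE)

  pack <- function(guess) {
    c(stats::median(y),
      unlist(lapply(guess, function(g) c(g$amplitude, g$center, g$fwhm / f))))
  }
  model <- function(par) {
    out <- rep(par[1], length(ppm))
    for (j in seq_len(n_peaks)) {
      b <- 1 + 3 * (j - 1)
      out <- out + .lorentz(ppm, par[b + 2], par[b + 3], par[b + 1])
    }
    out
  }
  run <- function(par0) {
    lo <- c(-Inf, rep(c(0, min(ppm), 1e-6 * span), n_peaks))
    hi <- c(Inf, rep(c(Inf, max(ppm), 2 * span), n_peaks))
    minpack.lm::nls.lm(par = pmin(pmax(par0, lo), hi),
                       fn = function(p) y - model(p),
                       lower = lo, upper = hi,
                       control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  res <- run(pack(init))
  flags <- character(0)
  if (n_peaks == 2L) {
    centers <- res$par[c(3, 6)]
    widths_ppm <- res$par[c(4, 7)]
    if (abs(diff(centers)) < 0.25 * min(widths_ppm)) {
      flags <- c(flags, "merged initialization; re-initialized from local maxima")
      res2 <- run(pack(auto_init()))
      if (res2$deviance < res$deviance) res <- res2
    }
  }
  converged <- res$info %in% 1:3
  if (!converged) flags <- c(flags, paste0("non-convergence: ", res$message))

  peaks <- lapply(seq_len(n_peaks), function(j) {
    b <- 1 + 3 * (j - 1)
    lorentzian_peak(center = res$par[b + 2], fwhm = res$par[b + 3] * f,
                    amplitude = res$par[b + 1])
  })
  peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "center"),
                       decreasing = TRUE)]
  structure(list(peaks = peaks, baseline = res$par[1],
                 converged = converged, flags = flags,
                 residuals = res$fvec, rss = res$deviance),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian deconvolution: %d peak(s), baseline %.4g, rss %.4g%s\n",
              length(x$peaks), x$baseline, x$rss,
              if (x$converged) "" else " [NOT CONVERGED]"))
  for (p in x$peaks) print(p)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Populations from two peak integrals
#'
#' Normalizes two peak areas into state populations,
#' `p_a = area_a / (area_a + area_b)`. Scale invariant.
#'
#' @param area_a,area_b Non-negative peak areas, not both zero.
#' @return Named vector `c(p_a, p_b)` summing to one.
#' @export
populations_from_integrals <- function(area_a, area_b) {
  stopifnot(area_a >= 0, area_b >= 0)
  tot <- area_a + area_b
  if (tot == 0) stop("both areas are zero; populations undefined", call. = FALSE)
  c(p_a = area_a / tot, p_b = area_b / tot)
}

#' Trapezoidal peak integral over a ppm window
#'
#' @param spectrum A [spectrum1d()].
#' @param window Numeric length-2 ppm interval (either order) lying within
#'   the axis.
#' @param baseline_windows Optional list of ppm intervals flagged as signal
#'   free; their pooled median intensity is subtracted before integration.
#'   `NULL` (default) subtracts nothing.
#' @return Integrated area in a.u. * ppm (positive for a positive peak).
#' @export
peak_integral <- function(spectrum, window, baseline_windows = NULL) {
  stopifnot(inherits(spectrum, "spectrum1d"), length(window) == 2)
  lo <- min(window); hi <- max(window)
  if (lo < min(spectrum$ppm) || hi > max(spectrum$ppm))
    stop("`window` must lie within the spectrum axis", call. = FALSE)
  sel <- spectrum$ppm >= lo & spectrum$ppm <= hi
  if (sum(sel) < 2) stop("`window` contains fewer than two axis points", call. = FALSE)
  base <- 0
  if (!is.null(baseline_windows)) {
    vals <- unlist(lapply(baseline_windows, function(w) {
      s <- spectrum$ppm >= min(w) & spectrum$ppm <= max(w)
      spectrum$intensity[s]
    }))
    if (length(vals) == 0)
      stop("no axis points fall inside `baseline_windows`", call. = FALSE)
    base <- stats::median(vals)
  }
  x <- spectrum$ppm[sel]; yy <- spectrum$intensity[sel] - base
  o <- order(x)
  x <- x[o]; yy <- yy[o]
  sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Correct titration intensities for dilution
#'
#' When a titrant is added from a stock, the observed intensities shrink by
#' the concentration ratio; the correction multiplies each intensity by
#' `(v0 + v_added) / v0`.
#'
#' @param intensity Intensities (a.u.).
#' @param v0 Initial sample volume.
#' @param v_added Cumulative added volume (same units, >= 0).
#' @return Corrected intensities.
#' @export
dilution_correct <- function(intensity, v0, v_added) {
  stopifnot(v0 > 0, all(v_added >= 0))
  intensity * (v0 + v_added) / v0
}
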