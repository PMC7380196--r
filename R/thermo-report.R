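#' Assemble the four-state exchange network
#'
#' Combines the slow (fold-switch, inactive <-> active) equilibrium with the
#' fast (compact <-> extended) equilibria inside each manifold into a joint
#' four-state model. The fast equilibria are treated as conditionally
#' independent within each slow manifold (timescale separation: milliseconds
#' inside a manifold versus seconds between manifolds), so joint populations
#' are products of the manifold population and the within-manifold
#' population.
#'
#' @param slow A [slow_exchange_params()] object (or equivalent list).
#' @param fast_inactive,fast_active Lists with `p_compact`, `p_extended`,
#'   `k_i` and a `condition` label, as stored in [ground_truth()] or derived
#'   from a [fit_carver_richards_global()] result.
#' @param temperature Kelvin.
#' @param condition Condition label; if the fast inputs carry `condition`
#'   fields they must match.
#' @return An object of class `four_state_model` with `populations` (named
#'   vector over inactive-compact, inactive-extended, active-extended,
#'   active-compact), `slow`, `fast` and `temperature`.
#' @export
assemble_four_state_model <- function(slow, fast_inactive, fast_active,
                                      temperature = 298.15,
                                      condition = "apo") {
  for (f in list(fast_inactive, fast_active)) {
    if (!is.null(f$condition) && !identical(f$condition, condition))
      stop("mismatched condition labels in four-state assembly", call. = FALSE)
    if (abs(f$p_compact + f$p_extended - 1) > 1e-8)
      stop("fast populations must sum to 1", call. = FALSE)
  }
  p <- c(
    "inactive-compact"  = slow$p_inactive * fast_inactive$p_compact,
    "inactive-extended" = slow$p_inactive * fast_inactive$p_extended,
    "active-extended"   = slow$p_active * fast_active$p_extended,
    "active-compact"    = slow$p_active * fast_active$p_compact)
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p >= 0))
  structure(list(populations = p, slow = slow,
                 fast = list(inactive = fast_inactive, active = fast_active),
                 temperature = temperature, condition = condition),
            class = "four_state_model")
}

#' @export
print.four_state_model <- function(x, ...) {
  cat(sprintf("Four-state model (%s, %.2f K)\n", x$condition, x$temperature))
  for (s in names(x$populations))
    cat(sprintf("  %-18s p = %.4f\n", s, x$populations[[s]]))
  cat(sprintf("  slow: k_s = %.4g s^-1; fast: k_i = %.4g (inactive), %.4g (active) s^-1\n",
              x$slow$k_s, x$fast$inactive$k_i, x$fast$active$k_i))
  invisible(x)
}

#' Free-energy levels of the four states
#'
#' `dG_state = -RT ln(p_state / p_ref)` with the most populated state as the
#' zero reference, so levels order opposite to populations. States with zero
#' population are reported as `Inf` with a flag.
#'
#' @param model A [assemble_four_state_model()] result.
#' @param gas_constant kcal mol^-1 K^-1.
#' @return A data frame with columns `state`, `population`,
#'   `delta_g` (kcal mol^-1) and `unbounded`.
#' @export
free_energy_levels <- function(model, gas_constant = gas_constant_kcal) {
  stopifnot(inherits(model, "four_state_model"))
  p <- model$populations
  ref <- max(p)
  rt <- gas_constant * model$temperature
  dg <- ifelse(p > 0, -rt * log(p / ref), Inf)
  data.frame(state = names(p), population = as.numeric(p),
             delta_g = as.numeric(dg), unbounded = !(p > 0),
             row.names = NULL)
}

.round_even <- function(x, digits) round(x, digits)  # R rounds half to even

#' Render slow- and fast-exchange results tables
#'
#' Emits the two report tables in the column layout used for
#' saturation-transfer (slow) and relaxation-dispersion (fast) results:
#' chemical shift, rates, populations, `k_s`, directed free-energy
#' difference, and `|ddelta|`, each with uncertainties where available.
#' The per-state free-energy convention follows the source tables: the row
#' of state X reports the rate into X, the population of X, and
#' `dG = RT ln(p_X / p_other)` (i.e. `G_other - G_X`). Display values are
#' rounded half-to-even at the printed precision; full precision is kept in
#' the returned data frames.
#'
#' @param slow_fits Named list (by condition) of [slow_exchange_params()],
#'   optionally with `se` attributes.
#' @param fast_fits Named list (by resonance) of
#'   [fit_carver_richards_global()] results (or truth-like lists).
#' @param shifts Per-condition named shift vectors (ppm), as in
#'   [ground_truth()].
#' @param path Optional directory; when given, writes
#'   `slow_exchange_table.tsv` and `dispersion_table.tsv` there.
#' @param digits Display rounding (rates 2, populations 2, dG 3).
#' @return List with data frames `slow_table` and `fast_table` (full
#'   precision) plus `slow_display`/`fast_display` (rounded).
#' @export
render_results_tables <- function(slow_fits, fast_fits = NULL, shifts = NULL,
                                  path = NULL,
                                  digits = list(rate = 2, pop = 2, dg = 3)) {
  stopifnot(length(slow_fits) >= 1)
  rows <- list()
  for (cond in names(slow_fits)) {
    s <- slow_fits[[cond]]
    rt <- gas_constant_kcal * s$temperature
    for (state in c("active", "inactive")) {
      p_state <- if (state == "active") s$p_active else s$p_inactive
      p_other <- 1 - p_state
      k_in <- if (state == "active") s$k_mn else s$k_nm
      shift <- if (!is.null(shifts)) shifts[[cond]][[state]] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, resonance = state, chemical_shift_ppm = shift,
        k_in_s1 = k_in, p = p_state, k_s_s1 = s$k_s,
        delta_g_kcal = rt * log(p_state / p_other))
    }
  }
  slow_table <- do.call(rbind, rows)

  fast_table <- NULL
  if (!is.null(fast_fits) && length(fast_fits)) {
    rows <- list()
    for (res in names(fast_fits)) {
      g <- fast_fits[[res]]
      for (cond in g$conditions) {
        shift <- if (!is.null(shifts)) shifts[[cond]][[res]] else NA_real_
        p_minor <- g$p_minor[[cond]]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, resonance = res, chemical_shift_ppm = shift,
          k_i_s1 = g$k_i[[cond]],
          k_i_se = if (!is.null(g$k_i_se)) g$k_i_se[[cond]] else NA_real_,
          p_minor = p_minor, p_major = 1 - p_minor,
          p_minor_se = if (!is.null(g$p_minor_se)) g$p_minor_se[[cond]] else NA_real_,
          delta_delta_ppm = g$delta_delta,
          delta_delta_se = if (!is.null(g$delta_delta_se)) g$delta_delta_se else NA_real_)
      }
    }
    fast_table <- do.call(rbind, rows)
  }

  slow_display <- slow_table
  slow_display$k_in_s1 <- .round_even(slow_display$k_in_s1, digits$rate)
  slow_display$k_s_s1 <- .round_even(slow_display$k_s_s1, digits$rate)
  slow_display$p <- .round_even(slow_display$p, digits$pop)
  slow_display$delta_g_kcal <- .round_even(slow_display$delta_g_kcal, digits$dg)
  fast_display <- NULL
  if (!is.null(fast_table)) {
    fast_display <- fast_table
    fast_display$k_i_s1 <- .round_even(fast_display$k_i_s1, -2)
    fast_display$p_minor <- .round_even(fast_display$p_minor, 3)
    fast_display$p_major <- .round_even(fast_display$p_major, 3)
    fast_display$delta_delta_ppm <- .round_even(fast_display$delta_delta_ppm, 1)
  }
  out <- list(slow_table = slow_table, fast_table = fast_table,
              slow_display = slow_display, fast_display = fast_display)
  if (!is.null(path)) {
    utils::write.table(slow_table, file.path(path, "slow_exchange_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(fast_table))
      utils::write.table(fast_table, file.path(path, "dispersion_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
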