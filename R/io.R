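# ---- delimited-text formats -------------------------------------------------
# All tables are tab-separated with a block of '#'-prefixed "key: value"
# header lines followed by a column-header row. ppm values are stored signed
# with the NMR sign convention; no Hz axis is persisted.

.write_header <- function(con, keys) {
  for (k in names(keys)) cat(sprintf("# %s: %s\n", k, keys[[k]]), file = con)
}

.parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

.read_body <- function(lines, path) {
  body_at <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_at) < 2)
    stop("no data rows in ", path, call. = FALSE)
  header_row <- lines[body_at[1]]
  cols <- strsplit(header_row, "\t")[[1]]
  problems <- character(0)
  rows <- lapply(body_at[-1], function(i) {
    cells <- strsplit(lines[i], "\t")[[1]]
    if (length(cells) != length(cols)) {
      problems <<- c(problems, sprintf("line %d: expected %d cells, found %d",
                                       i, length(cols), length(cells)))
      return(NULL)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals)))
      problems <<- c(problems, sprintf("line %d: non-numeric cell '%s'",
                                       i, cells[which(is.na(vals))[1]]))
    vals
  })
  list(cols = cols, data = do.call(rbind, rows), problems = problems,
       line_numbers = body_at[-1])
}

.require_keys <- function(kv, keys, path, problems) {
  missing <- setdiff(keys, names(kv))
  if (length(missing))
    problems <- c(problems, paste0("missing header key(s): ",
                                   paste(missing, collapse = ", ")))
  problems
}

#' Write a dataset to a tab-separated intensity table
#'
#' @param dataset A [cpmg_dataset()], [saturation_series()] or
#'   [relaxation_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(dataset, "cpmg_dataset")) {
    .write_header(con, list(kind = "cpmg",
                            field_mhz = dataset$spectrometer_freq,
                            condition = dataset$condition,
                            resonance = dataset$resonance,
                            constant_time_s = format(dataset$constant_time, digits = 15),
                            reference_intensity = format(dataset$reference_intensity, digits = 15)))
    cat("nu_cpmg\tintensity\n", file = con)
    for (i in seq_along(dataset$nu_cpmg))
      cat(sprintf("%.10g\t%.10g\n", dataset$nu_cpmg[i], dataset$intensity[i]),
          file = con)
  } else if (inherits(dataset, "saturation_series")) {
    .write_header(con, list(kind = "saturation",
                            condition = dataset$condition,
                            observed = dataset$observed,
                            saturated = dataset$saturated,
                            r1_s1 = if (is.null(dataset[["r1"]])) "NA" else format(dataset[["r1"]], digits = 15),
                            r1_provenance = dataset$r1_provenance))
    cat("tau_s\tintensity\n", file = con)
    for (i in seq_along(dataset$taus))
      cat(sprintf("%.10g\t%.10g\n", dataset$taus[i], dataset$intensities[i]),
          file = con)
  } else if (inherits(dataset, "relaxation_series")) {
    .write_header(con, list(kind = "inversion",
                            condition = dataset$condition,
                            resonance = dataset$resonance))
    cat("tau_s\tintensity\n", file = con)
    for (i in seq_along(dataset$taus))
      cat(sprintf("%.10g\t%.10g\n", dataset$taus[i], dataset$intensities[i]),
          file = con)
  } else stop("unsupported dataset class", call. = FALSE)
  invisible(path)
}

#' Read a typed dataset from a tab-separated intensity table
#'
#' The header declares the dataset kind (`cpmg`, `saturation` or
#' `inversion`) together with the metadata each kind requires. All problems
#' (missing header keys, non-numeric cells, duplicate abscissae) are
#' reported at once, with line numbers.
#'
#' @param path File path.
#' @param kind Optional expected kind; defaults to the header's declaration.
#' @return A [cpmg_dataset()], [saturation_series()] or
#'   [relaxation_series()].
#' @export
read_intensity_table <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- .parse_header(lines)
  body <- .read_body(lines, path)
  problems <- body$problems
  file_kind <- kv$kind
  if (!is.null(kind) && !identical(kind, file_kind))
    problems <- c(problems, sprintf("expected kind '%s' but file declares '%s'",
                                    kind, file_kind %||% "<none>"))
  kind <- file_kind %||% kind
  if (is.null(kind)) problems <- c(problems, "missing header key(s): kind")
  x <- body$data
  if (!is.null(x)) {
    dup <- duplicated(x[, 1])
    if (any(dup))
      problems <- c(problems, sprintf("duplicate %s value at line %d",
                                      body$cols[1], body$line_numbers[which(dup)[1]]))
  }
  if (identical(kind, "cpmg"))
    problems <- .require_keys(kv, c("field_mhz", "condition", "resonance",
                                    "constant_time_s", "reference_intensity"),
                              path, problems)
  else if (identical(kind, "saturation"))
    problems <- .require_keys(kv, c("condition", "observed", "saturated"),
                              path, problems)
  else if (identical(kind, "inversion"))
    problems <- .require_keys(kv, c("condition", "resonance"), path, problems)
  else if (!is.null(kind))
    problems <- c(problems, paste0("unknown kind: ", kind))
  if (length(problems))
    stop("problems reading ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  if (kind == "cpmg") {
    cpmg_dataset(x[, 1], x[, 2],
                 spectrometer_freq = as.numeric(kv$field_mhz),
                 constant_time = as.numeric(kv$constant_time_s),
                 reference_intensity = as.numeric(kv$reference_intensity),
                 condition = kv$condition, resonance = kv$resonance)
  } else if (kind == "saturation") {
    r1 <- if (!is.null(kv$r1_s1) && kv$r1_s1 != "NA") as.numeric(kv$r1_s1) else NULL
    saturation_series(x[, 1], x[, 2], observed = kv$observed,
                      saturated = kv$saturated, condition = kv$condition,
                      r1 = r1, r1_provenance = kv$r1_provenance %||% "user")
  } else {
    relaxation_series(x[, 1], x[, 2], resonance = kv$resonance,
                      condition = kv$condition)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 1D spectrum as two-column delimited text
#'
#' @param spectrum A [spectrum1d()].
#' @param path Output path.
#' @param extra Optional named list of extra header keys (e.g. condition).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  keys <- c(list(kind = "spectrum",
                 spectrometer_freq_mhz = spectrum$spectrometer_freq), extra)
  .write_header(con, keys)
  cat("ppm\tintensity\n", file = con)
  for (i in seq_along(spectrum$ppm))
    cat(sprintf("%.10g\t%.10g\n", spectrum$ppm[i], spectrum$intensity[i]),
        file = con)
  invisible(path)
}

#' Read a two-column (ppm, intensity) spectrum
#'
#' @param path File path; the header must carry the spectrometer frequency.
#' @return A [spectrum1d()] with any extra header keys attached as
#'   attribute `header`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- .parse_header(lines)
  body <- .read_body(lines, path)
  problems <- body$problems
  if (is.null(kv$spectrometer_freq_mhz))
    problems <- c(problems, "missing header key(s): spectrometer_freq_mhz")
  if (length(problems))
    stop("problems reading ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  sp <- spectrum1d(body$data[, 1], body$data[, 2],
                   as.numeric(kv$spectrometer_freq_mhz))
  attr(sp, "header") <- kv
  sp
}

# ---- configuration ----------------------------------------------------------

.default_config <- function() {
  list(fields = c(564, 659),
       constant_time = 0.00384,
       temperature = 298.15,
       gas_constant = gas_constant_kcal,
       conditions = c("apo", "ligand"),
       resonances = list(
         active = list(shift = list(apo = -82.7, ligand = -82.6),
                       minor_state = "compact"),
         inactive = list(shift = list(apo = -84.1, ligand = -84.3),
                         minor_state = "extended")),
       noise_sigma = 0.01,
       seed = 1,
       inputs = list(cpmg = character(0), saturation = character(0),
                     inversion = character(0), spectra = character(0)))
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with spectrometer frequencies, the constant-time
#' delay, temperature, gas constant, resonance assignments per condition,
#' seeds and input paths. Every omitted key falls back to a documented
#' default, and every default used is echoed into the pipeline log.
#'
#' @param path YAML file path, or a list to validate directly.
#' @return A validated `run_config` list; the defaults that were applied
#'   are recorded in attribute `defaults_used`.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- .default_config()
  defaults_used <- setdiff(names(cfg), names(user))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$fields <- as.numeric(unlist(cfg$fields))
  if (any(cfg$fields <= 0)) stop("fields must be positive", call. = FALSE)
  if (cfg$temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (cfg$constant_time <= 0) stop("constant_time must be positive", call. = FALSE)
  for (res in names(cfg$resonances)) {
    sh <- cfg$resonances[[res]]$shift
    missing <- setdiff(cfg$conditions, names(sh))
    if (length(missing))
      stop("resonance '", res, "' lacks a shift assignment for condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(cfg, "defaults_used") <- defaults_used
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

# ---- fixture generation -----------------------------------------------------

#' Write a complete synthetic fixture to disk
#'
#' Generates every input the pipeline consumes (CPMG tables for each
#' resonance, condition and field; reciprocal saturation-transfer decays
#' and inversion-recovery series per condition; one slow-exchange 1D
#' spectrum per condition), in the same delimited-text layouts the readers
#' accept, together with a `config.yaml` and a `manifest.yaml` recording
#' the ground truth and every derived seed.
#'
#' @param truth A [ground_truth()].
#' @param dir Output directory (created if needed).
#' @param seed Master integer seed; per-file seeds are derived as
#'   `seed + k` for consecutive small offsets and recorded in the manifest.
#' @param spectra_field Field (MHz) used for the 1D spectra.
#' @return The configuration list describing the fixture, invisibly.
#' @export
generate_fixture <- function(truth, dir, seed, spectra_field = 564) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conditions <- names(truth$slow)
  resonances <- names(truth$fast)
  seeds <- list()
  k <- 0L
  next_seed <- function(name) {
    k <<- k + 1L
    seeds[[name]] <<- seed + k
    seed + k
  }
  inputs <- list(cpmg = character(0), saturation = character(0),
                 inversion = character(0), spectra = character(0))
  for (res in resonances) for (cond in conditions) for (f in truth$fields) {
    nm <- sprintf("cpmg_%s_%s_%g.tsv", res, cond, f)
    ds <- generate_cpmg_series(truth, res, cond, f,
                               seed = next_seed(nm))
    write_intensity_table(ds, file.path(dir, nm))
    inputs$cpmg <- c(inputs$cpmg, nm)
  }
  for (cond in conditions) for (obs in resonances) {
    nm <- sprintf("saturation_obs-%s_%s.tsv", obs, cond)
    ss <- generate_saturation_series(truth, obs, cond, seed = next_seed(nm))
    ss["r1"] <- list(NULL)  # the pipeline takes R1 from its own inversion-recovery fits
    ss$r1_provenance <- "pending"
    write_intensity_table(ss, file.path(dir, nm))
    inputs$saturation <- c(inputs$saturation, nm)
  }
  for (cond in conditions) for (res in resonances) {
    nm <- sprintf("inversion_%s_%s.tsv", res, cond)
    ir <- generate_inversion_recovery(truth, res, cond, seed = next_seed(nm))
    write_intensity_table(ir, file.path(dir, nm))
    inputs$inversion <- c(inputs$inversion, nm)
  }
  for (cond in conditions) {
    nm <- sprintf("spectrum_%s.tsv", cond)
    sl <- truth$slow[[cond]]
    p_active <- sl$k_mn / (sl$k_mn + sl$k_nm)
    sys <- two_site_system(
      omega_a = delta_omega_from_ppm(truth$shifts[[cond]][["active"]], spectra_field),
      omega_b = delta_omega_from_ppm(truth$shifts[[cond]][["inactive"]], spectra_field),
      p_a = p_active, k_ex = sl$k_mn + sl$k_nm,
      r2_a = truth$linewidth_r2[[cond]][["active"]],
      r2_b = truth$linewidth_r2[[cond]][["inactive"]])
    sp <- simulate_spectrum(sys, seq(-86, -80.5, by = 0.004), spectra_field)
    s <- next_seed(nm)
    if (truth$noise_sigma > 0)
      sp$intensity <- sp$intensity + withr::with_seed(
        s, stats::rnorm(length(sp$ppm), 0, truth$noise_sigma * max(sp$intensity)))
    write_spectrum(sp, file.path(dir, nm), extra = list(condition = cond))
    inputs$spectra <- c(inputs$spectra, nm)
  }
  shifts <- lapply(resonances, function(res)
    lapply(conditions, function(cond) truth$shifts[[cond]][[res]]))
  cfg <- list(fields = truth$fields,
              constant_time = truth$constant_time,
              temperature = truth$temperature,
              gas_constant = gas_constant_kcal,
              conditions = conditions,
              resonances = stats::setNames(lapply(resonances, function(res) list(
                shift = stats::setNames(lapply(conditions, function(cond)
                  truth$shifts[[cond]][[res]]), conditions),
                minor_state = truth$fast[[res]][[conditions[1]]]$minor)),
                resonances),
              noise_sigma = truth$noise_sigma,
              seed = seed,
              inputs = inputs)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(truth = .truth_as_list(truth), master_seed = seed,
                        file_seeds = seeds),
                   file.path(dir, "manifest.yaml"))
  invisible(cfg)
}

.truth_as_list <- function(truth) {
  x <- unclass(truth)
  x$shifts <- lapply(x$shifts, as.list)
  x$r1 <- lapply(x$r1, as.list)
  x$r2_0 <- lapply(x$r2_0, as.list)
  x$linewidth_r2 <- lapply(x$linewidth_r2, as.list)
  x
}

# ---- pipeline ---------------------------------------------------------------

.write_report_table <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, stamp)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes the stages `deconvolve` -> `r1` -> `saturation` -> `cpmg` ->
#' `report` in dependency order on the inputs named in the configuration.
#' Every stage logs its parameters, seeds and convergence; requesting a
#' stage whose upstream products are absent raises an error naming the
#' stage to run first. Machine-readable outputs embed the configuration
#' hash and package version and are byte-reproducible for fixed seeds.
#'
#' @param config A `run_config` (from [read_run_config()]), a path to a
#'   YAML config, or a plain list.
#' @param dir Directory holding the input files (paths in
#'   `config$inputs` are relative to it); defaults to the config file's
#'   directory when `config` is a path.
#' @param output_dir Where to write reports (default `file.path(dir,
#'   "results")`).
#' @param stages Subset of `c("deconvolve", "r1", "saturation", "cpmg",
#'   "report")`.
#' @return A list with the fitted objects, tables, the four-state models
#'   per condition, flags, and the paths written.
#' @export
run_pipeline <- function(config, dir = NULL,
                         output_dir = NULL,
                         stages = c("deconvolve", "r1", "saturation",
                                    "cpmg", "report")) {
  if (is.character(config)) {
    if (is.null(dir)) dir <- dirname(config)
    config <- read_run_config(config)
  } else if (!inherits(config, "run_config")) {
    config <- read_run_config(config)
  }
  if (is.null(dir)) dir <- "."
  if (is.null(output_dir)) output_dir <- file.path(dir, "results")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, c("deconvolve", "r1", "saturation", "cpmg",
                                "report"), several.ok = TRUE)
  stamp <- list(config_md5 = .config_hash(config),
                package_version = as.character(utils::packageVersion("fluorex")))
  log_lines <- c(sprintf("pipeline run: config_md5=%s package=fluorex %s",
                         stamp$config_md5, stamp$package_version),
                 sprintf("stages: %s", paste(stages, collapse = ", ")),
                 sprintf("seed: %s", config$seed))
  du <- attr(config, "defaults_used")
  if (length(du))
    log_lines <- c(log_lines, sprintf("defaults applied for: %s",
                                      paste(du, collapse = ", ")))
  out <- list(stamp = stamp, flags = character(0), paths = character(0))
  add_log <- function(...) log_lines <<- c(log_lines, sprintf(...))
  fail_flag <- function(msg) out$flags <<- c(out$flags, msg)

  resolve <- function(p) ifelse(file.exists(p), p, file.path(dir, p))

  # deconvolve ---------------------------------------------------------------
  if ("deconvolve" %in% stages) {
    rows <- list()
    for (p in config$inputs$spectra) {
      sp <- read_spectrum(resolve(p))
      hx <- attr(sp, "header")
      fit <- fit_lorentzians(sp, n_peaks = 2)
      if (!fit$converged) fail_flag(paste0("deconvolution not converged: ", p))
      areas <- vapply(fit$peaks, `[[`, numeric(1), "area")
      pops <- populations_from_integrals(areas[1], areas[2])
      add_log("deconvolve %s: centers %.4f/%.4f ppm, populations %.3f/%.3f, converged=%s",
              p, fit$peaks[[1]]$center, fit$peaks[[2]]$center,
              pops[1], pops[2], fit$converged)
      rows[[length(rows) + 1L]] <- data.frame(
        file = p, condition = hx$condition %||% NA_character_,
        center_1_ppm = fit$peaks[[1]]$center, center_2_ppm = fit$peaks[[2]]$center,
        fwhm_1_hz = fit$peaks[[1]]$fwhm, fwhm_2_hz = fit$peaks[[2]]$fwhm,
        area_1 = areas[1], area_2 = areas[2],
        p_1 = pops[1], p_2 = pops[2], converged = fit$converged)
    }
    if (length(rows)) {
      out$deconvolution <- do.call(rbind, rows)
      pth <- .write_report_table(out$deconvolution,
                                 file.path(output_dir, "deconvolution.tsv"), stamp)
      out$paths <- c(out$paths, pth)
    }
  }

  # r1 ------------------------------------------------------------------------
  if ("r1" %in% stages) {
    fits <- list()
    rows <- list()
    for (p in config$inputs$inversion) {
      ser <- read_intensity_table(resolve(p), kind = "inversion")
      fit <- fit_inversion_recovery(ser)
      if (!fit$converged) fail_flag(paste0("R1 fit flagged: ", p))
      fits[[paste(ser$resonance, ser$condition, sep = "/")]] <- fit
      add_log("r1 %s: R1 = %.4g +- %.2g s^-1, flags=[%s]", p, fit$r1, fit$se,
              paste(fit$flags, collapse = "; "))
      rows[[length(rows) + 1L]] <- data.frame(
        file = p, resonance = ser$resonance, condition = ser$condition,
        r1_s1 = fit$r1, se = fit$se, converged = fit$converged)
    }
    out$r1_fits <- fits
    if (length(rows)) {
      out$r1_table <- do.call(rbind, rows)
      pth <- .write_report_table(out$r1_table,
                                 file.path(output_dir, "r1_fits.tsv"), stamp)
      out$paths <- c(out$paths, pth)
    }
  }

  # saturation ---------------------------------------------------------------
  if ("saturation" %in% stages) {
    fits <- list()
    rows <- list()
    for (p in config$inputs$saturation) {
      ser <- read_intensity_table(resolve(p), kind = "saturation")
      if (is.null(ser[["r1"]])) {
        key <- paste(ser$observed, ser$condition, sep = "/")
        if (is.null(out$r1_fits[[key]]))
          stop("saturation stage needs R1 for ", key,
               "; run the 'r1' stage first", call. = FALSE)
        ser$r1 <- out$r1_fits[[key]]$r1
        ser$r1_provenance <- "fit"
      }
      fit <- fit_saturation_transfer(ser)
      if (!fit$converged) fail_flag(paste0("saturation fit flagged: ", p))
      fits[[paste(ser$observed, ser$condition, sep = "/")]] <- fit
      add_log("saturation %s: k(%s->%s) = %.4g +- %.2g s^-1 (R1 %s)",
              p, ser$observed, ser$saturated, fit$k, fit$se, fit$r1_provenance)
      rows[[length(rows) + 1L]] <- data.frame(
        file = p, observed = ser$observed, saturated = ser$saturated,
        condition = ser$condition, k_s1 = fit$k, se = fit$se,
        r1_s1 = fit$r1, r1_provenance = fit$r1_provenance,
        converged = fit$converged)
    }
    out$saturation_fits <- fits
    if (length(rows)) {
      out$saturation_table <- do.call(rbind, rows)
      pth <- .write_report_table(out$saturation_table,
                                 file.path(output_dir, "saturation_fits.tsv"),
                                 stamp)
      out$paths <- c(out$paths, pth)
    }
    # pair reciprocal experiments into slow-exchange thermodynamics
    slow <- list()
    for (cond in config$conditions) {
      k_ia_fit <- fits[[paste("inactive", cond, sep = "/")]]
      k_ai_fit <- fits[[paste("active", cond, sep = "/")]]
      if (!is.null(k_ia_fit) && !is.null(k_ai_fit)) {
        s <- derive_slow_exchange_thermo(k_ia_fit$k, k_ai_fit$k,
                                         temperature = config$temperature,
                                         gas_constant = config$gas_constant)
        attr(s, "se") <- c(k_mn = k_ia_fit$se, k_nm = k_ai_fit$se)
        slow[[cond]] <- s
        add_log("thermo %s: k_s = %.4g s^-1, p_active = %.3f, dG(A-I) = %+.3f kcal/mol",
                cond, s$k_s, s$p_active, s$delta_g$active_minus_inactive)
      }
    }
    out$slow_params <- slow
  }

  # cpmg ----------------------------------------------------------------------
  if ("cpmg" %in% stages) {
    datasets <- lapply(config$inputs$cpmg, function(p)
      read_intensity_table(resolve(p), kind = "cpmg"))
    by_res <- split(datasets,
                    vapply(datasets, `[[`, character(1), "resonance"))
    fits <- list()
    for (res in names(by_res)) {
      fit <- fit_carver_richards_global(by_res[[res]])
      fits[[res]] <- fit
      if (length(fit$flags)) fail_flag(paste0("cpmg fit '", res, "': ",
                                              paste(fit$flags, collapse = "; ")))
      add_log("cpmg %s: |ddelta| = %.3f ppm; %s", res, fit$delta_delta,
              paste(sprintf("%s: k_i=%.4g p_minor=%.4g", fit$conditions,
                            fit$k_i, fit$p_minor), collapse = "; "))
    }
    out$cpmg_fits <- fits
  }

  # report --------------------------------------------------------------------
  if ("report" %in% stages) {
    if (is.null(out$slow_params) || !length(out$slow_params))
      stop("report stage needs slow-exchange fits; run the 'saturation' stage first",
           call. = FALSE)
    if (is.null(out$cpmg_fits))
      stop("report stage needs dispersion fits; run the 'cpmg' stage first",
           call. = FALSE)
    shifts <- lapply(stats::setNames(config$conditions, config$conditions),
                     function(cond)
                       vapply(config$resonances, function(r)
                         as.numeric(r$shift[[cond]]), numeric(1)))
    tables <- render_results_tables(out$slow_params, out$cpmg_fits,
                                    shifts = shifts)
    out$slow_table_report <- tables$slow_table
    out$fast_table_report <- tables$fast_table
    p1 <- .write_report_table(tables$slow_table,
                              file.path(output_dir, "slow_exchange_table.tsv"),
                              stamp)
    p2 <- .write_report_table(tables$fast_table,
                              file.path(output_dir, "dispersion_table.tsv"),
                              stamp)
    out$paths <- c(out$paths, p1, p2)

    models <- list()
    pop_rows <- list()
    fe_rows <- list()
    for (cond in names(out$slow_params)) {
      fast <- lapply(stats::setNames(names(out$cpmg_fits), names(out$cpmg_fits)),
                     function(res) {
        g <- out$cpmg_fits[[res]]
        if (!(cond %in% g$conditions)) return(NULL)
        minor_state <- config$resonances[[res]]$minor_state
        p_minor <- g$p_minor[[cond]]
        list(k_i = g$k_i[[cond]],
             p_compact = if (minor_state == "compact") p_minor else 1 - p_minor,
             p_extended = if (minor_state == "extended") p_minor else 1 - p_minor,
             condition = cond)
      })
      if (is.null(fast$inactive) || is.null(fast$active)) next
      m <- assemble_four_state_model(out$slow_params[[cond]],
                                     fast$inactive, fast$active,
                                     temperature = config$temperature,
                                     condition = cond)
      models[[cond]] <- m
      fe <- free_energy_levels(m, gas_constant = config$gas_constant)
      add_log("four-state %s: populations %s", cond,
              paste(sprintf("%s=%.4f", names(m$populations), m$populations),
                    collapse = ", "))
      pop_rows[[length(pop_rows) + 1L]] <-
        cbind(condition = cond,
              data.frame(state = names(m$populations),
                         population = as.numeric(m$populations)))
      fe_rows[[length(fe_rows) + 1L]] <- cbind(condition = cond, fe)
    }
    out$models <- models
    if (length(pop_rows)) {
      p3 <- .write_report_table(do.call(rbind, pop_rows),
                                file.path(output_dir, "four_state_populations.tsv"),
                                stamp)
      p4 <- .write_report_table(do.call(rbind, fe_rows),
                                file.path(output_dir, "free_energy_levels.tsv"),
                                stamp)
      out$paths <- c(out$paths, p3, p4)
    }
  }

  log_lines <- c(log_lines,
                 if (length(out$flags))
                   c("flagged failures:", paste0("  ", out$flags))
                 else "no flagged failures")
  writeLines(log_lines, file.path(output_dir, "pipeline.log"))
  out$paths <- c(out$paths, file.path(output_dir, "pipeline.log"))
  out$log <- log_lines
  out$ok <- length(out$flags) == 0
  out
}
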