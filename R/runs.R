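# Reproducible run surface: a serialisable run configuration plus the
# commands the shell front-end dispatches to.  Every command writes its
# outputs together with a config echo; re-running from the echo reproduces
# the outputs byte for byte.

#' Run configuration
#'
#' Bundles the grid, finite-difference scheme, fixed atmospheric
#' assumptions, envelope source, index selection and seed for a
#' reproducible run.  Fully serialisable to JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param t_min,t_max,t_step Temperature axis, degrees C.
#' @param h_min,h_max,h_step Relative-humidity axis, percent.
#' @param delta_t,delta_h,mode Finite-difference scheme (see
#'   [fd_scheme()]).
#' @param wind_ms Wind speed, m/s.
#' @param tmrt_offset_c Mean radiant temperature excess over air
#'   temperature, degrees C.
#' @param p_kpa Pressure, kPa.
#' @param envelope `"none"`, `"synthetic"`, or a path to an envelope CSV.
#' @param indices Character vector of registry index names.
#' @param seed Integer seed for stochastic commands.
#' @return List of class `run_config`.
#' @export
run_config <- function(t_min = 0, t_max = 50, t_step = 0.5,
                       h_min = 1, h_max = 100, h_step = 1,
                       delta_t = 0.1, delta_h = 0.1, mode = "forward",
                       wind_ms = 0.5, tmrt_offset_c = 0, p_kpa = 101.325,
                       envelope = "none",
                       indices = names(hsi_registry()), seed = 1L) {
  indices <- toupper(indices)
  unknown <- setdiff(indices, names(hsi_registry()))
  if (length(unknown))
    stop("unknown index name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(indices) == 0L)
    stop("index selection must not be empty", call. = FALSE)
  cfg <- list(t_min = t_min, t_max = t_max, t_step = t_step,
              h_min = h_min, h_max = h_max, h_step = h_step,
              delta_t = delta_t, delta_h = delta_h, mode = mode,
              wind_ms = wind_ms, tmrt_offset_c = tmrt_offset_c,
              p_kpa = p_kpa, envelope = envelope, indices = indices,
              seed = as.integer(seed))
  fd_scheme(delta_t, delta_h, mode)  # validate
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

.cfg_axes <- function(config) {
  list(t = seq(config$t_min, config$t_max, by = config$t_step),
       h = seq(config$h_min, config$h_max, by = config$h_step))
}

.cfg_scheme <- function(config) {
  fd_scheme(config$delta_t, config$delta_h, config$mode)
}

.cfg_envelope <- function(config) {
  if (identical(config$envelope, "none")) NULL
  else if (identical(config$envelope, "synthetic"))
    synthetic_envelope(p_kpa = config$p_kpa)
  else read_envelope(config$envelope)
}

.echo <- function(config, out_dir, command) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir,
                                     paste0(command, "_config.json")))
}

#' Evaluate the selected indices over the configured lattice
#'
#' Writes `grid.csv` (long format: `t_c, rh_pct, index, value, defined,
#' reason`) plus a config echo.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the path of the CSV written.
#' @export
run_grid <- function(config, out_dir) {
  .echo(config, out_dir, "grid")
  ax <- .cfg_axes(config)
  grid <- expand.grid(t_c = ax$t, rh_pct = ax$h, KEEP.OUT.ATTRS = FALSE)
  state <- air_state(grid$t_c, grid$rh_pct, wind_ms = config$wind_ms,
                     tmrt_c = grid$t_c + config$tmrt_offset_c,
                     p_kpa = config$p_kpa)
  out <- do.call(rbind, lapply(config$indices, function(nm) {
    u <- hsi_index(nm)(state)
    data.frame(t_c = grid$t_c, rh_pct = grid$rh_pct, index = nm,
               value = u$value, defined = u$defined, reason = u$reason,
               stringsAsFactors = FALSE)
  }))
  path <- file.path(out_dir, "grid.csv")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  message("grid: ", length(ax$t), " x ", length(ax$h), " lattice, ",
          length(config$indices), " indices, ",
          sum(!out$defined), " undefined cells")
  invisible(path)
}

#' M fields for the selected indices
#'
#' Writes one `m_<INDEX>.csv` per index (long format, see
#' [as.data.frame.m_field()]), plus `mgrid_summary.json` with per-index
#' masked-cell counts and M at the three canonical regimes, plus a config
#' echo.
#'
#' @inheritParams run_grid
#' @return Invisibly, the paths written.
#' @export
run_mgrid <- function(config, out_dir) {
  .echo(config, out_dir, "mgrid")
  ax <- .cfg_axes(config)
  env <- .cfg_envelope(config)
  scheme <- .cfg_scheme(config)
  paths <- character(0)
  summary <- list()
  for (nm in config$indices) {
    fld <- m_grid(nm, ax$t, ax$h, scheme = scheme, envelope = env,
                  wind_ms = config$wind_ms,
                  tmrt_offset_c = config$tmrt_offset_c,
                  p_kpa = config$p_kpa)
    path <- file.path(out_dir, paste0("m_", nm, ".csv"))
    utils::write.csv(as.data.frame(fld), path, row.names = FALSE, na = "")
    paths <- c(paths, path)
    counts <- table(fld$mask)
    message("mgrid ", nm, ": ", paste(names(counts), as.integer(counts),
                                      sep = "=", collapse = " "))
    summary[[nm]] <- list(mask_counts = as.list(counts))
  }
  reg <- regime_summary(hsi_registry()[config$indices], scheme = scheme,
                        wind_ms = config$wind_ms,
                        tmrt_offset_c = config$tmrt_offset_c,
                        p_kpa = config$p_kpa)
  sj <- file.path(out_dir, "mgrid_summary.json")
  jsonlite::write_json(list(mask = summary,
                            regimes = split(reg[c("index", "m", "status")],
                                            reg$regime)),
                       sj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "string")
  invisible(c(paths, sj))
}

#' Trace isopleths for one index
#'
#' Writes `isopleth_<INDEX>.csv` with columns `index, level, branch_id,
#' point_order, t_c, rh_pct`, plus a config echo.  Levels never bracketed
#' on the grid are logged and skipped, not fatal.
#'
#' @inheritParams run_grid
#' @param index Registry index name.
#' @param levels Numeric vector of contour levels.
#' @return Invisibly, the path written.
#' @export
run_isopleth <- function(config, index, levels, out_dir) {
  index <- toupper(index)
  hsi_index(index)  # validate name
  .echo(config, out_dir, "isopleth")
  ax <- .cfg_axes(config)
  rows <- lapply(levels, function(lv) {
    iso <- withCallingHandlers(
      trace_isopleth(index, lv, ax$t, ax$h, wind_ms = config$wind_ms,
                     tmrt_offset_c = config$tmrt_offset_c,
                     p_kpa = config$p_kpa),
      warning = function(w) {
        message("isopleth ", index, " level ", lv, ": ",
                conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (nrow(iso) == 0L) return(NULL)
    data.frame(index = index, level = lv, branch_id = iso$branch,
               point_order = iso$order, t_c = iso$t_c,
               rh_pct = iso$rh_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(index = character(0), level = numeric(0),
                      branch_id = integer(0), point_order = integer(0),
                      t_c = numeric(0), rh_pct = numeric(0))
  path <- file.path(out_dir, paste0("isopleth_", index, ".csv"))
  utils::write.csv(out, path, row.names = FALSE)
  message("isopleth ", index, ": ", length(levels), " level(s), ",
          nrow(out), " points")
  invisible(path)
}

#' Run the scenario audit
#'
#' With `source = "synthetic"` generates soil-moisture-style scenarios from
#' the config seed; otherwise reads a scenario CSV (schema `t0_c, h0_pct,
#' dt_c, dq_kgkg`).  Writes `audit_changes.csv`, `audit_summary.json` and
#' a config echo.
#'
#' @inheritParams run_grid
#' @param source `"synthetic"` or a scenario CSV path.
#' @param n Number of synthetic records.
#' @param coupling_c_per_gkg Synthetic coupling, degrees C per g/kg.
#' @return Invisibly, the `hsi_audit` object.
#' @export
run_audit <- function(config, source = "synthetic", out_dir, n = 200,
                      coupling_c_per_gkg = -0.7) {
  .echo(config, out_dir, "audit")
  records <- if (identical(source, "synthetic")) {
    synthesize_soil_moisture_scenarios(n, seed = config$seed,
                                       coupling_c_per_gkg =
                                         coupling_c_per_gkg)
  } else read_scenarios(source)
  res <- audit(records, hsi_registry()[config$indices],
               p_kpa = config$p_kpa, wind_ms = config$wind_ms)
  utils::write.csv(res$changes, file.path(out_dir, "audit_changes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = res$summary, reversal_flag = res$reversal,
         seed = config$seed, n_records = nrow(records)),
    file.path(out_dir, "audit_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  message("audit: reversal=", res$reversal, ", n=", nrow(records),
          ", flagged=", sum(attr(res$changes, "flagged")))
  invisible(res)
}

#' Build a climate envelope from an observation CSV
#'
#' Reads observations (`t_c, rh_pct` columns), bins them and writes the
#' envelope CSV.
#'
#' @param obs_path Observation CSV path.
#' @param out_path Envelope CSV path to write.
#' @param bin_width Humidity bin width, percent.
#' @return Invisibly, the `climate_envelope`.
#' @export
run_envelope_build <- function(obs_path, out_path, bin_width = 1) {
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  env <- build_envelope(obs, bin_width = bin_width,
                        provenance = basename(obs_path))
  write_envelope(env, out_path)
  message("envelope: ", nrow(env), " bins from ", nrow(obs),
          " observations")
  invisible(env)
}
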