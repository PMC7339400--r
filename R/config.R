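#' Default run configuration
#'
#' The full configuration tree with every model parameter at its default:
#' sections `diagenesis` (including the layer thicknesses `h1`, `h2`),
#' `routing`, `reach`, `budget`, `sensitivity`, `forcing` and `output`. A
#' zero-configuration run is valid: every default is usable as-is.
#'
#' @return A `run_config` nested list.
#' @export
default_run_config <- function() {
  cfg <- list(
    diagenesis = c(unclass(diagenesis_params()),
                   list(h1 = 0.001, h2 = 0.1)),
    routing = unclass(routing_params()),
    reach = list(length = 20000, width = 30),
    budget = list(area_ha = 22070, years = "calendar-complete"),
    sensitivity = list(k = 100, seed = 1, alpha = 0.05),
    forcing = unclass(forcing_spec())[
      !names(unclass(forcing_spec())) %in%
        c("area_ha", "reach_length", "reach_width")],
    output = list(dir = ".", log_level = "info")
  )
  cfg$forcing$start_date <- format(cfg$forcing$start_date)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' INI-style format: `[section]` headers, `key = value` lines, `#` or `;`
#' comments, blank lines ignored. Unknown sections or keys are rejected with
#' an error naming them; values omitted from the file keep their defaults.
#' Numeric-looking values are converted to numbers.
#'
#' @param path Path to the configuration file.
#' @return A `run_config` list (defaults merged with the file's overrides).
#' @export
#' @examples
#' p <- tempfile(fileext = ".ini")
#' writeLines(c("[routing]", "v_lpoc = 0.2"), p)
#' read_run_config(p)$routing$v_lpoc
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  section <- NULL
  for (ln in seq_along(lines)) {
    raw <- sub("[#;].*$", "", lines[ln])
    txt <- trimws(raw)
    if (txt == "") next
    if (grepl("^\\[.+\\]$", txt)) {
      section <- sub("^\\[(.+)\\]$", "\\1", txt)
      if (!section %in% names(cfg)) {
        stop("unknown config section [", section, "] at line ", ln,
             call. = FALSE)
      }
      next
    }
    if (!grepl("=", txt, fixed = TRUE)) {
      stop("expected 'key = value' at line ", ln, ": ", txt, call. = FALSE)
    }
    if (is.null(section)) {
      stop("key outside any [section] at line ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", txt))
    val <- trimws(sub("^[^=]*=", "", txt))
    if (!key %in% names(cfg[[section]])) {
      stop("unknown key '", key, "' in section [", section, "] at line ", ln,
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (is.na(num)) val else num
  }
  # re-validate the parameter sections through their constructors
  params_from_config(cfg)
  cfg
}

#' Write a run configuration to a flat key-value file
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- character(0)
  for (sec in names(config)) {
    out <- c(out, paste0("[", sec, "]"))
    for (key in names(config[[sec]])) {
      out <- c(out, paste0(key, " = ", format(config[[sec]][[key]],
                                              scientific = FALSE)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param config A `run_config` list.
#' @return List with `dparams`, `rparams`, `geom`, `lgeom`, `spec` (forcing
#'   spec), `area_ha`.
#' @export
params_from_config <- function(config = default_run_config()) {
  dg <- config$diagenesis
  lgeom <- layer_geometry(h1 = dg$h1, h2 = dg$h2)
  dg <- dg[!names(dg) %in% c("h1", "h2")]
  list(
    dparams = do.call(diagenesis_params, dg),
    rparams = do.call(routing_params, config$routing),
    geom = reach_geometry(config$reach$length, config$reach$width),
    lgeom = lgeom,
    spec = do.call(forcing_spec, c(config$forcing,
                                   list(area_ha = config$budget$area_ha,
                                        reach_length = config$reach$length,
                                        reach_width = config$reach$width))),
    area_ha = config$budget$area_ha
  )
}

# write a table as CSV with doubles at 17 significant digits, so that a
# write/read round trip reproduces every value bit-exactly
write_csv_exact_ <- function(df, path) {
  df[] <- lapply(df, function(x) {
    if (is.double(x) && !inherits(x, "Date")) sprintf("%.17g", x) else x
  })
  readr::write_csv(df, path)
}

#' Write simulation outputs as CSV files
#'
#' Writes the per-step sediment/water-column state table, the interface flux
#' table (ISO-8601 date column, one column per flux), the outlet-load table,
#' and a small run manifest (`manifest.txt`: configuration hash, package
#' version, run date).
#'
#' @param sim A `carbon_simulation`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- sim$daily
  state_cols <- c("date", "lpoc", "rpoc", "doc_alloch", "doc_autoch",
                  "sed_conc", "poc_g1", "poc_g2", "poc_g3", "ch4",
                  "bed_store")
  flux_cols <- c("date", grep("^j_", names(d), value = TRUE),
                 "sed_deposition")
  outlet_cols <- c("date", grep("^out_", names(d), value = TRUE))
  files <- c(
    state = file.path(dir, "state.csv"),
    fluxes = file.path(dir, "fluxes.csv"),
    outlet = file.path(dir, "outlet.csv"),
    manifest = file.path(dir, "manifest.txt")
  )
  write_csv_exact_(d[state_cols], files[["state"]])
  write_csv_exact_(d[flux_cols], files[["fluxes"]])
  write_csv_exact_(d[outlet_cols], files[["outlet"]])
  manifest <- c(
    paste0("package_version = ",
           as.character(utils::packageVersion("bedcarbon"))),
    paste0("parameter_hash = ",
           rlang::hash(list(sim$dparams, sim$rparams, sim$geom, sim$lgeom))),
    paste0("n_days = ", nrow(d)),
    paste0("area_ha = ", sim$area_ha)
  )
  writeLines(manifest, files[["manifest"]])
  invisible(files)
}

#' Read a daily forcing CSV
#'
#' @param path CSV with the [validate_forcing()] schema.
#' @return Validated forcing tibble.
#' @export
read_forcing_csv <- function(path) {
  # base read.csv parses doubles with strtod (correctly rounded), so values
  # written by write_forcing_csv() round-trip bit-exactly
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(df), "date")
  df[num] <- lapply(df[num], as.numeric)
  validate_forcing(df)
}

#' Write a daily forcing CSV
#'
#' @param forcing Forcing tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(forcing, path) {
  write_csv_exact_(validate_forcing(forcing), path)
  invisible(path)
}
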