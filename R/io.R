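# Serialization glue: delimited-text traces with JSON metadata sidecars,
# plain-text template banks (per-template CSV plus a JSON index; a single
# self-describing directory container), YAML run configuration.

#' Write and read pressure traces as delimited text
#'
#' Traces are stored as two-column text (time \[s\], amplitude), '#'-prefixed
#' header lines, '.' decimal separator, UTF-8, with a JSON sidecar
#' (`<path>.json`) carrying `t0`, `dt`, the kind tag, units and any scalar
#' metadata. Reading restores the trace from the sidecar when present and
#' falls back to the two columns otherwise.
#'
#' @param trace A [pressure_trace()].
#' @param path Output path for the trace text file.
#' @param digits Significant digits written (default 12).
#' @return `write_trace` invisibly returns `path`; `read_trace` returns a
#'   `pressure_trace`.
#' @export
write_trace <- function(trace, path, digits = 12) {
  stopifnot(inherits(trace, "pressure_trace"))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(c("# ionoacoustic trace",
               sprintf("# kind: %s", trace$kind),
               "# columns: time [s], amplitude"), con)
  df <- as.data.frame(trace)
  utils::write.table(format(df, digits = digits, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  scalar_meta <- Filter(function(x) is.atomic(x) && length(x) <= 2,
                        trace$meta)
  jsonlite::write_json(list(t0 = trace$t0, dt = trace$dt, kind = trace$kind,
                            n_samples = length(trace$samples),
                            units = if (trace$kind == "pdelta") "Pa s" else "Pa",
                            meta = scalar_meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("time", "amplitude"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pressure_trace(info$t0, info$dt, df$amplitude, kind = info$kind,
                   meta = if (is.null(info$meta)) list() else as.list(info$meta))
  } else {
    dt <- stats::median(diff(df$time))
    pressure_trace(df$time[1], dt, df$amplitude, kind = "measurement")
  }
}

#' Template banks as plain-text directory containers
#'
#' A template bank is a directory with one CSV trace per template plus an
#' `index.json` listing names and metadata; a text-only stand-in for a
#' single-file binary container that round-trips every template exactly.
#'
#' @param templates Named list of [pressure_trace()] objects.
#' @param path Directory to create.
#' @return `write_template_bank` invisibly returns `path`;
#'   `read_template_bank` returns the named list of traces.
#' @export
write_template_bank <- function(templates, path) {
  stopifnot(is.list(templates), length(names(templates)) == length(templates))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(templates)) {
    write_trace(templates[[nm]], file.path(path, paste0(nm, ".csv")))
  }
  jsonlite::write_json(list(templates = names(templates)),
                       file.path(path, "index.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_template_bank
#' @export
read_template_bank <- function(path) {
  idx <- jsonlite::read_json(file.path(path, "index.json"),
                             simplifyVector = TRUE)
  out <- lapply(idx$templates, function(nm) {
    read_trace(file.path(path, paste0(nm, ".csv")))
  })
  names(out) <- idx$templates
  out
}

#' Run configuration
#'
#' Reads a YAML configuration with the keys used by the command-line
#' interface (`medium`, `beam`, `pulse`, `detector`, `noise`, `sweep`,
#' `seed`, ...), fills defaults, and computes a stable content hash so a
#' run's outputs can be traced back to the exact configuration and seed.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file values (flat or nested).
#' @return A list of class `run_config` with a `hash` attribute.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    medium = list(temperature = 20.1, sound_speed = NULL),
    beam = list(energy = 20, lateral = "rectangular", width = 2.5, height = 3,
                sigma_x = 5, sigma_y = 5, range_shift = 0, energy_spread = 0),
    pulse = list(shape = "rectangular", duration = 150e-9, rise_time = 0,
                 current = 4.5e-6),
    detector = list(distance = 25.4, band = NULL, filter_order = 1),
    noise = list(rms = 0.01, kind = "white"),
    sweep = list(n_durations = 24, min_duration = 50e-9, max_duration = 1e-6,
                 fraction = 0.9),
    seed = 1L
  )
  cfg <- defaults
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) {
    cfg <- merge_into(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_into(cfg, overrides)
  if (cfg$medium$temperature <= 0 || cfg$medium$temperature >= 60) {
    stop("config: medium temperature outside (0, 60) degC")
  }
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, class = "run_config", hash = hash)
}

# assemble package objects from a run_config
config_medium <- function(cfg) {
  ov <- list()
  if (!is.null(cfg$medium$sound_speed)) ov$sound_speed <- cfg$medium$sound_speed
  water_properties(cfg$medium$temperature, overrides = ov)
}

config_beam <- function(cfg) {
  lat <- if (identical(cfg$beam$lateral, "gaussian")) {
    lateral_gaussian(cfg$beam$sigma_x, cfg$beam$sigma_y)
  } else {
    lateral_rectangular(cfg$beam$width, cfg$beam$height)
  }
  beam_spec(cfg$beam$energy, lateral = lat, range_shift = cfg$beam$range_shift,
            energy_spread = cfg$beam$energy_spread)
}

config_detector <- function(cfg, beam) {
  band <- cfg$detector$band
  if (!is.null(band)) band <- as.numeric(band)
  axial_detector(beam, cfg$detector$distance, band = band,
                 filter_order = cfg$detector$filter_order)
}

config_pulse <- function(cfg, dt) {
  .make_pulse(cfg$pulse$shape, cfg$pulse$duration, dt, cfg$pulse$current,
              rise_time = cfg$pulse$rise_time)
}
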