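#' Write a per-channel histogram to delimited text
#'
#' The file format is shared by IRF histograms, autofluorescence histograms
#' and simulated outputs: a comment header recording the time base, then a
#' two-column tab-separated table `channel` (0-based index) and `count`.
#'
#' @param counts numeric per-channel counts.
#' @param path file path to write.
#' @param tb the [time_base()] the histogram lives on.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(counts, path, tb) {
  stopifnot(inherits(tb, "flim_time_base"))
  if (length(counts) != tb$n_channels)
    stop("counts length does not match the time base")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_channels=%d cycle_ns=%.10g",
                     tb$n_channels, tb$cycle_ns), con)
  writeLines("channel\tcount", con)
  writeLines(sprintf("%d\t%.10g", seq_along(counts) - 1L, counts), con)
  invisible(path)
}

#' Read a histogram file written by [write_histogram()]
#'
#' @param path file path.
#' @return a list with `counts`, and the `time_base` reconstructed from the
#'   header.
#' @export
read_histogram <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("n_channels=([0-9]+) cycle_ns=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L)
    stop("missing or malformed histogram header in ", path)
  tb <- time_base(as.integer(m[2]), as.numeric(m[3]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  if (nrow(tab) != tb$n_channels)
    stop("histogram length does not match its header in ", path)
  counts <- tab$count[order(tab$channel)]
  list(counts = counts, time_base = tb)
}

#' Write a simulation grid result with a reproducibility sidecar
#'
#' Writes the per-repeat results and the condition summaries of a
#' [run_grid()] result as tab-separated tables, plus a JSON sidecar holding
#' the full configuration (seed included) so a run can be reproduced
#' bit-exactly.
#'
#' @param grid a `flim_grid` from [run_grid()].
#' @param dir output directory (created if missing).
#' @param stem file name stem, default `"grid"`.
#' @return the directory, invisibly.
#' @export
write_grid_results <- function(grid, dir, stem = "grid") {
  stopifnot(inherits(grid, "flim_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(grid$results, file.path(dir, paste0(stem, "_results.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(grid$summary, file.path(dir, paste0(stem, "_summary.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(config_to_list(grid$config),
                       file.path(dir, paste0(stem, "_config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

## plain-list view of a simulation config (for JSON/YAML sidecars)
config_to_list <- function(config) {
  list(
    decay = list(kind = config$decay$kind, tau1_ns = config$decay$tau1_ns,
                 tau2_ns = config$decay$tau2_ns, p1 = config$decay$p1),
    n_sensor_photons = config$n_sensor_photons,
    noise = list(f_auto = config$noise$f_auto,
                 afterpulse_ratio = config$noise$afterpulse_ratio,
                 f_background = config$noise$f_background,
                 fluctuation_fraction = config$noise$fluctuation_fraction,
                 noise_scale = config$noise$noise_scale,
                 autofluor_mode = config$noise$autofluor$mode),
    detector = config$detector$name,
    time_base = list(n_channels = config$time_base$n_channels,
                     cycle_ns = config$time_base$cycle_ns),
    n_repeats = config$n_repeats,
    seed = config$seed,
    sources_enabled = as.list(config$sources_enabled),
    noise_isolation = config$noise_isolation,
    window = list(start_ns = config$window$start_ns,
                  end_ns = config$window$end_ns)
  )
}

#' Build a simulation configuration from a YAML or JSON file
#'
#' The file mirrors the fields of [simulation_config()]; unspecified fields
#' fall back to the defaults.  Used by the command-line wrapper.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a `flim_simulation_config`.
#' @export
simulation_config_from_file <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  tb <- if (!is.null(cfg$time_base))
    time_base(cfg$time_base$n_channels %||% 256L,
              cfg$time_base$cycle_ns %||% 12.5)
  else time_base()
  decay <- if (!is.null(cfg$decay))
    decay_model(cfg$decay$kind %||% "double",
                tau1_ns = cfg$decay$tau1_ns %||% 2.14,
                tau2_ns = cfg$decay$tau2_ns,
                p1 = cfg$decay$p1 %||% 0.5)
  else decay_model("double", 2.14, 0.69, 0.5)
  det <- detector_preset(cfg$detector %||% "gaasp")
  noise_args <- cfg$noise %||% list()
  noise <- noise_model(
    f_auto = noise_args$f_auto %||% 4560,
    afterpulse_ratio = noise_args$afterpulse_ratio %||% det$afterpulse_ratio,
    f_background = noise_args$f_background %||% 3484,
    fluctuation_fraction = noise_args$fluctuation_fraction %||% 0.05,
    noise_scale = noise_args$noise_scale %||% 1
  )
  src <- cfg$sources_enabled %||% list()
  simulation_config(
    decay = decay,
    n_sensor_photons = cfg$n_sensor_photons %||% 652126,
    noise = noise, detector = det, time_base = tb,
    n_repeats = cfg$n_repeats %||% 500L,
    seed = cfg$seed %||% 1L,
    sources_enabled = c(autofluor = src$autofluor %||% TRUE,
                        afterpulse = src$afterpulse %||% TRUE,
                        background = src$background %||% TRUE),
    noise_isolation = cfg$noise_isolation %||% "none"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
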