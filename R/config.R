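#' Build a run configuration
#'
#' Assembles a fully resolved, serializable configuration for a coupled
#' simulation or sensitivity run. Every unprinted constant receives an
#' explicit default here, so the configuration written next to the outputs
#' is a complete provenance record: any emitted result is reproducible
#' from it alone.
#'
#' @param mode `"field"` (weather + salinity scenario) or `"hydroponic"`
#'   (constant growth-chamber forcing).
#' @param seed Integer seed for weather generation and sampling.
#' @param season_length Days in the season.
#' @param traits Named list overriding [trait_parameters()] defaults.
#' @param aux Named list overriding [auxiliary_constants()] defaults.
#' @param host Named list overriding scalar [host_parameters()] defaults.
#' @param scenario Named list passed to [salinity_scenario()] (field
#'   mode).
#' @param hydroponic Named list with `na_mm` (and optionally `days`,
#'   `radiation`, `et0`) for hydroponic mode.
#' @param equation_modes Named list passed to [default_modes()].
#' @param sensitivity Named list with `gamma`, optional `base_n`, `cv`,
#'   `n_boot`.
#' @return An object of class `run_config` (nested named list).
#' @export
run_config <- function(mode = c("field", "hydroponic"), seed = 1,
                       season_length = 130, traits = list(),
                       aux = list(), host = list(), scenario = list(),
                       hydroponic = list(na_mm = 0),
                       equation_modes = list(),
                       sensitivity = list(gamma = 500, cv = 0.05,
                                          n_boot = 100)) {
  mode <- match.arg(mode)
  cfg <- list(
    schema_version = 1,
    mode = mode,
    seed = as.integer(seed),
    season_length = as.integer(season_length),
    traits = unclass(do.call(trait_parameters, traits)),
    aux = unclass(do.call(auxiliary_constants, aux)),
    host = utils::modifyList(host_scalar_defaults(), host),
    scenario = utils::modifyList(list(pattern = "early_peak"), scenario),
    hydroponic = utils::modifyList(list(na_mm = 0), hydroponic),
    equation_modes = utils::modifyList(
      default_modes(), equation_modes)[c("rrbf_literal", "rpn_literal",
                                         "sla_clamp", "k_sen",
                                         "retain_senescent_na")],
    sensitivity = utils::modifyList(list(gamma = 500, cv = 0.05,
                                         n_boot = 100), sensitivity)
  )
  structure(cfg, class = "run_config")
}

# scalar host parameters exposed through the configuration file; the
# tabulated SLA/partitioning curves stay programmatic
host_scalar_defaults <- function() {
  h <- host_parameters()
  h[c("tt_anthesis", "tt_maturity", "t_base", "rue", "k_ext", "kc",
      "n_layers", "plant_density", "grain_fraction")]
}

config_objects <- function(cfg) {
  list(
    params = do.call(trait_parameters, cfg$traits),
    aux = do.call(auxiliary_constants, cfg$aux),
    host = do.call(host_parameters, cfg$host),
    modes = do.call(default_modes, cfg$equation_modes)
  )
}

#' Read / write run configurations as YAML
#'
#' Configurations round-trip losslessly through YAML. Reading validates
#' the schema and reports offending field paths.
#'
#' @param cfg A [run_config()] object.
#' @param path File path.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns the path invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("schema_version", "mode", "seed", "season_length", "traits",
             "aux", "host", "scenario", "hydroponic", "equation_modes",
             "sensitivity", "config_md5")   # provenance files re-read too
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub <- function(block, allowed) {
    x <- raw[[block]] %||% list()
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown config field(s): ",
           paste(paste0(block, ".", bad), collapse = ", "), call. = FALSE)
    x
  }
  tr <- sub("traits", names(trait_parameters()))
  ax <- sub("aux", names(auxiliary_constants()))
  ho <- sub("host", names(host_scalar_defaults()))
  em <- sub("equation_modes",
            c("rrbf_literal", "rpn_literal", "sla_clamp", "k_sen",
              "retain_senescent_na"))
  cfg <- tryCatch(
    run_config(mode = raw$mode %||% "field",
               seed = raw$seed %||% 1,
               season_length = raw$season_length %||% 130,
               traits = tr, aux = ax, host = ho,
               scenario = raw$scenario %||% list(),
               hydroponic = raw$hydroponic %||% list(na_mm = 0),
               equation_modes = em,
               sensitivity = raw$sensitivity %||% list()),
    error = function(e) stop("invalid config: ", conditionMessage(e),
                             call. = FALSE))
  cfg
}

forcing_from_config <- function(cfg) {
  if (cfg$mode == "hydroponic") {
    hf <- do.call(hydroponic_forcing,
                  utils::modifyList(list(days = cfg$season_length),
                                    cfg$hydroponic))
    list(weather = hf$weather, salinity = hf$salinity)
  } else {
    sc <- do.call(salinity_scenario, cfg$scenario)
    list(weather = make_weather(cfg$season_length, cfg$seed),
         salinity = make_salinity_series(sc, cfg$season_length))
  }
}

#' Run a simulation from a configuration file
#'
#' Executes one coupled season and writes a daily output table
#' (`daily.tsv`), a summary (`summary.yaml`) and a provenance file
#' (`provenance.yaml`) echoing every resolved default plus an MD5 hash of
#' the resolved configuration.
#'
#' @param config_path Path to a YAML configuration
#'   (see [write_run_config()]).
#' @param out_dir Output directory, created if missing.
#' @return The [run_season()] result, invisibly.
#' @export
cmd_simulate <- function(config_path, out_dir = ".") {
  cfg <- read_run_config(config_path)
  obj <- config_objects(cfg)
  forcing <- forcing_from_config(cfg)
  res <- run_season(forcing$weather, forcing$salinity, params = obj$params,
                    aux = obj$aux, host = obj$host, modes = obj$modes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$daily, file.path(out_dir, "daily.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(yield = res$yield, agb = res$agb,
                        cumulative_fertility = res$cumulative_fertility,
                        plant_na_mg_ha = total_na(res$final_pools),
                        na_balance_error = res$na_balance_error),
                   file.path(out_dir, "summary.yaml"))
  write_provenance(cfg, out_dir)
  invisible(res)
}

write_provenance <- function(cfg, out_dir) {
  resolved <- file.path(out_dir, "provenance.yaml")
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), tmp, precision = 15)
  hash <- unname(tools::md5sum(tmp))
  yaml::write_yaml(c(unclass(cfg), list(config_md5 = hash)), resolved,
                   precision = 15)
  unlink(tmp)
  invisible(resolved)
}

#' Run the sensitivity / ideotyping workflow from a configuration file
#'
#' Executes sample-size rule, Saltelli sampling, the batch of season
#' simulations, Sobol' index estimation and ideotype extraction, and
#' writes `sobol_indices.tsv`, `ideotype.tsv` and a provenance file.
#'
#' @inheritParams cmd_simulate
#' @param base_n Optional base sample size overriding the sample-size
#'   rule (must be a power of two).
#' @return The [run_sensitivity()] result, invisibly.
#' @export
cmd_sensitivity <- function(config_path, out_dir = ".", base_n = NULL) {
  cfg <- read_run_config(config_path)
  obj <- config_objects(cfg)
  sc <- do.call(salinity_scenario, cfg$scenario)
  dists <- trait_distributions(obj$params,
                               cv = cfg$sensitivity$cv %||% 0.05)
  res <- run_sensitivity(sc, seed = cfg$seed,
                         gamma = cfg$sensitivity$gamma %||% 500,
                         base_n = base_n %||% cfg$sensitivity$base_n,
                         season_length = cfg$season_length,
                         dists = dists, aux = obj$aux, host = obj$host,
                         modes = obj$modes,
                         n_boot = cfg$sensitivity$n_boot %||% 100)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$sobol$indices,
                     file.path(out_dir, "sobol_indices.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ide <- data.frame(name = names(res$ideotype),
                    value = as.numeric(res$ideotype))
  utils::write.table(ide, file.path(out_dir, "ideotype.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_provenance(cfg, out_dir)
  if (res$sobol$degenerate)
    warning("output variance is zero: Sobol' indices are undefined",
            call. = FALSE)
  invisible(res)
}

#' Evaluate a simulated series against observations
#'
#' Reads a delimited two-column numeric file (header optional; columns
#' observed, simulated) and computes RRMSE, modelling efficiency, CRM and
#' R^2. Non-numeric rows are rejected with their line numbers.
#'
#' @param path Path to the paired file (tab, comma or whitespace
#'   separated).
#' @return Named list of the four statistics.
#' @export
cmd_evaluate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input file", call. = FALSE)
  parse_row <- function(s) as.numeric(strsplit(trimws(s), "[,\t ]+")[[1]])
  first <- suppressWarnings(parse_row(lines[1]))
  start <- if (any(is.na(first))) 2L else 1L   # header line
  if (start > length(lines))
    stop("no data rows in input file", call. = FALSE)
  rows <- suppressWarnings(lapply(lines[start:length(lines)], parse_row))
  bad <- which(vapply(rows, function(r) length(r) < 2 || any(is.na(r[1:2])),
                      logical(1)))
  if (length(bad))
    stop("non-numeric or short row(s) at line(s): ",
         paste(bad + start - 1L, collapse = ", "), call. = FALSE)
  obs <- vapply(rows, `[`, numeric(1), 1)
  sim <- vapply(rows, `[`, numeric(1), 2)
  evaluate_series(obs, sim)
}

#' Write scenario forcing files from a configuration
#'
#' Materializes the weather and salinity series implied by a
#' configuration as the delimited files read back by [read_weather()] /
#' [read_salinity()].
#'
#' @inheritParams cmd_simulate
#' @return Paths of the written files, invisibly.
#' @export
cmd_make_scenario <- function(config_path, out_dir = ".") {
  cfg <- read_run_config(config_path)
  forcing <- forcing_from_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wp <- file.path(out_dir, "weather.tsv")
  sp <- file.path(out_dir, "salinity.tsv")
  write_weather(forcing$weather, wp)
  write_salinity(forcing$salinity, sp)
  invisible(c(weather = wp, salinity = sp))
}
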