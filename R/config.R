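#' Default full configuration
#'
#' The complete configuration tree with the model's standard constants:
#' energy block (E_a = 3 kT, A = 3.5, B = -12 kT nm, C = 5.2 kT,
#' r_max = 150 nm, forward rates 10/10/1 1/s, dt = 10 ms), simulation block
#' (1000 integrins on a 100 x 100 grid of 60 nm sites), sweep block
#' (scenarios, pore sizes, replicates) and substrate block (Cahn-Hilliard
#' generator settings).
#'
#' @return A nested named list of class `npg_config`.
#' @export
default_config <- function() {
  structure(list(
    energy = list(E_a = 3, A = 3.5, B = -12, C = 5.2, r_max = 150,
                  alpha = 1, beta = 1, k_a_plus = 10, k_b_plus = 10,
                  k_c_plus = 1, dt = 0.010),
    simulation = list(n_integrins = 1000, n_rows = 100, n_cols = 100,
                      site_spacing_nm = 60, c_mode = "uniform",
                      hop_prob = 1, max_steps = 2e5, min_steps = 1e5,
                      equil_window = 5000,
                      equil_tolerance = 1e-3, checkpoint_every = 100),
    sweep = list(scenarios = c("baseline"),
                 pore_sizes_nm = c(20, 50, 75, 100, 150),
                 include_flat = TRUE, n_replicates = 10, base_seed = 1,
                 measure_samples = 20, measure_every = 5000),
    substrate = list(mean_composition = 0.5, mobility = 1, kappa = 1,
                     dt_ch = 0.5, noise_amplitude = 0.05, size_px = 256,
                     min_feature_px = 8, seed = 1)
  ), class = "npg_config")
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON — a subset of YAML) configuration, fills every
#' missing entry with the defaults of [default_config()], rejects unknown
#' keys by name, and validates values. An empty file yields the full default
#' configuration.
#'
#' @param path path to the configuration file.
#' @return A validated `npg_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(user)
}

#' Build a configuration from overrides
#'
#' @param user nested named list of overrides (may be empty).
#' @return A validated `npg_config` list.
#' @export
merge_config <- function(user = list()) {
  cfg <- unclass(default_config())
  for (block in names(user)) {
    if (!block %in% names(cfg)) {
      stop(sprintf("unknown configuration block: `%s`", block), call. = FALSE)
    }
    for (key in names(user[[block]])) {
      if (!key %in% names(cfg[[block]])) {
        stop(sprintf("unknown configuration key: `%s$%s`", block, key),
             call. = FALSE)
      }
      cfg[[block]][[key]] <- user[[block]][[key]]
    }
  }
  validate_config(structure(cfg, class = "npg_config"))
}

validate_config <- function(cfg) {
  en <- cfg$energy
  must_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop(sprintf("configuration key `%s` must be a positive number", name),
           call. = FALSE)
    }
  }
  must_pos(en$dt, "energy$dt")
  must_pos(en$r_max, "energy$r_max")
  must_pos(en$k_a_plus, "energy$k_a_plus")
  must_pos(en$k_b_plus, "energy$k_b_plus")
  must_pos(en$k_c_plus, "energy$k_c_plus")
  sim <- cfg$simulation
  must_pos(sim$site_spacing_nm, "simulation$site_spacing_nm")
  must_pos(sim$max_steps, "simulation$max_steps")
  if (sim$n_integrins > sim$n_rows * sim$n_cols) {
    stop("configuration: more integrins than lattice sites", call. = FALSE)
  }
  if (!sim$c_mode %in% c("uniform", "field")) {
    stop("configuration key `simulation$c_mode` must be \"uniform\" or \"field\"",
         call. = FALSE)
  }
  sw <- cfg$sweep
  if (sw$n_replicates < 1) {
    stop("configuration key `sweep$n_replicates` must be at least 1",
         call. = FALSE)
  }
  bad <- setdiff(sw$scenarios, c("baseline", "constant_association",
                                 "weak_coupling", "strong_coupling"))
  if (length(bad)) {
    stop(sprintf("unknown scenario preset(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  sb <- cfg$substrate
  if (sb$mean_composition <= 0 || sb$mean_composition >= 1) {
    stop("configuration key `substrate$mean_composition` must lie in (0, 1)",
         call. = FALSE)
  }
  cfg
}

#' Write a configuration to YAML
#'
#' Round-trips with [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param cfg an `npg_config` list.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full pipeline: substrate, sweep, report
#'
#' Executes the configured study end to end: generates the Cahn-Hilliard
#' substrate if the concentration mode is `"field"`, runs the scenario x
#' pore-size sweep, and writes all artifacts to `out_dir`: per-run and
#' aggregated sweep CSVs, the configuration echo (YAML), and a JSON manifest
#' listing every output file with its MD5 checksum, the seeds used and the
#' package version. Re-running with the same configuration reproduces
#' identical CSVs.
#'
#' @param cfg an `npg_config` list (see [load_config()], [merge_config()]).
#' @param out_dir output directory, created if missing.
#' @param .progress print one line per completed run.
#' @return The manifest list, invisibly. A warning is raised if any run
#'   failed to equilibrate within the step budget.
#' @export
run_pipeline <- function(cfg, out_dir, .progress = FALSE) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 error = function(e) FALSE)
  if (!isTRUE(ok)) stop(sprintf("output directory not writable: %s", out_dir),
                        call. = FALSE)
  unlink(probe)

  sim <- cfg$simulation
  config_args <- list(n_integrins = sim$n_integrins, n_rows = sim$n_rows,
                      n_cols = sim$n_cols,
                      site_spacing_nm = sim$site_spacing_nm,
                      hop_prob = sim$hop_prob, max_steps = sim$max_steps,
                      min_steps = sim$min_steps,
                      equil_window = sim$equil_window,
                      equil_tolerance = sim$equil_tolerance,
                      checkpoint_every = sim$checkpoint_every,
                      c_mode = sim$c_mode)
  files <- character()

  if (sim$c_mode == "field") {
    sb <- cfg$substrate
    field <- generate_npg_field(
      seed = sb$seed, target_length_nm = min(cfg$sweep$pore_sizes_nm),
      params = ch_params(sb$mean_composition, sb$mobility, sb$kappa,
                         sb$dt_ch, sb$noise_amplitude),
      size_px = sb$size_px, min_feature_px = sb$min_feature_px)
    field_path <- file.path(out_dir, "substrate_field.csv")
    write_field(field, field_path)
    files <- c(files, field_path, paste0(field_path, ".json"))
    config_args$substrate <- field
  }

  sweep <- sweep_scenarios(
    scenarios = cfg$sweep$scenarios,
    pore_sizes_nm = cfg$sweep$pore_sizes_nm,
    include_flat = cfg$sweep$include_flat,
    n_replicates = cfg$sweep$n_replicates,
    base_seed = cfg$sweep$base_seed,
    config_args = config_args,
    measure_samples = cfg$sweep$measure_samples,
    measure_every = cfg$sweep$measure_every, .progress = .progress)

  runs_path <- file.path(out_dir, "sweep_runs.csv")
  utils::write.csv(as.data.frame(sweep), runs_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "sweep_summary.csv")
  utils::write.csv(as.data.frame(summarize_sweep(sweep)), summary_path,
                   row.names = FALSE)
  cfg_path <- file.path(out_dir, "config_echo.yaml")
  write_config(cfg, cfg_path)
  files <- c(files, runs_path, summary_path, cfg_path)

  n_noneq <- sum(!sweep$equilibrated)
  if (n_noneq > 0) {
    warning(sprintf("%d of %d runs did not equilibrate within max_steps",
                    n_noneq, nrow(sweep)), call. = FALSE)
  }

  manifest <- list(
    package = "npgclust",
    version = as.character(utils::packageVersion("npgclust")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = unique(sweep$seed),
    n_runs = nrow(sweep),
    n_not_equilibrated = n_noneq,
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
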