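#' Simulation configuration for the membrane lattice
#'
#' The membrane is a square patch divided into `n_rows` x `n_cols` sites
#' with periodic boundaries (defaults: 100 x 100 sites of 60 nm, a 6 x 6 um
#' patch). Every site carries exactly one ECM ligand; at most one integrin
#' occupies a site. `n_integrins` receptors are placed uniformly at random
#' and evolve by the activation / binding / association ladder plus nearest-
#' neighbour diffusion.
#'
#' @param n_integrins number of integrins (default 1000).
#' @param n_rows,n_cols lattice dimensions (default 100 x 100).
#' @param site_spacing_nm lattice constant in nm (default 60).
#' @param pore_nm pore size of the substrate in nm; `Inf` selects the flat
#'   gold control (binding loses its pore term, association takes its
#'   r_max value).
#' @param c_mode `"uniform"` (gold concentration 1 at every site — a
#'   dealloyed NPG surface is pure gold) or `"field"` (per-site concentration
#'   sampled from a [substrate_field()]).
#' @param substrate a [substrate_field()]; required for `c_mode = "field"`.
#' @param scenario preset name passed to [scenario_params()].
#' @param enable_binding,enable_association channel switches; disabling a
#'   channel removes its forward rate (used for closed-form calibration runs).
#' @param hop_prob probability that a non-associated integrin that fired no
#'   reaction attempts a diffusion hop (default 1: one attempt per step).
#' @param max_steps cap on Monte Carlo steps (default 2e5).
#' @param min_steps floor on Monte Carlo steps before the equilibrium
#'   detector may stop the run (default 0). The associated *count* plateaus
#'   within a few thousand steps, but the cluster-*size* distribution keeps
#'   relaxing on the much slower disassociation timescale 1/k_c- (tens of
#'   thousands of steps); set a floor of order 1/(k_c- dt) when cluster
#'   sizes are the observable.
#' @param equil_window trailing window, in steps, over which the slope of
#'   the associated count is measured (default 5000).
#' @param equil_tolerance relative slope threshold: equilibrium is declared
#'   when |slope| x 1000 steps / mean associated count falls below this
#'   (default 1e-3).
#' @param checkpoint_every record state counts every this many steps.
#' @param seed integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_integrins = 1000, n_rows = 100, n_cols = 100,
                       site_spacing_nm = 60, pore_nm = 150,
                       c_mode = c("uniform", "field"), substrate = NULL,
                       scenario = "baseline",
                       enable_binding = TRUE, enable_association = TRUE,
                       hop_prob = 1, max_steps = 2e5, min_steps = 0,
                       equil_window = 5000,
                       equil_tolerance = 1e-3, checkpoint_every = 100,
                       seed = 1) {
  c_mode <- match.arg(c_mode)
  if (n_integrins < 0) stop("`n_integrins` must be non-negative", call. = FALSE)
  if (n_integrins > n_rows * n_cols) {
    stop(sprintf("cannot place %d integrins on %d sites (one per site)",
                 n_integrins, n_rows * n_cols), call. = FALSE)
  }
  if (pore_nm <= 0) stop("`pore_nm` must be positive (Inf = flat gold)",
                         call. = FALSE)
  if (c_mode == "field" && !inherits(substrate, "substrate_field")) {
    stop("`c_mode = \"field\"` requires a substrate_field", call. = FALSE)
  }
  if (equil_window >= max_steps) {
    stop("`equil_window` must be smaller than `max_steps`", call. = FALSE)
  }
  structure(
    list(n_integrins = n_integrins, n_rows = n_rows, n_cols = n_cols,
         site_spacing_nm = site_spacing_nm, pore_nm = pore_nm,
         c_mode = c_mode, substrate = substrate, scenario = scenario,
         enable_binding = enable_binding,
         enable_association = enable_association,
         hop_prob = hop_prob, max_steps = max_steps, min_steps = min_steps,
         equil_window = equil_window, equil_tolerance = equil_tolerance,
         checkpoint_every = checkpoint_every, seed = seed),
    class = "sim_config"
  )
}

#' Project a substrate field onto the membrane lattice
#'
#' Each 60 nm lattice site receives the mean gold concentration of the field
#' pixels it covers. The generated fields are periodic, so a field smaller
#' than the 6 um membrane is tiled periodically across it (`tile = FALSE`
#' restores the strict requirement that the field cover the membrane).
#'
#' @param field a [substrate_field()].
#' @param n_rows,n_cols lattice dimensions.
#' @param site_spacing_nm lattice constant in nm.
#' @param tile tile a small periodic field across the membrane (default TRUE).
#' @return `n_rows` x `n_cols` matrix of per-site gold fractions in \[0, 1\].
#' @export
map_substrate_to_lattice <- function(field, n_rows = 100, n_cols = 100,
                                     site_spacing_nm = 60, tile = TRUE) {
  px <- field$pixel_size
  m <- pmin(pmax(field$concentration, 0), 1)
  extent_r <- n_rows * site_spacing_nm
  extent_c <- n_cols * site_spacing_nm
  if (!tile && (nrow(m) * px < extent_r || ncol(m) * px < extent_c)) {
    stop("substrate field does not cover the membrane; enable `tile` or use a larger field",
         call. = FALSE)
  }
  site_means_1d <- function(n_sites, extent, npx) {
    n_tot <- ceiling(extent / px) # pixels spanning the membrane, tiled
    centers <- (seq_len(n_tot) - 0.5) * px
    grp <- pmin(floor(centers / site_spacing_nm) + 1, n_sites)
    idx <- ((seq_len(n_tot) - 1) %% npx) + 1
    list(grp = grp, idx = idx)
  }
  rr <- site_means_1d(n_rows, extent_r, nrow(m))
  cc <- site_means_1d(n_cols, extent_c, ncol(m))
  a <- rowsum(m[rr$idx, cc$idx, drop = FALSE], rr$grp) /
    as.vector(table(rr$grp))
  b <- t(rowsum(t(a), cc$grp) / as.vector(table(cc$grp)))
  unname(b)
}

# per-site reaction rates derived from the energy model
site_rates <- function(config, params) {
  constant_mode <- isTRUE(attr(params, "ec_constant"))
  site_c <- if (config$c_mode == "uniform") {
    matrix(1, config$n_rows, config$n_cols)
  } else {
    map_substrate_to_lattice(config$substrate, config$n_rows, config$n_cols,
                             config$site_spacing_nm)
  }
  e_b <- binding_energy(config$pore_nm, site_c, params)
  e_c <- association_energy(config$pore_nm, site_c, params,
                            constant_mode = constant_mode)
  list(
    site_c = site_c,
    k_aplus = params$k_a_plus,
    k_aminus = reverse_rate(params$k_a_plus, params$E_a, "favors_reverse"),
    k_bplus = if (config$enable_binding) params$k_b_plus else 0,
    k_bminus = reverse_rate(params$k_b_plus, e_b, "favors_forward"),
    k_cplus = if (config$enable_association) params$k_c_plus else 0,
    k_cminus = reverse_rate(params$k_c_plus, e_c, "favors_forward")
  )
}

#' Place integrins on the lattice
#'
#' Integrins are placed uniformly at random on distinct sites, all in the
#' INACTIVE state. Placement is bit-identical for a fixed `config$seed`
#' (the seed also drives the subsequent trajectory).
#'
#' @param config a [sim_config()].
#' @return An object of class `lattice_state`: occupancy matrix, integrin
#'   table (id, row, col, state), per-site gold concentration, config echo.
#' @export
initialize_lattice <- function(config) {
  set.seed(config$seed)
  n_sites <- config$n_rows * config$n_cols
  sites <- sample.int(n_sites, config$n_integrins)
  # sites are 1-based column-major over (row, col)
  row0 <- (sites - 1) %% config$n_rows
  col0 <- (sites - 1) %/% config$n_rows
  occ <- integer(n_sites)
  occ[row0 * config$n_cols + col0 + 1] <- seq_len(config$n_integrins)
  structure(
    list(n_rows = config$n_rows, n_cols = config$n_cols,
         occ = occ, row = as.integer(row0), col = as.integer(col0),
         state = integer(config$n_integrins),
         config = config),
    class = "lattice_state"
  )
}

state_labels <- c("inactive", "active", "bound", "associated")

#' @export
print.lattice_state <- function(x, ...) {
  counts <- tabulate(x$state + 1L, 4L)
  cat(sprintf("<lattice_state> %d x %d sites, %d integrins\n",
              x$n_rows, x$n_cols, length(x$state)))
  cat(sprintf("  %s\n", paste(sprintf("%s: %d", state_labels, counts),
                              collapse = ", ")))
  invisible(x)
}

#' Integrin table of a lattice state
#'
#' @param x a `lattice_state`.
#' @param ... unused.
#' @return A tibble with one row per integrin: id, row, col (1-based),
#'   state label.
#' @export
tidy.lattice_state <- function(x, ...) {
  tibble::tibble(id = seq_along(x$state), row = x$row + 1L, col = x$col + 1L,
                 state = factor(state_labels[x$state + 1L],
                                levels = state_labels))
}

#' Advance a lattice state by fixed-time-step Monte Carlo
#'
#' Runs `n_steps` sweeps of the engine. Randomness continues from R's
#' current RNG stream; call `set.seed()` (or use [run_to_equilibrium()],
#' which seeds from the config) for reproducibility.
#'
#' @param state a `lattice_state` from [initialize_lattice()].
#' @param params an [energy_params()] or [scenario_params()] object.
#' @param n_steps number of Monte Carlo steps.
#' @param rates precomputed site rates (internal use).
#' @return The advanced `lattice_state`, with a `checkpoints` attribute
#'   holding the recorded state counts.
#' @export
mc_steps <- function(state, params, n_steps, rates = NULL) {
  config <- state$config
  if (is.null(rates)) rates <- site_rates(config, params)
  res <- .engine_run(state$occ, state$row, state$col, state$state,
                     config$n_rows, config$n_cols,
                     rates$k_aplus, rates$k_aminus, rates$k_bplus,
                     as.numeric(t(rates$k_bminus)), rates$k_cplus,
                     as.numeric(t(rates$k_cminus)),
                     params$dt, config$hop_prob, as.integer(n_steps),
                     as.integer(config$checkpoint_every))
  state$occ <- res$occ
  state$row <- res$row
  state$col <- res$col
  state$state <- res$state
  chk <- res$checkpoints
  colnames(chk) <- c("step", "n_inactive", "n_active", "n_bound",
                     "n_associated")
  attr(state, "checkpoints") <- tibble::as_tibble(chk)
  state
}

#' Run a simulation to equilibrium
#'
#' Advances the lattice in chunks, recording state counts every
#' `checkpoint_every` steps, until the least-squares slope of the associated
#' count over the trailing `equil_window` steps falls below
#' `equil_tolerance` (relative change per 1000 steps), or `max_steps` is
#' reached — in which case the trajectory is flagged non-equilibrated rather
#' than silently accepted.
#'
#' @param config a [sim_config()].
#' @param params an [energy_params()] object; defaults to the config's
#'   scenario preset.
#' @return An object of class `mc_trajectory`: checkpoint tibble, final
#'   `lattice_state`, equilibration flag, steps run, final slope, config.
#' @export
run_to_equilibrium <- function(config, params = NULL) {
  if (is.null(params)) params <- scenario_params(config$scenario)
  state <- initialize_lattice(config) # seeds the RNG
  rates <- site_rates(config, params)
  if (config$n_integrins == 0) {
    return(structure(
      list(checkpoints = tibble::tibble(step = integer(), n_inactive = integer(),
                                        n_active = integer(), n_bound = integer(),
                                        n_associated = integer()),
           state = state, equilibrated = TRUE, steps = 0L, slope = 0,
           config = config, params = params),
      class = "mc_trajectory"))
  }
  chunk <- config$equil_window
  checkpoints <- vector("list", ceiling(config$max_steps / chunk))
  steps_done <- 0L
  i <- 0L
  equilibrated <- FALSE
  rel_slope <- NA_real_
  while (steps_done < config$max_steps) {
    n_now <- min(chunk, config$max_steps - steps_done)
    state <- mc_steps(state, params, n_now, rates = rates)
    i <- i + 1L
    chk <- attr(state, "checkpoints")
    chk$step <- chk$step + steps_done
    checkpoints[[i]] <- chk
    steps_done <- steps_done + n_now
    if (steps_done >= config$min_steps && steps_done >= config$equil_window) {
      traj <- dplyr::bind_rows(checkpoints[seq_len(i)])
      tail_chk <- traj[traj$step > steps_done - config$equil_window, ]
      rel_slope <- trailing_rel_slope(tail_chk$step, tail_chk$n_associated)
      if (is.finite(rel_slope) && rel_slope < config$equil_tolerance) {
        equilibrated <- TRUE
        break
      }
    }
  }
  structure(
    list(checkpoints = dplyr::bind_rows(checkpoints[seq_len(i)]),
         state = state, equilibrated = equilibrated, steps = steps_done,
         slope = rel_slope, config = config, params = params),
    class = "mc_trajectory"
  )
}

# |OLS slope| of count vs step, expressed as relative change per 1000 steps
trailing_rel_slope <- function(step, count) {
  if (length(step) < 3) return(Inf)
  sx <- step - mean(step)
  slope <- sum(sx * count) / sum(sx^2)
  abs(slope) * 1000 / max(mean(count), 1)
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("<mc_trajectory> %d steps (%s), %d integrins\n", x$steps,
              if (x$equilibrated) "equilibrated" else "NOT equilibrated",
              length(x$state$state)))
  if (nrow(x$checkpoints)) {
    last <- x$checkpoints[nrow(x$checkpoints), ]
    cat(sprintf("  final counts: inactive %d, active %d, bound %d, associated %d\n",
                last$n_inactive, last$n_active, last$n_bound,
                last$n_associated))
  }
  invisible(x)
}

#' Checkpoint table of a trajectory
#' @param x an `mc_trajectory`.
#' @param ... unused.
#' @return Tibble of (step, n_inactive, n_active, n_bound, n_associated).
#' @export
tidy.mc_trajectory <- function(x, ...) x$checkpoints

#' Write a trajectory to plain-text files
#'
#' Writes `checkpoints.csv` (step and state counts), `final_state.csv`
#' (id, row, col, state per integrin) and `run_manifest.json` (seed,
#' configuration echo, equilibration outcome, package version) into a
#' directory.
#'
#' @param traj an `mc_trajectory`.
#' @param dir output directory, created if missing.
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(traj$checkpoints),
                   file.path(dir, "checkpoints.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(tidy.lattice_state(traj$state)),
                   file.path(dir, "final_state.csv"), row.names = FALSE)
  cfg <- traj$config
  cfg$substrate <- if (is.null(cfg$substrate)) NULL else "substrate_field"
  manifest <- list(
    package = "npgclust",
    version = as.character(utils::packageVersion("npgclust")),
    seed = traj$config$seed,
    steps = traj$steps,
    equilibrated = traj$equilibrated,
    rel_slope = traj$slope,
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' One-row summary of a trajectory
#' @param x an `mc_trajectory`.
#' @param ... unused.
#' @return Tibble with steps run, equilibration flag, final slope and
#'   final state counts.
#' @export
glance.mc_trajectory <- function(x, ...) {
  last <- if (nrow(x$checkpoints)) x$checkpoints[nrow(x$checkpoints), ] else
    tibble::tibble(n_inactive = NA_integer_, n_active = NA_integer_,
                   n_bound = NA_integer_, n_associated = NA_integer_)
  tibble::tibble(steps = x$steps, equilibrated = x$equilibrated,
                 rel_slope = x$slope, n_inactive = last$n_inactive,
                 n_active = last$n_active, n_bound = last$n_bound,
                 n_associated = last$n_associated)
}
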