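#' Find integrin clusters on the lattice
#'
#' Clusters are connected components of ASSOCIATED integrins under 4-neighbour
#' (von Neumann) adjacency on the periodic lattice — the same neighbourhood
#' the association move uses. Singleton components are excluded (the engine's
#' orphan-cleanup rule guarantees none survive a step, but the exclusion is
#' enforced here too so the function is safe on hand-built states).
#'
#' @param state a `lattice_state`.
#' @return A list of integer vectors, each the integrin ids of one cluster
#'   (size >= 2); empty list if nothing is associated.
#' @export
find_clusters <- function(state) {
  assoc <- which(state$state == 3L)
  if (length(assoc) < 2) return(list())
  nr <- state$n_rows
  nc <- state$n_cols
  site <- state$row[assoc] * nc + state$col[assoc] # 0-based row-major
  site_of <- integer(nr * nc)
  site_of[site + 1L] <- seq_along(assoc)
  r <- state$row[assoc]
  cc <- state$col[assoc]
  # edges to the wrapped right and down neighbours (each adjacency once)
  nb_right <- site_of[(r * nc + (cc + 1L) %% nc) + 1L]
  nb_down <- site_of[(((r + 1L) %% nr) * nc + cc) + 1L]
  from <- c(seq_along(assoc)[nb_right > 0], seq_along(assoc)[nb_down > 0])
  to <- c(nb_right[nb_right > 0], nb_down[nb_down > 0])
  g <- igraph::make_empty_graph(n = length(assoc), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  lapply(keep, function(k) assoc[comp$membership == k])
}

#' Summarise clusters into focal-adhesion statistics
#'
#' The area of a focal adhesion is taken as the number of integrins in a
#' cluster. The headline statistic is the mean area over the largest decile
#' of clusters: the top `ceiling(0.10 * n_clusters)` clusters by size
#' (stable order under ties), so any non-empty cluster set contributes at
#' least one cluster.
#'
#' @param clusters a list of clusters from [find_clusters()].
#' @return A one-row tibble: `n_clustered` (integrins in clusters),
#'   `n_clusters`, `mean_fa_area_top10`, `mean_cluster_size`,
#'   `max_cluster_size`, and `cluster_sizes` (list-column). Empty input
#'   yields zeros with `empty = TRUE`.
#' @export
summarize_clusters <- function(clusters) {
  sizes <- vapply(clusters, length, integer(1))
  if (length(sizes) == 0) {
    return(tibble::tibble(n_clustered = 0L, n_clusters = 0L,
                          mean_fa_area_top10 = 0, mean_cluster_size = 0,
                          max_cluster_size = 0L,
                          cluster_sizes = list(integer()), empty = TRUE))
  }
  k <- ceiling(0.10 * length(sizes))
  top <- sort(sizes, decreasing = TRUE, method = "radix")[seq_len(k)]
  tibble::tibble(n_clustered = sum(sizes), n_clusters = length(sizes),
                 mean_fa_area_top10 = mean(top),
                 mean_cluster_size = mean(sizes),
                 max_cluster_size = max(sizes),
                 cluster_sizes = list(sizes), empty = FALSE)
}

#' Time-averaged cluster statistics at equilibrium
#'
#' Continues a trajectory from its final state and samples the cluster
#' summary every `every` steps, `n_samples` times. The top-decile
#' focal-adhesion area is a heavy-tailed statistic of the few largest
#' clusters, so a single end-state snapshot is noisy; averaging snapshots
#' along the equilibrated trajectory is the standard Monte Carlo estimator.
#' Randomness continues from R's current RNG stream, so a seeded
#' [run_to_equilibrium()] followed by this measurement is reproducible
#' end to end.
#'
#' @param traj an `mc_trajectory` from [run_to_equilibrium()].
#' @param n_samples number of snapshots (default 20).
#' @param every steps between snapshots (default 5000).
#' @return A tibble with one row per snapshot (sample, step, n_clustered,
#'   n_clusters, mean_fa_area_top10), with the advanced `lattice_state` in
#'   attribute `"state"`.
#' @export
measure_clusters <- function(traj, n_samples = 20, every = 5000) {
  state <- traj$state
  rows <- vector("list", n_samples)
  for (m in seq_len(n_samples)) {
    state <- mc_steps(state, traj$params, every)
    cs <- summarize_clusters(find_clusters(state))
    rows[[m]] <- tibble::tibble(sample = m, step = traj$steps + m * every,
                                n_clustered = cs$n_clustered,
                                n_clusters = cs$n_clusters,
                                mean_fa_area_top10 = cs$mean_fa_area_top10)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "state") <- state
  out
}

#' Scenario x pore-size sweep of the clustering simulation
#'
#' Runs [run_to_equilibrium()] for every combination of scenario preset and
#' substrate (pore sizes in nm, plus optionally the flat gold control),
#' `n_replicates` times each with derived seeds `base_seed + replicate - 1`,
#' then estimates the focal-adhesion statistics by time-averaging
#' [measure_clusters()] snapshots along the equilibrated trajectory
#' (`measure_samples = 0` falls back to the single end-state snapshot).
#'
#' @param scenarios character vector of [scenario_params()] preset names.
#' @param pore_sizes_nm numeric vector of pore sizes (default
#'   c(20, 50, 75, 100, 150)).
#' @param include_flat add the flat gold control (`pore_nm = Inf`).
#' @param n_replicates replicates per condition (>= 1).
#' @param base_seed seed of the first replicate.
#' @param config_args named list of overrides passed to [sim_config()]
#'   (e.g. `max_steps`, `n_integrins`).
#' @param measure_samples,measure_every snapshots and spacing for the
#'   measurement phase (defaults 20 snapshots, 5000 steps apart).
#' @param .progress print one line per completed run.
#' @return A tibble of class `npg_sweep`, one row per run: scenario,
#'   substrate label, pore_nm, replicate, seed, equilibrated, steps,
#'   n_clustered, n_clusters, mean_fa_area_top10 (time averages).
#' @export
sweep_scenarios <- function(scenarios = c("baseline"),
                            pore_sizes_nm = c(20, 50, 75, 100, 150),
                            include_flat = TRUE, n_replicates = 10,
                            base_seed = 1, config_args = list(),
                            measure_samples = 20, measure_every = 5000,
                            .progress = FALSE) {
  if (n_replicates < 1) stop("`n_replicates` must be at least 1", call. = FALSE)
  pores <- pore_sizes_nm
  if (include_flat) pores <- c(pores, Inf)
  grid <- tidyr::expand_grid(scenario = scenarios, pore_nm = pores,
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(scenario, pore_nm, replicate) {
    seed <- base_seed + replicate - 1
    cfg <- do.call(sim_config, c(
      list(pore_nm = pore_nm, scenario = scenario, seed = seed),
      config_args))
    traj <- run_to_equilibrium(cfg)
    if (measure_samples > 0) {
      samples <- measure_clusters(traj, n_samples = measure_samples,
                                  every = measure_every)
      stats <- tibble::tibble(
        n_clustered = mean(samples$n_clustered),
        n_clusters = mean(samples$n_clusters),
        mean_fa_area_top10 = mean(samples$mean_fa_area_top10))
    } else {
      cs <- summarize_clusters(find_clusters(traj$state))
      stats <- cs[, c("n_clustered", "n_clusters", "mean_fa_area_top10")]
    }
    if (.progress) {
      message(sprintf("%s pore=%s rep=%d: %.1f clustered, top-decile FA %.2f (%d steps%s)",
                      scenario, ifelse(is.infinite(pore_nm), "flat", pore_nm),
                      replicate, stats$n_clustered, stats$mean_fa_area_top10,
                      traj$steps,
                      if (traj$equilibrated) "" else ", not equilibrated"))
    }
    dplyr::bind_cols(
      tibble::tibble(scenario = scenario,
                     substrate = ifelse(is.infinite(pore_nm), "flat",
                                        paste0(pore_nm, " nm")),
                     pore_nm = pore_nm, replicate = replicate, seed = seed,
                     equilibrated = traj$equilibrated, steps = traj$steps),
      stats)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("npg_sweep", class(out))
  out
}

#' Aggregate a sweep into per-condition means and standard errors
#'
#' @param sweep an `npg_sweep` tibble from [sweep_scenarios()].
#' @return A tibble with one row per (scenario, substrate): replicate count,
#'   mean and standard error of the clustered-integrin count and of the
#'   top-decile focal-adhesion area.
#' @export
summarize_sweep <- function(sweep) {
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  dplyr::summarise(
    dplyr::group_by(sweep, .data$scenario, .data$substrate, .data$pore_nm),
    n_replicates = dplyr::n(),
    n_clustered_mean = mean(.data$n_clustered),
    n_clustered_se = sem(.data$n_clustered),
    fa_area_mean = mean(.data$mean_fa_area_top10),
    fa_area_se = sem(.data$mean_fa_area_top10),
    .groups = "drop"
  )
}
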