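test_that("adjacent associated integrins form a single cluster", {
  st <- make_state(rows = c(3, 3), cols = c(4, 5), states = c(3, 3),
                   n_rows = 10, n_cols = 10)
  cl <- find_clusters(st)
  expect_length(cl, 1)
  expect_setequal(cl[[1]], c(1, 2))
})

test_that("states without associated integrins yield no clusters", {
  st <- make_state(rows = c(1, 5), cols = c(1, 5), states = c(2, 2),
                   n_rows = 10, n_cols = 10)
  expect_identical(find_clusters(st), list())
})

test_that("a plus-sign of five is one cluster; removing its centre fragments it", {
  rows <- c(5, 4, 6, 5, 5)
  cols <- c(5, 5, 5, 4, 6)
  st <- make_state(rows, cols, states = rep(3, 5), n_rows = 10, n_cols = 10)
  cl <- find_clusters(st)
  expect_length(cl, 1)
  expect_length(cl[[1]], 5)
  # centre bound instead: four singletons, all excluded
  st2 <- make_state(rows, cols, states = c(2, 3, 3, 3, 3),
                    n_rows = 10, n_cols = 10)
  expect_identical(find_clusters(st2), list())
})

test_that("clusters spanning the periodic seam are counted once", {
  # horizontal wrap
  st <- make_state(rows = c(2, 2), cols = c(1, 10), states = c(3, 3),
                   n_rows = 10, n_cols = 10)
  expect_length(find_clusters(st), 1)
  # vertical wrap plus an interior member
  st2 <- make_state(rows = c(1, 10, 9), cols = c(4, 4, 4),
                    states = c(3, 3, 3), n_rows = 10, n_cols = 10)
  cl2 <- find_clusters(st2)
  expect_length(cl2, 1)
  expect_length(cl2[[1]], 3)
})

test_that("cluster labelling matches a flood-fill oracle on random lattices", {
  set.seed(17)
  for (rep in seq_len(100)) {
    mask <- matrix(runif(100) < 0.35, 10, 10)
    if (!any(mask)) next
    st <- state_from_mask(mask)
    got <- lapply(find_clusters(st),
                  function(ids) cbind(st$row[ids] + 1, st$col[ids] + 1))
    want <- flood_fill_clusters(mask)
    expect_identical(canonical_clusters(got), canonical_clusters(want))
  }
})

test_that("cluster summaries implement the top-decile area statistic", {
  fake <- function(sizes) lapply(sizes, seq_len)
  s <- summarize_clusters(fake(2:11))
  expect_equal(s$n_clusters, 10)
  expect_equal(s$mean_fa_area_top10, 11)  # ceiling(0.1 * 10) = 1 cluster
  expect_equal(s$n_clustered, sum(2:11))

  one <- summarize_clusters(fake(7))
  expect_equal(one$mean_fa_area_top10, 7)

  ties <- summarize_clusters(fake(rep(4, 25)))
  expect_equal(ties$mean_fa_area_top10, 4)  # ceiling(2.5) = 3 selected, all 4

  empty <- summarize_clusters(list())
  expect_true(empty$empty)
  expect_equal(empty$n_clustered, 0)
  expect_equal(empty$mean_fa_area_top10, 0)
})

test_that("cluster sizes always sum to the clustered-integrin count", {
  set.seed(23)
  for (rep in seq_len(20)) {
    mask <- matrix(runif(144) < 0.4, 12, 12)
    if (!any(mask)) next
    s <- summarize_clusters(find_clusters(state_from_mask(mask)))
    expect_equal(sum(s$cluster_sizes[[1]]), s$n_clustered)
    if (s$n_clusters > 0) {
      expect_true(all(s$cluster_sizes[[1]] >= 2))
      expect_gte(s$mean_fa_area_top10, s$mean_cluster_size)
      expect_lte(s$mean_fa_area_top10, s$max_cluster_size)
    }
  }
})

test_that("sweeps validate replicate counts and record per-run metadata", {
  expect_error(sweep_scenarios(n_replicates = 0), "at least 1")
  sw <- sweep_scenarios("baseline", pore_sizes_nm = 75, include_flat = FALSE,
                        n_replicates = 2, base_seed = 40,
                        config_args = list(n_integrins = 40, n_rows = 20,
                                           n_cols = 20, max_steps = 1500,
                                           min_steps = 1500,
                                           equil_window = 500),
                        measure_samples = 3, measure_every = 200)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$seed, c(40, 41))
  expect_true(all(c("n_clustered", "mean_fa_area_top10", "equilibrated")
                  %in% names(sw)))
  agg <- summarize_sweep(sw)
  expect_equal(agg$n_replicates, 2)
  expect_gte(agg$n_clustered_se, 0)
})

test_that("measurement phases continue a trajectory reproducibly", {
  cfg <- sim_config(n_integrins = 60, n_rows = 20, n_cols = 20, pore_nm = 150,
                    max_steps = 2000, min_steps = 2000, equil_window = 1000,
                    seed = 77)
  run <- function() {
    traj <- run_to_equilibrium(cfg)
    measure_clusters(traj, n_samples = 4, every = 250)
  }
  a <- run()
  b <- run()
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 4)
})
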