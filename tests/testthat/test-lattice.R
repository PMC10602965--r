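test_that("initialisation places the configured integrins on distinct sites", {
  cfg <- sim_config(seed = 5)
  st <- initialize_lattice(cfg)
  tab <- tidy(st)
  expect_equal(nrow(tab), 1000)
  expect_true(all(tab$state == "inactive"))
  expect_equal(nrow(dplyr::distinct(tab, row, col)), 1000)
  # occupancy map is consistent with the integrin table
  expect_equal(sum(st$occ > 0), 1000)
  expect_identical(initialize_lattice(cfg), st) # same seed, same placement
})

test_that("full occupancy and over-capacity are handled", {
  cfg <- sim_config(n_integrins = 100, n_rows = 10, n_cols = 10)
  st <- initialize_lattice(cfg)
  expect_true(all(st$occ > 0))
  expect_error(sim_config(n_integrins = 101, n_rows = 10, n_cols = 10),
               "one per site")
})

test_that("integrin count is conserved at every checkpoint", {
  cfg <- sim_config(pore_nm = 75, max_steps = 5000, min_steps = 5000,
                    equil_window = 2500, seed = 2)
  traj <- run_to_equilibrium(cfg)
  chk <- tidy(traj)
  totals <- chk$n_inactive + chk$n_active + chk$n_bound + chk$n_associated
  expect_true(all(totals == 1000))
})

test_that("trajectories are bit-identical under a fixed seed", {
  cfg <- sim_config(n_integrins = 120, n_rows = 30, n_cols = 30, pore_nm = 50,
                    max_steps = 3000, min_steps = 3000, equil_window = 1000,
                    seed = 9)
  a <- run_to_equilibrium(cfg)
  b <- run_to_equilibrium(cfg)
  expect_identical(a$checkpoints, b$checkpoints)
  expect_identical(a$state$state, b$state$state)
  expect_identical(a$state$row, b$state$row)
})

test_that("every associated integrin keeps an associated 4-neighbour", {
  cfg <- sim_config(n_integrins = 200, n_rows = 40, n_cols = 40, pore_nm = 150,
                    max_steps = 8000, min_steps = 8000, equil_window = 2000,
                    seed = 4)
  st <- run_to_equilibrium(cfg)$state
  assoc <- which(st$state == 3L)
  expect_gt(length(assoc), 0)
  occ_state <- rep(NA_integer_, st$n_rows * st$n_cols)
  occ_state[st$row * st$n_cols + st$col + 1] <- st$state
  for (i in assoc) {
    r <- st$row[i]; cc <- st$col[i]
    nb <- c(((r - 1) %% st$n_rows) * st$n_cols + cc,
            ((r + 1) %% st$n_rows) * st$n_cols + cc,
            r * st$n_cols + (cc - 1) %% st$n_cols,
            r * st$n_cols + (cc + 1) %% st$n_cols) + 1
    expect_true(any(occ_state[nb] == 3L, na.rm = TRUE))
  }
})

test_that("a single two-state integrin spends the Boltzmann fraction active", {
  cfg <- sim_config(n_integrins = 1, n_rows = 10, n_cols = 10,
                    enable_binding = FALSE, enable_association = FALSE,
                    checkpoint_every = 1, seed = 21)
  st <- initialize_lattice(cfg)
  st <- mc_steps(st, energy_params(), 2e5)
  x <- attr(st, "checkpoints")$n_active[-(1:5000)]
  se <- batch_se(x)
  expect_lt(abs(mean(x) - 1 / (1 + exp(3))), 3 * se)
})

test_that("halving dt leaves equilibrium occupancies unchanged", {
  frac <- function(dt) {
    cfg <- sim_config(n_integrins = 200, n_rows = 20, n_cols = 20,
                      enable_binding = FALSE, enable_association = FALSE,
                      checkpoint_every = 10, seed = 31)
    st <- initialize_lattice(cfg)
    st <- mc_steps(st, energy_params(dt = dt), 2e4)
    x <- attr(st, "checkpoints")$n_active[-(1:200)] / 200
    c(mean(x), batch_se(x, 20))
  }
  a <- frac(0.010)
  b <- frac(0.005)
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("with reactions disabled integrins only diffuse", {
  cfg <- sim_config(n_integrins = 50, n_rows = 20, n_cols = 20,
                    enable_binding = FALSE, enable_association = FALSE,
                    checkpoint_every = 0, seed = 13)
  st0 <- initialize_lattice(cfg)
  # vanishing activation rate: no reaction can fire
  st <- mc_steps(st0, energy_params(k_a_plus = 1e-12), 200)
  expect_true(all(st$state == 0L))
  expect_false(identical(st$row, st0$row) && identical(st$col, st0$col))
  # occupancy stays consistent: one integrin per site
  expect_equal(sum(st$occ > 0), 50)
  expect_equal(sort(st$occ[st$occ > 0]), 1:50)
})

test_that("zero-integrin systems equilibrate immediately", {
  cfg <- sim_config(n_integrins = 0, n_rows = 10, n_cols = 10)
  traj <- run_to_equilibrium(cfg)
  expect_true(traj$equilibrated)
  expect_equal(traj$steps, 0L)
  expect_equal(nrow(tidy(traj)), 0)
})

test_that("non-equilibrated runs are flagged, not silently accepted", {
  cfg <- sim_config(n_integrins = 100, n_rows = 20, n_cols = 20,
                    pore_nm = 150, max_steps = 2000, equil_window = 1000,
                    equil_tolerance = 0, seed = 3)
  traj <- run_to_equilibrium(cfg)
  expect_false(traj$equilibrated)
  expect_equal(traj$steps, 2000L)
})

test_that("substrate fields project onto the lattice by local averaging", {
  flat <- make_flat_gold(64, pixel_size = 100)
  m <- map_substrate_to_lattice(flat, 10, 10, site_spacing_nm = 60)
  expect_true(all(m == 1))

  # vertical stripes of period 2 sites: 30 nm/px, site = 60 nm = 2 px
  stripe <- matrix(rep(c(1, 1, 0, 0), length.out = 64), 64, 64, byrow = TRUE)
  f <- substrate_field(stripe, pixel_size = 30)
  sites <- map_substrate_to_lattice(f, 8, 8, site_spacing_nm = 60)
  expect_true(all(sites %in% c(0, 1)))
  expect_equal(sites[1, ], rep(c(1, 0), 4))
  expect_equal(mean(sites), mean(stripe), tolerance = 0.05)

  expect_error(map_substrate_to_lattice(f, 100, 100, 60, tile = FALSE),
               "cover")
})

test_that("field-mode simulations run with per-site gold concentrations", {
  f <- generate_npg_field(seed = 3, target_length_nm = 20, size_px = 128)
  cfg <- sim_config(n_integrins = 90, n_rows = 30, n_cols = 30, pore_nm = 20,
                    c_mode = "field", substrate = f, max_steps = 2000,
                    min_steps = 2000, equil_window = 1000, seed = 6)
  traj <- run_to_equilibrium(cfg)
  chk <- tidy(traj)
  expect_true(all(chk$n_inactive + chk$n_active + chk$n_bound +
                    chk$n_associated == 90))
})

test_that("trajectories export checkpoints, final state and a manifest", {
  cfg <- sim_config(n_integrins = 30, n_rows = 12, n_cols = 12, pore_nm = 75,
                    max_steps = 1000, min_steps = 1000, equil_window = 500,
                    seed = 8)
  traj <- run_to_equilibrium(cfg)
  dir <- file.path(tempdir(), "trajdir")
  write_trajectory(traj, dir)
  chk <- utils::read.csv(file.path(dir, "checkpoints.csv"))
  st <- utils::read.csv(file.path(dir, "final_state.csv"))
  man <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  expect_equal(nrow(st), 30)
  expect_true(all(chk$n_inactive + chk$n_active + chk$n_bound +
                    chk$n_associated == 30))
  expect_equal(man$seed, 8)
  expect_equal(man$config$n_rows, 12)
  unlink(dir, recursive = TRUE)
})
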