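# Independent oracles used by the test suite. Everything here is written
# against the *definitions* (flood fill, exact Markov chains, closed-form
# least squares), not against the package's implementation paths.

# ---- hand-built lattice states ------------------------------------------

# build a lattice_state from explicit integrin positions/states
# (rows/cols 1-based; states 0..3)
make_state <- function(rows, cols, states, n_rows, n_cols, config = NULL) {
  if (is.null(config)) {
    config <- sim_config(n_integrins = length(rows), n_rows = n_rows,
                         n_cols = n_cols)
  }
  row0 <- as.integer(rows - 1)
  col0 <- as.integer(cols - 1)
  occ <- integer(n_rows * n_cols)
  occ[row0 * n_cols + col0 + 1] <- seq_along(rows)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, occ = occ, row = row0,
         col = col0, state = as.integer(states), config = config),
    class = "lattice_state"
  )
}

# lattice_state with ASSOCIATED integrins at every TRUE cell of a mask
state_from_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  make_state(idx[, 1], idx[, 2], rep(3L, nrow(idx)),
             n_rows = nrow(mask), n_cols = ncol(mask))
}

# ---- flood-fill connected components (periodic, 4-neighbour) ------------

# queue-based flood fill over a logical mask; returns list of clusters of
# size >= 2, each a matrix of (row, col) 1-based coordinates
flood_fill_clusters <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  out <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    members <- NULL
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      members <- rbind(members, p)
      nbs <- rbind(c((p[1] - 2) %% nr + 1, p[2]),
                   c(p[1] %% nr + 1, p[2]),
                   c(p[1], (p[2] - 2) %% nc + 1),
                   c(p[1], p[2] %% nc + 1))
      for (k in 1:4) {
        rr <- nbs[k, 1]; cc <- nbs[k, 2]
        if (mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- c(queue, list(c(rr, cc)))
        }
      }
    }
    if (nrow(members) >= 2) out <- c(out, list(unname(members)))
  }
  out
}

# canonical form for comparing cluster partitions: sorted vector of
# "row,col" keys per cluster, clusters sorted lexicographically
canonical_clusters <- function(coord_list) {
  keys <- lapply(coord_list, function(m) {
    sort(paste(m[, 1], m[, 2], sep = ","))
  })
  keys[order(vapply(keys, `[`, "", 1))]
}

# ---- exact one-step Markov chain for a 2x2 lattice with 2 integrins ------
#
# Mirrors the engine's update semantics exactly: shuffled sequential update,
# within-step first-reaction kinetics (computed here by matrix exponentials
# of the per-integrin generator, with the partner frozen except for
# recruitment), diffusion only when no reaction fired, then orphan cleanup.
# States 1..4 = INACTIVE, ACTIVE, BOUND, ASSOCIATED (1-based here).

# on the 2x2 periodic lattice (sites 0..3, site = r*2+c), two sites are
# 4-neighbours iff they share a row or a column
adjacent2x2 <- function(s1, s2) {
  (s1 %/% 2 == s2 %/% 2) != (s1 %% 2 == s2 %% 2)
}

# within-update propagators for the three partner contexts
toy_propagators <- function(rates, dt) {
  four_state_Q <- function(eligible) {
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- rates$ka_p
    Q[2, 1] <- rates$ka_m
    Q[2, 3] <- rates$kb_p
    Q[3, 2] <- rates$kb_m
    if (eligible) Q[3, 4] <- rates$kc_p
    Q[4, 3] <- rates$kc_m
    diag(Q) <- -rowSums(Q)
    Q
  }
  # partner adjacent and BOUND: my association recruits it; augmented state
  # (my state, partner in {BOUND, ASSOCIATED}), index (s-1)*4 + m
  Q8 <- matrix(0, 8, 8)
  for (s in 1:2) {
    o <- (s - 1) * 4
    Q8[o + 1, o + 2] <- rates$ka_p
    Q8[o + 2, o + 1] <- rates$ka_m
    Q8[o + 2, o + 3] <- rates$kb_p
    Q8[o + 3, o + 2] <- rates$kb_m
    Q8[o + 4, o + 3] <- rates$kc_m
  }
  Q8[3, 8] <- rates$kc_p      # (B, partner B) -> (As, partner recruited)
  Q8[4 + 3, 4 + 4] <- rates$kc_p # (B, partner As) -> (As, partner As)
  diag(Q8) <- -rowSums(Q8)
  list(
    none = as.matrix(Matrix::expm(four_state_Q(FALSE) * dt)),
    eligible_as = as.matrix(Matrix::expm(four_state_Q(TRUE) * dt)),
    eligible_b = as.matrix(Matrix::expm(Q8 * dt))
  )
}

# total exit rate of a state given its context (for the no-event probability)
toy_exit_rate <- function(state, eligible, rates) {
  switch(state,
         rates$ka_p,
         rates$ka_m + rates$kb_p,
         rates$kb_m + if (eligible) rates$kc_p else 0,
         rates$kc_m)
}

# update one integrin: returns a list of outcomes
# (prob, states (both), sites (both)); `who` is 1 or 2
toy_update_one <- function(sites, states, who, rates, dt, props) {
  me <- who; ot <- 3 - who
  adj <- adjacent2x2(sites[me], sites[ot])
  eligible <- adj && states[ot] >= 3
  ctx <- if (!eligible) "none" else if (states[ot] == 4) "eligible_as"
         else "eligible_b"
  q0 <- exp(-toy_exit_rate(states[me], eligible, rates) * dt)
  out <- list()
  add <- function(p, st_me, st_ot, site_me) {
    if (p <= 0) return()
    st <- states; st[me] <- st_me; st[ot] <- st_ot
    ss <- sites; ss[me] <- site_me
    out[[length(out) + 1]] <<- list(prob = p, states = st, sites = ss)
  }
  # no-event branch: state unchanged, diffusion attempt unless associated
  if (states[me] != 4) {
    vt <- bitwXor(sites[me], 2L) # vertical partner site
    ht <- bitwXor(sites[me], 1L) # horizontal partner site
    for (tgt in c(vt, ht)) {
      new_site <- if (tgt == sites[ot]) sites[me] else tgt
      add(q0 / 2, states[me], states[ot], new_site)
    }
  } else {
    add(q0, states[me], states[ot], sites[me])
  }
  # jump branches from the propagator, with the no-event mass carved out
  if (ctx == "eligible_b") {
    P <- props$eligible_b
    from <- states[me] # partner index s=1 (BOUND)
    for (s in 1:2) for (m in 1:4) {
      p <- P[from, (s - 1) * 4 + m]
      if (s == 1 && m == states[me]) p <- p - q0
      add(p, m, if (s == 2) 4L else states[ot], sites[me])
    }
  } else {
    P <- props[[ctx]]
    for (m in 1:4) {
      p <- P[states[me], m]
      if (m == states[me]) p <- p - q0
      add(p, m, states[ot], sites[me])
    }
  }
  out
}

# orphan cleanup for the pair system
toy_cleanup <- function(sites, states) {
  both_as <- states[1] == 4 && states[2] == 4
  if (!(both_as && adjacent2x2(sites[1], sites[2]))) {
    states[states == 4] <- 3
  }
  states
}

toy_config_id <- function(sites, states) {
  paste(sites[1], states[1], sites[2], states[2], sep = ".")
}

# enumerate valid (post-cleanup) configurations
toy_valid_configs <- function() {
  out <- list()
  for (s1 in 0:3) for (s2 in setdiff(0:3, s1)) {
    for (st1 in 1:4) for (st2 in 1:4) {
      any_as <- st1 == 4 || st2 == 4
      ok <- !any_as ||
        (st1 == 4 && st2 == 4 && adjacent2x2(s1, s2))
      if (ok) out[[length(out) + 1]] <-
          list(sites = c(s1, s2), states = c(st1, st2))
    }
  }
  out
}

# exact one-step transition matrix over valid configurations
toy_transition_matrix <- function(rates, dt) {
  props <- toy_propagators(rates, dt)
  configs <- toy_valid_configs()
  ids <- vapply(configs, function(cf) toy_config_id(cf$sites, cf$states), "")
  n <- length(configs)
  T <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    cf <- configs[[i]]
    for (first in 1:2) {
      o1 <- toy_update_one(cf$sites, cf$states, first, rates, dt, props)
      for (a in o1) {
        o2 <- toy_update_one(a$sites, a$states, 3 - first, rates, dt, props)
        for (b in o2) {
          st <- toy_cleanup(b$sites, b$states)
          j <- match(toy_config_id(b$sites, st), ids)
          T[i, j] <- T[i, j] + 0.5 * a$prob * b$prob
        }
      }
    }
  }
  T
}

# stationary distribution of a stochastic matrix (left eigenvector)
stationary_dist <- function(T) {
  e <- eigen(t(T))
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

# aggregate a configuration distribution onto state-count classes
# key = "nI.nA.nB.nAs"
toy_class_of <- function(states) {
  cnt <- tabulate(states, 4)
  paste(cnt, collapse = ".")
}

# ---- batch-means standard error ------------------------------------------

batch_se <- function(x, n_batches = 40) {
  n <- length(x)
  size <- n %/% n_batches
  means <- vapply(seq_len(n_batches), function(b) {
    mean(x[((b - 1) * size + 1):(b * size)])
  }, numeric(1))
  stats::sd(means) / sqrt(n_batches)
}
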