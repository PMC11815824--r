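# System composition, minimum-distance networks and aggregate statistics.

test_that("the reference composition numbers are reproduced", {
  # 20 trehalose in 7609 waters is 50 g/L to the nearest integer
  expect_identical(round(concentration_of(20, 342.30, 7609)), 50)
  # 4:1 water mapping
  expect_identical(cg_water_beads(7609), 1902L)
  expect_identical(cg_water_beads(0), 0L)
  for (k in c(1L, 13L, 400L)) expect_identical(cg_water_beads(4L * k), k)
  # algebraic inversion of the 50 g/L target lands on 7600 waters
  expect_identical(waters_for_concentration(20, 342.30, 50), 7600)
})

test_that("composition is scale invariant and rejects bad input", {
  c1 <- concentration_of(20, 342.30, 7609)
  expect_equal(concentration_of(40, 342.30, 2 * 7609), c1, tolerance = 1e-12)
  expect_error(concentration_of(0, 342.30, 7609))
  expect_error(waters_for_concentration(20, 342.30, -1))
})

test_that("minimum intermolecular distance respects the minimum image", {
  box <- c(10, 10, 10)
  expect_equal(min_intermolecular_distance(c(1, 1, 1), c(1, 1, 1.3), box), 0.3)
  # beads 0.1 nm apart across the periodic boundary
  expect_equal(min_intermolecular_distance(c(0.05, 5, 5), c(9.95, 5, 5), box),
               0.1, tolerance = 1e-12)
  expect_error(min_intermolecular_distance(matrix(0, 0, 3), c(1, 1, 1), box),
               "empty")
  expect_error(min_intermolecular_distance(c(0, 0, 0), c(1, 1, 1), diag(3)),
               "orthorhombic")
})

test_that("minimum image agrees with exhaustive 27-image enumeration", {
  set.seed(21)
  box <- c(4, 5, 6)
  for (rep in 1:20) {
    mi <- matrix(runif(9, 0, max(box)), 3)
    mj <- matrix(runif(12, 0, max(box)), 4)
    brute <- Inf
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      shift <- c(sx, sy, sz) * box
      shifted <- sweep(mj, 2, shift, "+")
      for (a in 1:3) for (b in 1:4)
        brute <- min(brute, sqrt(sum((mi[a, ] - shifted[b, ])^2)))
    }
    expect_equal(min_intermolecular_distance(mi, mj, box), brute,
                 tolerance = 1e-12)
  }
})

test_that("aggregate components match planted partitions", {
  # all-singleton limit
  lone <- gen_clustered_config(20, rep(1L, 20), gap = 1, box = c(12, 25, 12))
  expect_sizes(aggregate_sizes(lone), rep(1L, 20))
  # ten dimers (the dimer-dominated regime)
  dimers <- gen_clustered_config(20, rep(2L, 10), gap = 1, box = c(12, 25, 12))
  expect_sizes(aggregate_sizes(dimers), rep(2L, 10))
  # uneven plant {9, 11} and {5, 15}
  expect_sizes(aggregate_sizes(
    gen_clustered_config(20, c(9L, 11L), gap = 1, box = c(12, 12, 12))),
    c(11L, 9L))
  expect_sizes(aggregate_sizes(
    gen_clustered_config(20, c(5L, 15L), gap = 1, box = c(12, 12, 12))),
    c(15L, 5L))
  # a single aggregate of everything
  expect_sizes(aggregate_sizes(
    gen_clustered_config(20, 20L, gap = 1, box = c(12, 12, 12))), 20L)
})

test_that("chained proximity is transitive: A-B-C with A-C distant", {
  frame <- list(coords = rbind(c(1, 1, 1), c(1.4, 1, 1), c(1.8, 1, 1)),
                box = c(10, 10, 10), mol_index = 1:3, time = 0)
  rec <- aggregate_sizes(frame, cutoff = 0.45)
  expect_sizes(rec, 3L)
  # edge exactly at the cutoff is kept (inclusive filter)
  frame2 <- list(coords = rbind(c(1, 1, 1), c(1.47, 1, 1)),
                 box = c(10, 10, 10), mol_index = 1:2, time = 0)
  expect_sizes(aggregate_sizes(frame2, cutoff = 0.47), 2L)
})

test_that("component sizes always sum to the molecule count and edges match a brute-force scan", {
  set.seed(22)
  box <- c(6, 6, 6)
  for (rep in 1:5) {
    n_mol <- 15L
    coords <- matrix(runif(n_mol * 3 * 3, 0, 6), ncol = 3)
    frame <- list(coords = coords, box = box,
                  mol_index = rep(seq_len(n_mol), each = 3), time = 0)
    cutoff <- runif(1, 0.4, 1.5)
    rec <- aggregate_sizes(frame, cutoff)
    expect_identical(sum(rec$sizes), n_mol)
    # oracle: brute-force pair scan defines the same edge set, so the same
    # membership partition
    per <- lapply(seq_len(n_mol), function(m)
      coords[frame$mol_index == m, , drop = FALSE])
    adj <- matrix(FALSE, n_mol, n_mol)
    for (i in 1:(n_mol - 1)) for (j in (i + 1):n_mol)
      adj[i, j] <- adj[j, i] <-
        min_intermolecular_distance(per[[i]], per[[j]], box) <= cutoff
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_identical(sort(rec$sizes),
                     sort(as.integer(igraph::components(g)$csize)))
  }
})

test_that("aggregate count is monotone non-increasing in the cutoff", {
  set.seed(23)
  coords <- matrix(runif(60, 0, 5), ncol = 3)
  frame <- list(coords = coords, box = c(5, 5, 5), mol_index = 1:20, time = 0)
  cutoffs <- seq(0.3, 1.0, by = 0.1)
  ncomp <- vapply(cutoffs, function(ct) length(aggregate_sizes(frame, ct)$sizes),
                  0L)
  expect_true(all(diff(ncomp) <= 0))
})

test_that("windowed size distributions pool frames and replicas additively", {
  mk_traj <- function(sizes, times) lapply(times, function(t) {
    fr <- gen_clustered_config(20, sizes, gap = 1, box = c(12, 25, 12),
                               seed = 1L + as.integer(t))
    fr$time <- t
    fr
  })
  times <- seq(0, 1000, by = 100)
  reps <- list(aggregate_series(mk_traj(rep(2L, 10), times)),
               aggregate_series(mk_traj(c(5L, 15L), times)))
  pooled <- size_distribution(reps)
  single <- lapply(reps, size_distribution)
  expect_equal(pooled$count, single[[1]]$count + single[[2]]$count)
  expect_identical(pooled$size, 1:20)
  # stride equal to frame spacing keeps every frame in the window
  d_all <- size_distribution(reps[[1]], window_ps = 1000, stride_ps = 100)
  expect_identical(sum(d_all$count * d_all$size), 20L * length(times))
  # static plant: point mass at the planted sizes
  expect_identical(which(single[[2]]$count > 0), c(5L, 15L))
  # a window longer than the trajectory is refused
  expect_error(size_distribution(reps[[1]], window_ps = 2000), "exceeds")
})

test_that("time evolution tracks per-frame aggregate statistics", {
  frames <- list(
    gen_clustered_config(20, rep(1L, 20), gap = 1, box = c(12, 25, 12)),
    gen_clustered_config(20, c(10L, 10L), gap = 1, box = c(12, 25, 12)))
  frames[[1]]$time <- 0; frames[[2]]$time <- 100
  evo <- time_evolution(aggregate_series(frames))
  expect_equal(evo$time, c(0, 100))
  expect_identical(evo$n_aggregates, c(20L, 2L))
  expect_identical(evo$largest, c(1L, 10L))
})
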