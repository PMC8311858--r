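# Participation coefficient and connection-count metrics.

test_that("PC has its analytic anchors: all-within 0, even split 1 - 1/M", {
  # star node 0 with 10 edges, all inside its own module
  n <- 11
  adj <- matrix(FALSE, n, n)
  adj[1, 2:11] <- adj[2:11, 1] <- TRUE
  part <- tiny_partition(rep(0L, n))
  expect_equal(participation_coefficient(adj, part)$pc[1], 0)

  # node with exactly one edge into each of 7 modules
  n <- 8
  adj <- matrix(FALSE, n, n)
  adj[1, 2:8] <- adj[2:8, 1] <- TRUE
  part <- tiny_partition(c(0L, 0:6))
  pc <- participation_coefficient(adj, part)$pc[1]
  expect_equal(pc, 1 - 7 * (1 / 7)^2)
  expect_equal(pc, 6 / 7)

  # isolated node: defined as 0, and bounded by 1 - 1/M
  adj2 <- matrix(FALSE, 4, 4)
  part2 <- tiny_partition(c(0L, 0L, 1L, 1L))
  expect_equal(participation_coefficient(adj2, part2)$pc, rep(0, 4))
})

test_that("PC equals the brute-force evaluation on seeded random graphs", {
  set.seed(90)
  for (rep in 1:10) {
    n <- sample(10:30, 1)
    memb <- sample(c(0:2, sample(0:2, n - 3, replace = TRUE)))
    adj <- random_adjacency(n, 0.3, seed = 1000 + rep)
    got <- participation_coefficient(adj, tiny_partition(memb))$pc
    expect_equal(got, pc_bruteforce(adj, memb), tolerance = 1e-12)
  }
  # mismatched node sets error
  expect_error(
    participation_coefficient(random_adjacency(5, 0.5, 1),
                              tiny_partition(c(0L, 1L, 0L))),
    "absent"
  )
})

test_that("threshold averaging is the arithmetic mean of per-threshold PC", {
  set.seed(41)
  z <- fisher_z_connectivity(matrix(rnorm(20 * 80), nrow = 20))
  part <- tiny_partition(rep(0:3, 5), tiny_node_table(20))
  graphs <- multi_threshold_graphs(z)

  avg <- threshold_averaged_pc(graphs, part)
  per <- pc_by_threshold(graphs, part)
  manual <- vapply(split(per$pc, per$node_id), mean, numeric(1))
  expect_equal(avg$pc, unname(manual))

  # compositional oracle: mean of independent single-threshold calls
  singles <- vapply(default_thresholds(), function(p) {
    participation_coefficient(proportional_threshold(z, p), part)$pc
  }, numeric(20))
  expect_equal(avg$pc, rowMeans(singles), tolerance = 1e-12)

  # identical graphs at all thresholds average to the single-graph PC
  g1 <- proportional_threshold(z, 0.3)
  same <- structure(list(a = g1, b = g1, c = g1), thresholds = c(0.3, 0.3, 0.3),
                    class = "conn_graphs")
  expect_equal(threshold_averaged_pc(same, part)$pc,
               participation_coefficient(g1, part)$pc)
})

test_that("connection counts decompose the mean degree exactly", {
  set.seed(55)
  part <- make_partition(default_node_table(), 7)
  for (rep in 1:5) {
    z <- fisher_z_connectivity(matrix(rnorm(76 * 60), nrow = 76))
    graphs <- multi_threshold_graphs(z)
    node <- sample(default_node_table()$label, 1)
    counts <- module_connection_counts(graphs, part, node)
    wb <- within_between_counts(graphs, part, node)
    i <- match(node, part$label)
    mean_deg <- mean(vapply(graphs, function(g) sum(g[i, ]), numeric(1)))

    expect_equal(sum(counts$count), mean_deg, tolerance = 1e-12)
    expect_equal(wb$within_count + wb$between_count, mean_deg,
                 tolerance = 1e-12)
    # per-module counts reproduce the per-threshold PC algebraically
    for (g in graphs) {
      k_im <- vapply(sort(unique(part$module)), function(m) {
        sum(g[i, part$module == m])
      }, numeric(1))
      k <- sum(k_im)
      pc_alg <- if (k == 0) 0 else 1 - sum((k_im / k)^2)
      expect_equal(participation_coefficient(g, part)$pc[i], pc_alg,
                   tolerance = 1e-12)
    }
  }
})

test_that("all-internal and hemisphere-restricted counts behave as partitions of the neighbor set", {
  # node with all edges internal: between count is 0
  n <- 8
  adj <- matrix(FALSE, n, n)
  adj[1, 2:4] <- adj[2:4, 1] <- TRUE
  nt <- tiny_node_table(n, hemispheres = rep(c("L", "R"), each = 4))
  part <- tiny_partition(rep(c(0L, 1L), each = 4), nt)
  gs <- structure(list(a = adj), thresholds = 0.2, class = "conn_graphs")
  wb <- within_between_counts(gs, part, "n00")
  expect_equal(wb$between_count, 0)
  expect_equal(wb$within_count, 3)

  # all neighbors are L nodes: R-restricted counts are zero
  hemi <- hemisphere_connection_counts(gs, part, "n00", nt)
  expect_equal(hemi$within_count[hemi$hemisphere == "R"], 0)
  expect_equal(hemi$between_count[hemi$hemisphere == "R"], 0)

  # L + R reproduces whole-brain counts on seeded fixtures, and matches a
  # brute-force neighbor enumeration
  set.seed(66)
  for (rep in 1:5) {
    z <- fisher_z_connectivity(matrix(rnorm(76 * 60), nrow = 76))
    graphs <- multi_threshold_graphs(z)
    ref <- reference_partition()
    node <- "LIFG_tri"
    hemi <- hemisphere_connection_counts(graphs, ref, node)
    wb <- within_between_counts(graphs, ref, node)
    expect_equal(sum(hemi$within_count), wb$within_count, tolerance = 1e-12)
    expect_equal(sum(hemi$between_count), wb$between_count, tolerance = 1e-12)

    ntab <- default_node_table()
    i <- match(node, ref$label)
    brute <- sapply(graphs, function(g) {
      nb <- which(g[i, ])
      c(sum(ntab$hemisphere[nb] == "L" & ref$module[nb] == ref$module[i]),
        sum(ntab$hemisphere[nb] == "L" & ref$module[nb] != ref$module[i]),
        sum(ntab$hemisphere[nb] == "R" & ref$module[nb] == ref$module[i]),
        sum(ntab$hemisphere[nb] == "R" & ref$module[nb] != ref$module[i]))
    })
    expect_equal(hemi$within_count, rowMeans(brute)[c(1, 3)],
                 ignore_attr = TRUE)
    expect_equal(hemi$between_count, rowMeans(brute)[c(2, 4)],
                 ignore_attr = TRUE)
  }
})

test_that("PC never exceeds 1 - 1/M and coarsening modules never raises it", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 24
    memb <- sample(c(0:3, sample(0:3, n - 4, replace = TRUE)))
    adj <- random_adjacency(n, 0.35, seed = 2000 + rep)
    pc4 <- participation_coefficient(adj, tiny_partition(memb))$pc
    expect_true(all(pc4 <= 1 - 1 / 4 + 1e-12))
    expect_true(all(pc4 >= 0))
    # merge modules 2 and 3
    memb3 <- ifelse(memb == 3, 2, memb)
    pc3 <- participation_coefficient(adj, tiny_partition(memb3))$pc
    expect_true(all(pc3 <= pc4 + 1e-12))
    expect_equal(pc3, pc_bruteforce(adj, memb3), tolerance = 1e-12)
  }
})

test_that("cohort-level metrics match the single-scan building blocks", {
  coh <- small_cohort(seed = 31, n_hc = 2, n_per_group = 2, t_len = 60)
  part <- reference_partition()
  m <- compute_node_metrics(coh$timeseries, part,
                            nodes = c("LIFG_tri", "R_precuneus"))
  expect_equal(nrow(m), length(coh$timeseries) * 2)

  key <- "P01_pre"
  graphs <- multi_threshold_graphs(fisher_z_connectivity(coh$timeseries[[key]]))
  avg <- threshold_averaged_pc(graphs, part)
  wb <- within_between_counts(graphs, part, "LIFG_tri")
  row <- m[m$subject_id == "P01" & m$timepoint == "pre" &
             m$node == "LIFG_tri", ]
  expect_equal(row$pc, avg$pc[avg$label == "LIFG_tri"])
  expect_equal(row$within_count, wb$within_count)
  expect_equal(row$between_count, wb$between_count)

  mc <- compute_module_counts(coh$timeseries, part, "LIFG_tri")
  mc_row <- mc[mc$subject_id == "P01" & mc$timepoint == "pre", ]
  expect_equal(sum(mc_row$count), wb$mean_degree, tolerance = 1e-12)
})

test_that("planted severity raises the target's between-module count and PC", {
  design <- cohort_design(seed = 9)
  part <- design$partition
  sev_grid <- seq(1, 15, length.out = 12)
  vals <- t(vapply(seq_along(sev_grid), function(i) {
    cv <- build_block_covariance(design, severity = sev_grid[i],
                                 timepoint = "pre", arm = "sham")
    ts <- simulate_timeseries(cv, 2000, seed = 400 + i)
    graphs <- multi_threshold_graphs(fisher_z_connectivity(ts))
    wb <- within_between_counts(graphs, part, "LIFG_tri")
    avg <- threshold_averaged_pc(graphs, part)
    c(between = wb$between_count, pc = avg$pc[avg$label == "LIFG_tri"])
  }, numeric(2)))
  expect_gt(cor(sev_grid, vals[, "between"], method = "spearman"), 0)
  expect_gt(cor(sev_grid, vals[, "pc"], method = "spearman"), 0)
})
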