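test_that("zero switching probabilities give a static trajectory", {
  spec <- plant_spec(p_cohesive = 0, p_disjoint = 0, seed = 1)
  pl <- plant_trajectory(spec)
  expect_equal(nrow(pl$events), 0)
  m <- node_metrics(pl$trajectory)
  expect_true(all(m$flexibility == 0))
  # balanced initial partition
  expect_equal(unname(table(pl$trajectory$labels[, 1])), rep(10L, 3),
               ignore_attr = TRUE)
})

test_that("planted events are exact ground truth for the classifier", {
  for (s in 1:25) {
    spec <- plant_spec(n_nodes = 15, n_layers = 8, k = 3, p_cohesive = 0.4,
                       p_disjoint = 0.2, seed = s)
    pl <- plant_trajectory(spec)
    ev <- classify_switches(pl$trajectory)
    ev_sorted <- dplyr::arrange(ev, transition, kind, source, destination)
    tr_sorted <- dplyr::arrange(pl$events, transition, kind, source,
                                destination)
    expect_equal(ev_sorted$transition, tr_sorted$transition)
    expect_equal(ev_sorted$kind, tr_sorted$kind)
    expect_equal(ev_sorted$source, tr_sorted$source)
    expect_equal(ev_sorted$destination, tr_sorted$destination)
    expect_equal(lapply(ev_sorted$nodes, sort),
                 lapply(tr_sorted$nodes, sort))
  }
})

test_that("metrics from the trajectory equal metrics from the emitted log", {
  for (s in 1:20) {
    spec <- plant_spec(n_nodes = 12, n_layers = 6, k = 3, p_cohesive = 0.3,
                       p_disjoint = 0.15, seed = 100 + s)
    pl <- plant_trajectory(spec)
    from_log <- metrics_from_log(pl$events, 12, 6)
    m <- node_metrics(pl$trajectory)
    expect_equal(m$flexibility, from_log$flexibility, tolerance = 1e-15)
    expect_equal(m$disjointedness, from_log$disjointedness,
                 tolerance = 1e-15)
    expect_equal(m$cohesion_strength, from_log$cohesion_strength,
                 tolerance = 1e-15)
  }
})

test_that("planted disjoint rates are recovered over replicates", {
  # k = 6 keeps (source, destination) pairs plentiful so that lone moves are
  # almost never skipped for lack of an unclaimed destination
  rates <- vapply(1:500, function(s) {
    spec <- plant_spec(n_nodes = 20, n_layers = 25, k = 6, p_cohesive = 0,
                       p_disjoint = 0.2, seed = s)
    pl <- plant_trajectory(spec)
    mean(node_metrics(pl$trajectory)$disjointedness)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.2), 0.02)
  strengths <- vapply(1:50, function(s) {
    spec <- plant_spec(n_nodes = 20, n_layers = 25, k = 6, p_cohesive = 0,
                       p_disjoint = 0.2, seed = s)
    mean(node_metrics(plant_trajectory(spec)$trajectory)$cohesion_strength)
  }, numeric(1))
  expect_equal(mean(strengths), 0, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  spec <- plant_spec(seed = 7)
  p1 <- plant_trajectory(spec)
  p2 <- plant_trajectory(spec)
  expect_identical(p1$trajectory$labels, p2$trajectory$labels)
  expect_identical(realize_network(p1$trajectory, spec)$layers,
                   realize_network(p2$trajectory, spec)$layers)
  c1 <- generate_learning_curve(seed = 9)
  c2 <- generate_learning_curve(seed = 9)
  expect_identical(c1, c2)
})

test_that("infeasible plant specs are rejected", {
  expect_error(plant_spec(n_nodes = 6, k = 3, group_size = 3),
               "infeasible")
  expect_error(plant_spec(w_in = 0.5, w_out = 0.6))
})

test_that("noise-free realization is block-constant and label-equivariant", {
  spec <- plant_spec(n_nodes = 9, n_layers = 3, k = 3, edge_noise = 0,
                     seed = 3)
  pl <- plant_trajectory(spec)
  net <- realize_network(pl$trajectory, spec, seed = 11)
  for (t in 1:3) {
    g <- pl$trajectory$labels[, t]
    same <- outer(g, g, "==")
    diag(same) <- NA
    a <- net$layers[[t]]
    expect_true(all(a[same & !is.na(same)] == spec$w_in))
    expect_true(all(a[!same & !is.na(same)] == spec$w_out))
  }
  perm <- c(3, 1, 2, 6, 4, 5, 9, 7, 8)
  permuted <- community_trajectory(pl$trajectory$labels[perm, ])
  net_p <- realize_network(permuted, spec, seed = 11)
  for (t in 1:3) {
    expect_equal(unname(net_p$layers[[t]]),
                 unname(net$layers[[t]][perm, perm]))
  }
})

test_that("infinite SNR makes co-members' series identical", {
  spec <- plant_spec(n_nodes = 6, n_layers = 2, k = 2, p_cohesive = 0,
                     p_disjoint = 0, seed = 5)
  pl <- plant_trajectory(spec)
  ts <- realize_timeseries(pl$trajectory, samples_per_layer = 80, snr = Inf,
                           seed = 6)
  g <- pl$trajectory$labels[, 1]
  pair <- which(g == g[1])[1:2]
  expect_equal(ts$values[pair[1], 1:80], ts$values[pair[2], 1:80])
  # distinct communities carry distinct latents
  other <- which(g != g[1])[1]
  expect_gt(stats::sd(ts$values[pair[1], 1:80] - ts$values[other, 1:80]), 0)
})

test_that("singleton communities gain no spurious coherence", {
  lab <- cbind(c(1L, 1L, 2L, 3L), c(1L, 1L, 2L, 3L))
  traj <- community_trajectory(lab)
  ts <- realize_timeseries(traj, samples_per_layer = 80, snr = 5, seed = 12)
  layer <- wavelet_band_coherence(
    timeseries_set(ts$values[, 1:80], ts$sampling_interval))
  expect_gt(layer[1, 2], layer[3, 4])
})

test_that("learning curves follow the model exactly when noise-free", {
  curve <- generate_learning_curve(d1 = 2, kappa = 0.1, d2 = 1,
                                   lambda = 0.01, noise_sd = 0, seed = 1)
  t <- curve$trial
  expect_equal(curve$mt, 2 * exp(-t * 0.1) + 1 * exp(-t * 0.01),
               tolerance = 1e-15)
  with_out <- generate_learning_curve(noise_sd = 0.01, outlier_frac = 0.1,
                                      n_trials = 100, seed = 2)
  without <- generate_learning_curve(noise_sd = 0.01, outlier_frac = 0,
                                     n_trials = 100, seed = 2)
  expect_equal(sum(with_out$mt != without$mt), 10)
})
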