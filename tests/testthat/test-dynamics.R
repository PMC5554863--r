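# Worked trajectories: rows are nodes, columns are layers.

test_that("a pair moving together is one cohesive event, no disjoint", {
  traj <- community_trajectory(rbind(c(1, 2), c(1, 2), c(1, 1)))
  ev <- classify_switches(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "cohesive")
  expect_equal(ev$source, 1)
  expect_equal(ev$destination, 2)
  expect_equal(sort(ev$nodes[[1]]), c(1, 2))
  cm <- cohesion_matrix(traj)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], 0)
  expect_equal(cm[2, 3], 0)
  expect_equal(unname(cohesion_strength(traj)), c(1, 1, 0))
  expect_equal(unname(disjointedness(traj)), c(0, 0, 0))
})

test_that("a lone mover is one disjoint event", {
  traj <- community_trajectory(rbind(c(1, 2), c(1, 1), c(1, 1)))
  ev <- classify_switches(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "disjoint")
  expect_equal(ev$nodes[[1]], 1L)
  expect_equal(unname(disjointedness(traj)), c(1, 0, 0))
  expect_equal(unname(flexibility(traj)), c(1, 0, 0))
})

test_that("community splits and merges give cohesion without disjointedness", {
  # community 1 splits: nodes 3,4 leave together
  split <- community_trajectory(rbind(c(1, 1), c(1, 1), c(1, 2), c(1, 2)))
  ev <- classify_switches(split)
  expect_equal(ev$kind, "cohesive")
  expect_equal(sort(ev$nodes[[1]]), c(3, 4))
  expect_true(all(disjointedness(split) == 0))
  expect_true(sum(cohesion_strength(split)) > 0)

  # two communities merge: nodes 3,4 join community 1 together
  merge <- community_trajectory(rbind(c(1, 1), c(1, 1), c(2, 1), c(2, 1)))
  evm <- classify_switches(merge)
  expect_equal(evm$kind, "cohesive")
  expect_true(all(disjointedness(merge) == 0))
  expect_true(all(cohesion_strength(merge)[3:4] > 0))
})

test_that("static trajectories have empty logs and zero metrics", {
  traj <- community_trajectory(matrix(rep(c(1L, 2L, 2L), 4), 3, 4))
  expect_equal(nrow(classify_switches(traj)), 0)
  expect_true(all(flexibility(traj) == 0))
  expect_true(all(disjointedness(traj) == 0))
  expect_true(all(cohesion_matrix(traj) == 0))
})

test_that("flexibility counts transitions: alternating labels give 1", {
  traj <- community_trajectory(matrix(c(1L, 2L, 1L, 2L), 1))
  expect_equal(unname(flexibility(traj)), 1)
})

test_that("same destination from different sources stays disjoint under the pair rule", {
  traj <- community_trajectory(rbind(c(1, 2), c(3, 2)))
  expect_equal(unname(disjointedness(traj)), c(1, 1))
  expect_equal(unname(disjointedness(traj, rule = "dest-only")), c(0, 0))
  expect_equal(unname(cohesion_strength(traj, rule = "dest-only")), c(1, 1))
})

test_that("three nodes moving together once in T=3 co-switch at rate 1/2", {
  lab <- rbind(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2), c(3, 3, 3))
  traj <- community_trajectory(lab)
  cm <- cohesion_matrix(traj)
  expect_equal(cm[1, 2], 0.5)
  expect_equal(cm[1, 3], 0.5)
  expect_equal(cm[2, 3], 0.5)
  expect_true(all(cm[, 4] == 0))
  expect_equal(unname(cohesion_strength(traj))[1:3], rep(1, 3))
})

test_that("metrics agree exactly with the brute-force oracle on random trajectories", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      n <- sample(2:10, 1)
      tt <- sample(2:8, 1)
      k <- sample(2:5, 1)
      rule <- sample(c("pair", "dest-only"), 1)
      traj <- random_trajectory(n, tt, k)
      o <- oracle_metrics(traj$labels, rule)
      m <- node_metrics(traj, rule = rule)
      expect_identical(m$flexibility, o$flexibility)
      expect_identical(m$disjointedness, o$disjointedness)
      expect_identical(m$cohesion, o$cohesion)
      expect_identical(m$cohesion_strength, o$cohesion_strength)
      expect_identical(bare_matrix(cohesion_matrix(traj, rule)),
                       o$cohesion_matrix)
    }
  })
})

test_that("every change is disjoint or cohesive: f = d + c identically", {
  withr::with_seed(202, {
    for (rep in 1:300) {
      traj <- random_trajectory(sample(2:10, 1), sample(2:8, 1),
                                sample(2:5, 1))
      m <- node_metrics(traj)
      expect_equal(m$flexibility, m$disjointedness + m$cohesion,
                   tolerance = 1e-15)
    }
  })
})

test_that("metrics are equivariant under node permutation", {
  withr::with_seed(33, {
    traj <- random_trajectory(8, 6, 3)
    perm <- sample(8)
    permuted <- community_trajectory(traj$labels[perm, ])
    m1 <- node_metrics(traj)
    m2 <- node_metrics(permuted)
    expect_equal(m2$flexibility, m1$flexibility[perm])
    expect_equal(m2$disjointedness, m1$disjointedness[perm])
    expect_equal(m2$cohesion_strength, m1$cohesion_strength[perm])
    cm1 <- bare_matrix(cohesion_matrix(traj))
    cm2 <- bare_matrix(cohesion_matrix(permuted))
    expect_equal(cm2, cm1[perm, perm])
  })
})

test_that("ensemble metrics average per-run metrics", {
  withr::with_seed(44, {
    t1 <- random_trajectory(6, 5, 3)
    t2 <- random_trajectory(6, 5, 3)
    t3 <- random_trajectory(6, 5, 3)
  })
  single <- ensemble_metrics(list(t1))
  expect_equal(single$disjointedness, node_metrics(t1)$disjointedness)

  m <- ensemble_metrics(list(t1, t2, t3))
  manual <- (node_metrics(t1)$disjointedness +
             node_metrics(t2)$disjointedness +
             node_metrics(t3)$disjointedness) / 3
  expect_equal(m$disjointedness, manual, tolerance = 1e-15)

  g <- glance(m)
  expect_equal(g$mean_disjointedness, mean(manual), tolerance = 1e-15)
  expect_error(ensemble_metrics(list(t1, random_trajectory(5, 5, 3))),
               "share N and T")
})

test_that("metric bounds hold under fuzzing", {
  withr::with_seed(55, {
    for (rep in 1:50) {
      n <- sample(2:10, 1)
      traj <- random_trajectory(n, sample(2:8, 1), sample(2:6, 1))
      m <- node_metrics(traj)
      expect_true(all(m$flexibility >= 0 & m$flexibility <= 1))
      expect_true(all(m$disjointedness >= 0 & m$disjointedness <= 1))
      expect_true(all(m$cohesion_strength >= 0 &
                        m$cohesion_strength <= n - 1))
      cm <- cohesion_matrix(traj)
      expect_true(all(cm >= 0 & cm <= 1))
      expect_true(all(diag(cm) == 0))
      expect_identical(unclass(cm), t(unclass(cm)))
    }
  })
})

test_that("T = 2 trajectories are scored with denominator 1", {
  traj <- community_trajectory(rbind(c(1, 2), c(1, 2), c(2, 2)))
  expect_equal(unname(cohesion_strength(traj)), c(1, 1, 0))
  expect_error(flexibility(community_trajectory(matrix(1L, 3, 1))),
               "T >= 2")
})
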