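test_that("distance conversion follows l = 1/x - 1 with clamping", {
  w <- matrix(c(NA, 1, 0.5, 1, NA, 0.125, 0.5, 0.125, NA), 3, 3)
  dg <- to_distance(fc_matrix(w))
  expect_equal(dg$lengths[1, 2], 0)
  expect_equal(dg$lengths[1, 3], 1)
  expect_equal(dg$lengths[2, 3], 7)
  # zero weight clamps to eps, keeping the edge finite
  w0 <- matrix(c(NA, 0, 0, NA), 2, 2)
  dg0 <- to_distance(fc_matrix(w0), eps = 1e-6)
  expect_equal(dg0$lengths[1, 2], 1e6 - 1)
  expect_error(to_distance(matrix(c(0, 2, 2, 0), 2, 2)), "outside")
})

test_that("worked triangle example: detour beats the direct edge", {
  an <- semimetric_analysis(fig1_triangle())
  expect_equal(an$distance$lengths["A", "C"], 7)
  expect_equal(an$shortest$dist["A", "C"], 6)
  expect_equal(reconstruct_path(an$shortest, 1, 3), c(1, 2, 3))
  expect_equal(an$result$ratio["A", "C"], 7 / 6)
  expect_identical(an$result$labels["A", "C"], "semi_metric")
  expect_identical(an$result$labels["A", "B"], "metric")
  expect_equal(an$smp_global, 1 / 3)
  # one three-node path, two two-node paths
  expect_equal(an$histogram$counts, c("2" = 2L, "3" = 1L))
  expect_equal(an$histogram$fraction_gt2, 1 / 3)
})

test_that("shortest paths, labels and SMP match enumeration oracles", {
  skip_if_not_installed("igraph")
  for (seed in 1:12) {
    n <- sample(4:7, 1)
    fc <- random_fc(n, seed)
    dg <- to_distance(fc)
    sp <- all_pairs_shortest(dg)
    # triangle inequality and upper bound by direct edges
    expect_true(all(sp$dist <= dg$lengths + 1e-12))
    for (k in seq_len(n))
      expect_true(all(sp$dist <= outer(sp$dist[, k], sp$dist[k, ], "+") + 1e-12))
    # agreement with two independent oracles
    expect_equal(unname(sp$dist), unname(oracle_shortest_igraph(dg$lengths)),
                 tolerance = 1e-12)
    or <- oracle_shortest_enum(dg$lengths)
    expect_equal(unname(sp$dist), unname(or$dist), tolerance = 1e-12)
    # labels equal the enumeration verdict edge by edge
    res <- semimetric_ratio(dg, sp)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      semi_or <- dg$lengths[i, j] > or$dist[i, j] + 1e-12
      expect_identical(res$labels[i, j] == "semi_metric", semi_or)
    }
    expect_equal(res$smp_global,
                 sum(dg$lengths[upper.tri(dg$lengths)] >
                       or$dist[upper.tri(or$dist)] + 1e-12) / (n * (n - 1) / 2))
    # ratios never below 1
    expect_true(all(res$ratio[upper.tri(res$ratio)] >= 1 - 1e-12))
  }
})

test_that("uniform complete graphs are fully metric", {
  an <- semimetric_analysis(uniform_fc(6, 0.5))
  expect_equal(an$smp_global, 0)
  expect_equal(an$histogram$fraction_gt2, 0)
})

test_that("metric backbone alone reproduces all shortest-path lengths", {
  for (seed in 1:8) {
    fc <- random_fc(6, seed + 100)
    dg <- to_distance(fc)
    sp <- all_pairs_shortest(dg)
    res <- semimetric_ratio(dg, sp)
    pruned <- dg$lengths
    pruned[res$labels == "semi_metric" & !is.na(res$labels)] <- Inf
    d2 <- semifc:::fw_dist(pruned)
    expect_equal(unname(d2), unname(sp$dist), tolerance = 1e-12)
  }
})

test_that("SMP and histogram are invariant under node relabeling", {
  fc <- random_fc(7, 9)
  an <- semimetric_analysis(fc)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  fc_p <- fc_matrix(fc$weights[perm, perm])
  an_p <- semimetric_analysis(fc_p)
  expect_equal(an_p$smp_global, an$smp_global)
  expect_equal(an_p$histogram$counts, an$histogram$counts)
})

test_that("raising a semi-metric weight far enough flips it to metric", {
  fc <- fig1_triangle()
  w <- fc$weights
  # A-C currently semi-metric; raise its weight until l <= l'
  w["A", "C"] <- w["C", "A"] <- 1 / 7    # l = 6 = shortest detour
  an <- semimetric_analysis(fc_matrix(w))
  expect_identical(an$result$labels["A", "C"], "metric")
  expect_equal(an$smp_global, 0)
})

test_that("regional SMP counts intra-ROI edges and honors exclusions", {
  # planted network: left block metric, right block with one planted edge
  toy <- gen_toy_network(8, planted_semimetric = rbind(c(5, 6)), seed = 2)
  ids <- toy$fc$channel_ids
  roi <- setNames(rep(c("L", "R"), each = 4), ids)
  dg <- to_distance(toy$fc)
  res <- semimetric_ratio(dg, all_pairs_shortest(dg))
  reg <- regional_smp(res, roi)
  expect_equal(unname(reg["L"]), 0)
  expect_equal(unname(reg["R"]), 1 / choose(4, 2))
  # ROI = all nodes reproduces the global value
  roi_all <- setNames(rep("all", 8), ids)
  expect_equal(unname(regional_smp(res, roi_all)["all"]), res$smp_global)
  # excluding the planted edge's endpoint empties the count
  reg_ex <- regional_smp(res, roi, exclusions = ids[5])
  expect_equal(unname(reg_ex["R"]), 0)
  expect_error(regional_smp(res, roi, exclusions = ids[5:7]),
               "fewer than 2")
})

test_that("path graphs route through intermediates", {
  # near-zero A-C weight: the only sensible route is A-B-C
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.8
  w[1, 3] <- w[3, 1] <- 1e-9            # clamped to eps
  an <- semimetric_analysis(fc_matrix(w), eps = 1e-6)
  expect_equal(length(reconstruct_path(an$shortest, 1, 3)), 3L)
  expect_equal(an$shortest$dist[1, 3], 2 * (1 / 0.8 - 1), tolerance = 1e-12)
})
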