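test_that("generators are seed-deterministic", {
  spec <- sim_spec(seed = 12, n_channels = 4, paradigm = short_paradigm())
  a <- gen_fnirs(spec); b <- gen_fnirs(spec)
  expect_identical(a$raw$data, b$raw$data)
  p1 <- gen_ppg(spec, duration_s = 30); p2 <- gen_ppg(spec, duration_s = 30)
  expect_identical(p1$ppg$samples, p2$ppg$samples)
  t1 <- gen_toy_network(6, rbind(c(1, 4)), seed = 3)
  t2 <- gen_toy_network(6, rbind(c(1, 4)), seed = 3)
  expect_identical(t1$fc$weights, t2$fc$weights)
})

test_that("fNIRS generator returns consistent ground truth", {
  spec <- sim_spec(seed = 8, n_channels = 4, paradigm = short_paradigm())
  sim <- gen_fnirs(spec)
  expect_identical(dim(sim$raw$data)[2], 4L)
  # truth components obey the mixing model exactly
  expect_equal(sim$truth$functional$hbr, spec$k1 * sim$truth$functional$hbo)
  expect_equal(sim$truth$systemic$hbr, spec$k2 * sim$truth$systemic$hbo)
  expect_equal(sim$truth$total$hbo,
               sim$truth$functional$hbo + sim$truth$systemic$hbo)
  # intensities strictly positive (valid for the log transform)
  expect_true(all(sim$raw$data > 0))
})

test_that("coupled channels cohere more than uncoupled ones", {
  paradigm <- short_paradigm()
  wins_coupled <- 0L
  for (seed in 1:8) {
    spec_c <- sim_spec(seed = seed, n_channels = 4, paradigm = paradigm,
                       coupling_blocks = rep(1, 4), coupling = 0.6)
    spec_u <- sim_spec(seed = seed, n_channels = 4, paradigm = paradigm,
                       coupling_blocks = 1:4, coupling = 0.6)
    fc_c <- build_fc_matrix(semifc:::gen_fnirs_hemo(spec_c), paradigm,
                            voices = 6)
    fc_u <- build_fc_matrix(semifc:::gen_fnirs_hemo(spec_u), paradigm,
                            voices = 6)
    up <- upper.tri(fc_c$weights)
    if (mean(fc_c$weights[up]) > mean(fc_u$weights[up]))
      wins_coupled <- wins_coupled + 1L
  }
  expect_gte(wins_coupled, 7L)
})

test_that("PPG generator hits its RMSSD target and rejects infeasible ones", {
  pg0 <- gen_ppg(sim_spec(seed = 5, target_rmssd = 0), duration_s = 30)
  expect_equal(pg0$truth$rmssd, 0)
  pg <- gen_ppg(sim_spec(seed = 5, target_rmssd = 40), duration_s = 60)
  expect_equal(pg$truth$rmssd, 40, tolerance = 1e-9)
  expect_error(gen_ppg(sim_spec(seed = 5, target_rmssd = 300)), "infeasible")
  expect_error(sim_spec(mean_hr = 50), "mean_hr")
})

test_that("toy networks plant exactly the requested semi-metric edges", {
  # no planting: uniform-band weights are fully metric
  t0 <- gen_toy_network(7, seed = 1)
  expect_equal(semimetric_analysis(t0$fc)$smp_global, 0)
  for (seed in 1:10) {
    n <- sample(5:8, 1)
    pairs <- utils::combn(n, 2)
    k <- sample(1:2, 1)
    planted <- t(pairs[, sample(ncol(pairs), k), drop = FALSE])
    toy <- gen_toy_network(n, planted, seed = seed)
    an <- semimetric_analysis(toy$fc)
    expect_equal(an$smp_global, toy$smp_true)
    semi <- which(an$result$labels == "semi_metric" &
                    upper.tri(an$result$labels), arr.ind = TRUE)
    got <- semi[order(semi[, 1], semi[, 2]), , drop = FALSE]
    want <- toy$planted[order(toy$planted[, 1], toy$planted[, 2]), ,
                        drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
  # infeasible planting: a triangle cannot have every edge semi-metric
  expect_error(gen_toy_network(3, rbind(c(1, 2), c(1, 3), c(2, 3)), seed = 1),
               "infeasible")
})

test_that("study generator emits a complete balanced table with truth", {
  spec <- sim_spec(seed = 21, n_channels = 4, paradigm = short_paradigm(),
                   n_per_group = c(student = 3, nurse = 3))
  st <- gen_study(spec, indices = c("RMSSD"), ppg_duration_s = 40)
  tab <- st$table
  expect_equal(sort(unique(tab$state)), c("affective", "neutral"))
  expect_equal(nrow(tab), 12)                       # 6 subjects x 2 states
  expect_equal(length(unique(tab$subject)), 6)
  cells <- table(tab$subject, tab$state)
  expect_true(all(cells == 1))
  st2 <- gen_study(spec, indices = c("RMSSD"), ppg_duration_s = 40)
  expect_identical(st$table, st2$table)
})

test_that("planted RMSSD interactions propagate through the pipeline", {
  pe <- list(rmssd = matrix(c(-25, 0, 0, 0), 2, 2,
                            dimnames = list(c("student", "nurse"),
                                            c("affective", "neutral"))))
  hits <- 0L
  for (seed in 1:6) {
    spec <- sim_spec(seed = seed, n_channels = 4,
                     paradigm = short_paradigm(),
                     n_per_group = c(student = 5, nurse = 5),
                     target_rmssd = 55, planted_effects = pe)
    st <- gen_study(spec, indices = "RMSSD", ppg_duration_s = 60,
                    subject_sd = 3)
    tab <- st$table
    m <- tapply(tab$value, list(tab$group, tab$state), mean)
    # planted direction: students lower in affective than neutral
    if (m["student", "affective"] < m["student", "neutral"] &&
        abs(m["nurse", "affective"] - m["nurse", "neutral"]) <
          (m["student", "neutral"] - m["student", "affective"]))
      hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})
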