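test_that("mixed ANOVA agrees with the closed-form sums-of-squares oracle", {
  for (seed in 1:5) {
    tab <- make_balanced_table(seed, effect = 0.4, interaction = 0.6)
    res <- mixed_anova(tab, factors = 2)
    or <- oracle_mixed_anova_2x2(tab)
    expect_equal(res$F[res$effect == "group"], or$F_group, tolerance = 1e-9)
    expect_equal(res$F[res$effect == "state"], or$F_state, tolerance = 1e-9)
    expect_equal(res$F[res$effect == "group x state"], or$F_inter,
                 tolerance = 1e-9)
    expect_equal(res$pes[res$effect == "group"], or$pes_group,
                 tolerance = 1e-9)
    expect_equal(res$pes[res$effect == "group x state"], or$pes_inter,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and malformed designs are handled", {
  tab <- make_balanced_table(1)
  tab$value <- 1                       # identical values everywhere
  res <- mixed_anova(tab, factors = 2)
  # no effect can be declared on constant data
  expect_true(all(is.na(res$p) | res$p > 0.05))
  tab2 <- make_balanced_table(2)
  tab2 <- tab2[-1, ]                   # missing cell
  expect_error(mixed_anova(tab2, factors = 2), "incomplete")
})

test_that("planted interactions are detected with high power", {
  hits <- 0L
  for (seed in 1:20) {
    tab <- make_balanced_table(seed, n_per_group = 8, interaction = 2)
    res <- mixed_anova(tab, factors = 2)
    if (res$p[res$effect == "group x state"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("three-way mixed ANOVA runs and finds a planted region effect", {
  set.seed(10)
  rows <- list(); sid <- 0
  for (g in c("student", "nurse")) for (k in 1:6) {
    sid <- sid + 1
    for (s in c("affective", "neutral")) for (r in c("left", "right")) {
      val <- rnorm(1, sd = 0.3) +
        (g == "student" && s == "affective" && r == "right") * 2
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("s%02d", sid), group = g, state = s, region = r,
        index = "SMP", value = val)
    }
  }
  tab <- do.call(rbind, rows)
  res <- mixed_anova(tab, factors = 3)
  expect_true("group x state x region" %in% res$effect)
  expect_lt(res$p[res$effect == "group x state x region"], 0.01)
  expect_true(all(res$pes >= 0 & res$pes <= 1, na.rm = TRUE))
})

test_that("t tests and Cohen's d match hand-computed formulas", {
  x <- c(5.1, 4.8, 5.6, 5.0, 5.3)
  y <- c(4.2, 4.6, 4.9, 4.4, 4.8)
  pt <- paired_t(x, y)
  d <- x - y
  expect_equal(pt$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(pt$d, mean(d) / sd(d), tolerance = 1e-12)

  it <- independent_t(x, y)
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  expect_equal(it$t, (mean(x) - mean(y)) / (sp * sqrt(2 / 5)),
               tolerance = 1e-12)
  expect_equal(it$d, (mean(x) - mean(y)) / sp, tolerance = 1e-12)

  # identical paired vectors: zero differences, degenerate
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x - 1), "zero variance")
})

test_that("BH adjustment equals the step-up oracle on random p-lists", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(2:30, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("state-change correlation matches its definition and the null", {
  # perfect negative linear relation
  tab <- NULL
  set.seed(3)
  for (i in 1:8) {
    dr <- rnorm(1)
    tab <- rbind(tab,
      data.frame(subject = i, group = "g", state = "affective",
                 region = "global", index = "RMSSD", value = 10 + dr),
      data.frame(subject = i, group = "g", state = "neutral",
                 region = "global", index = "RMSSD", value = 10),
      data.frame(subject = i, group = "g", state = "affective",
                 region = "global", index = "SMP", value = 1 - 2 * dr),
      data.frame(subject = i, group = "g", state = "neutral",
                 region = "global", index = "SMP", value = 1))
  }
  res <- delta_correlation(tab, "RMSSD", "SMP")
  expect_equal(res$r, -1, tolerance = 1e-9)

  # independent changes: mean |r| small across simulations
  rs <- vapply(1:60, function(seed) {
    set.seed(seed)
    t2 <- NULL
    for (i in 1:38) {
      t2 <- rbind(t2,
        data.frame(subject = i, group = "g", state = c("affective", "neutral"),
                   region = "global", index = "RMSSD", value = rnorm(2)),
        data.frame(subject = i, group = "g", state = c("affective", "neutral"),
                   region = "global", index = "SMP", value = rnorm(2)))
    }
    abs(delta_correlation(t2, "RMSSD", "SMP")$r)
  }, numeric(1))
  expect_lt(mean(rs), 0.2)

  # hand-computed covariance ratio on a 5-pair fixture
  dx <- c(1, 2, 3, 4, 5); dy <- c(2, 1, 4, 3, 6)
  t3 <- NULL
  for (i in 1:5) t3 <- rbind(t3,
    data.frame(subject = i, group = "g", state = c("affective", "neutral"),
               region = "global", index = "A", value = c(dx[i], 0)),
    data.frame(subject = i, group = "g", state = c("affective", "neutral"),
               region = "global", index = "B", value = c(dy[i], 0)))
  expect_equal(delta_correlation(t3, "A", "B")$r,
               cov(dx, dy) / (sd(dx) * sd(dy)), tolerance = 1e-12)
})

test_that("pairwise comparison tables adjust p values as one family", {
  tab <- make_balanced_table(4, interaction = 1.5)
  res <- pairwise_comparisons(tab, index = "SMP")
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  expect_equal(res$p_fdr, oracle_bh(res$p), tolerance = 1e-12)
})

test_that("simple effects split and rerun within levels", {
  tab <- make_balanced_table(6, interaction = 2)
  se <- simple_effects(tab, split_by = "group", index = "SMP", factors = 1)
  expect_named(se, c("student", "nurse"), ignore.order = TRUE)
  expect_lt(se$student$p, se$nurse$p)
})
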