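test_that("one-way ANOVA matches hand computation and handles degeneracy", {
  tab <- counts_to_table(
    cbind(b1 = c(1, 9), b2 = c(2, 8), b3 = c(3, 7),
          b4 = c(2, 8), b5 = c(3, 7), b6 = c(4, 6),
          b7 = c(3, 7), b8 = c(4, 6), b9 = c(5, 5)) * 10,
    rep(c("g1", "g2", "g3"), each = 3), c("A", "B"))
  # region A percents are {10,20,30}, {20,30,40}, {30,40,50}:
  # SSB = 600, SSW = 600 (percent scale), F = 3.0 with df (2, 6)
  res <- anova_by_region(build_condition_profiles(tab), regions = "A")
  expect_equal(res$statistic, 3, tolerance = 1e-9)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p.value, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups with nonzero spread -> F = 0
  tab0 <- counts_to_table(cbind(b1 = c(1, 9), b2 = c(2, 8),
                                b3 = c(1, 9), b4 = c(2, 8)) * 10,
                          rep(c("g1", "g2"), each = 2), c("A", "B"))
  res0 <- anova_by_region(build_condition_profiles(tab0))
  expect_equal(res0$statistic, c(0, 0), tolerance = 1e-12)

  # zero within-group variance with unequal means errors
  tabz <- counts_to_table(cbind(b1 = c(1, 9), b2 = c(1, 9),
                                b3 = c(3, 7), b4 = c(3, 7)) * 10,
                          rep(c("g1", "g2"), each = 2), c("A", "B"))
  expect_error(anova_by_region(build_condition_profiles(tabz)),
               "zero within-group variance")
})

test_that("under permuted labels the ANOVA p-value is uniform", {
  withr::with_seed(11, {
    pv <- replicate(400, {
      x <- rnorm(12)
      g <- rep(c("a", "b", "c"), each = 4)
      stats_df <- tibble::tibble(condition = g, region = "R",
                                 percent = x, region_id = 1L,
                                 starter_excluded = FALSE, brain_id = paste0("b", 1:12))
      anova_by_region(structure(list(), class = "condition_profiles",
                                replicates = stats_df))$p.value
    })
  })
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.035)
})

test_that("Holm-Sidak thresholds and step-down decisions are exact", {
  hs <- holm_sidak(c(0.001, 0.01, 0.04), alpha = 0.05)
  # oracle: direct formula evaluation
  expect_equal(hs$threshold,
               c(1 - 0.95^(1 / 3), 1 - 0.95^(1 / 2), 1 - 0.95), tolerance = 1e-12)
  expect_equal(hs$threshold, c(0.016952, 0.025321, 0.05), tolerance = 1e-4)
  expect_true(all(hs$reject))

  # single p compares directly to alpha
  expect_true(holm_sidak(0.049)$reject)
  expect_false(holm_sidak(0.051)$reject)
  # all p = 1 -> none rejected
  expect_false(any(holm_sidak(rep(1, 5))$reject))
  # step-down: a failure blocks all larger p-values even below threshold
  hs2 <- holm_sidak(c(0.5, 0.001, 0.04))
  expect_equal(hs2$reject, c(FALSE, TRUE, FALSE))
  expect_error(holm_sidak(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak sits between Bonferroni and uncorrected testing", {
  withr::with_seed(12, {
    for (i in 1:50) {
      m <- sample(1:12, 1)
      p <- runif(m)^sample(1:3, 1)
      hs <- holm_sidak(p)
      bonf <- p <= 0.05 / m
      raw <- p <= 0.05
      expect_true(all(hs$reject[bonf]))   # superset of Bonferroni
      expect_true(all(raw[hs$reject]))    # subset of uncorrected
    }
  })
})

test_that("the pooled t-test matches its closed form", {
  eq <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  expect_error(two_sample_ttest(c(0, 0, 0, 0), c(1, 1, 1, 1)),
               "zero pooled variance")
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")

  tt <- two_sample_ttest(c(1, 2), c(3, 4))
  # closed form: t = -2 sqrt(2), df = 2; CDF of t_2: 1/2 + t / (2 sqrt(2 + t^2))
  t_oracle <- -2 * sqrt(2)
  p_oracle <- 2 * (0.5 + t_oracle / (2 * sqrt(2 + t_oracle^2)))
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-9)
  expect_equal(tt$df, 2)
  expect_equal(tt$p.value, p_oracle, tolerance = 1e-9)
  expect_equal(tt$p.value, 0.105572809, tolerance = 1e-6)
})

test_that("correlation matrices are valid and exact on collinear profiles", {
  tab <- counts_to_table(cbind(b1 = c(1, 2, 3), b2 = c(2, 4, 6),
                               b3 = c(3, 2, 1)) * 100,
                         c("u", "v", "w"), c("A", "B", "C"))
  cm <- correlation_matrix(build_condition_profiles(tab))
  expect_equal(unname(diag(unclass(cm))), rep(1, 3))
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_true(all(unclass(cm) >= -1 & unclass(cm) <= 1))
  expect_equal(cm["u", "v"], 1)   # [1,2,3] vs [2,4,6]
  expect_equal(cm["u", "w"], -1)  # [1,2,3] vs [3,2,1]
})

test_that("UPGMA clustering on 1 - r matches a hand computation", {
  # 2 conditions: single merge at 1 - r
  tab2 <- counts_to_table(cbind(b1 = c(5, 3, 2), b2 = c(2, 3, 5)) * 100,
                          c("u", "v"), c("A", "B", "C"))
  cm2 <- correlation_matrix(build_condition_profiles(tab2))
  dd2 <- hierarchical_cluster(cm2)
  expect_equal(length(dd2$height), 1)
  expect_equal(dd2$height, 1 - cm2["u", "v"], tolerance = 1e-12)

  # 3 items with d(A,B) = 0.1, d(A,C) = d(B,C) = 0.9
  m <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # encode distances directly: d = 1 - r, so r(A,B) = 0.9; r(to C) = 0.1
  cm3 <- structure(m, class = "correlation_matrix")
  dd3 <- hierarchical_cluster(cm3)
  expect_equal(dd3$height, c(0.1, 0.9), tolerance = 1e-12)
  expect_equal(sort(dd3$labels[-dd3$merge[1, ]]), c("A", "B"))
  expect_equal(outgroup_label(dd3), "C")
})

test_that("UPGMA agrees with brute-force recomputation up to 8 x 8", {
  withr::with_seed(13, {
    for (k in c(4, 6, 8)) {
      r <- matrix(runif(k * k, -0.5, 0.99), k, k)
      r <- (r + t(r)) / 2; diag(r) <- 1
      dimnames(r) <- list(letters[1:k], letters[1:k])
      cm <- structure(r, class = "correlation_matrix")
      dd <- hierarchical_cluster(cm)
      oracle <- upgma_oracle(1 - r)
      expect_equal(dd$height, oracle$heights, tolerance = 1e-9)
    }
  })
})

test_that("reciprocity comparison is calibrated under the null and powered", {
  at <- test_atlas
  regions <- c("cortex", "GP", "ZI", "Amy")
  p0 <- c(cortex = 0.6, GP = 0.15, ZI = 0.15, Amy = 0.1)
  mapping <- list(c1 = "GP", c2 = "ZI", c3 = "Amy")
  # null: all conditions share one input distribution
  withr::with_seed(14, {
    rej <- replicate(60, {
      counts <- rmultinom(9, 2000, p0)
      colnames(counts) <- paste0("b", 1:9)
      tab <- counts_to_table(counts, rep(c("c1", "c2", "c3"), each = 3),
                             names(p0))
      any(reciprocity_compare(tab, mapping, at)$p.value < 0.05)
    })
  })
  # familywise over 3 tests at alpha = 0.05: expect well under 0.3
  expect_lt(mean(rej), 0.3)
  expect_gt(mean(rej), 0)

  # planted reciprocity: own-region fraction x2, n = 4 brains/condition
  withr::with_seed(15, {
    hits <- replicate(40, {
      mk <- function(cond) {
        p <- p0
        p[[mapping[[cond]]]] <- 2 * p[[mapping[[cond]]]]
        p <- p / sum(p)
        rmultinom(4, 2000, p)
      }
      counts <- cbind(mk("c1"), mk("c2"), mk("c3"))
      colnames(counts) <- paste0("b", 1:12)
      tab <- counts_to_table(counts, rep(c("c1", "c2", "c3"), each = 4),
                             names(p0))
      rc <- reciprocity_compare(tab, mapping, at)
      all(rc$p.value < 0.05 & rc$own_mean > rc$others_mean)
    })
  })
  expect_gte(mean(hits), 0.8)

  # a single condition has no comparison group
  one <- counts_to_table(matrix(c(100, 100), 2, dimnames = list(NULL, "b1")),
                         "c1", c("A", "B"))
  expect_error(reciprocity_compare(one, list(c1 = "A"), at), "2 conditions")
})

test_that("the null-calibration simulator computes the same F as the tester", {
  sim <- holm_sidak_fwe_sim(n_reps = 200, seed = 3)
  expect_lt(sim$fwe, 0.05 + 3 * sqrt(0.05 * 0.95 / 200) + 0.02)
  # cross-check the vectorized F against anova_by_region on one draw
  withr::with_seed(4, {
    counts <- rmultinom(8, 1000, rep(0.25, 4))
  })
  colnames(counts) <- paste0("b", 1:8)
  tab <- counts_to_table(counts, rep(c("x", "y"), each = 4),
                         c("A", "B", "C", "D"))
  ref <- anova_by_region(build_condition_profiles(tab))
  pct <- 100 * sweep(counts, 2, colSums(counts), `/`)
  for (r in 1:4) {
    gm <- matrix(pct[r, ], 4)
    cmn <- colMeans(gm)
    ssb <- 4 * sum((cmn - mean(cmn))^2)
    ssw <- sum(sweep(gm, 2, cmn)^2)
    f <- (ssb / 1) / (ssw / 6)
    expect_equal(ref$statistic[ref$region == LETTERS[r]], f, tolerance = 1e-9)
  }
})
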