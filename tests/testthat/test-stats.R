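test_that("2x2 exact p agrees with the standard Fisher test to 1e-10", {
  tables <- list(
    matrix(c(65, 41, 68, 23), 2),
    matrix(c(3, 1, 1, 3), 2),
    matrix(c(10, 2, 3, 15), 2),
    matrix(c(1, 9, 11, 3), 2),
    matrix(c(12, 12, 12, 12), 2)
  )
  for (tb in tables) {
    expect_equal(fisher_exact_rxc(tb)$p_value,
                 fisher.test(tb)$p.value, tolerance = 1e-10)
  }
})

test_that("r x c enumeration matches fisher.test and is permutation invariant", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      tb <- matrix(rpois(6, 5), 3, 2)
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
      p <- fisher_exact_rxc(tb)
      expect_identical(p$method, "enumeration")
      expect_equal(p$p_value, fisher.test(tb)$p.value, tolerance = 1e-8)
      expect_equal(fisher_exact_rxc(tb[sample(3), sample(2)])$p_value,
                   p$p_value, tolerance = 1e-12)
    }
  })
})

test_that("all-zero rows cannot affect the exact test", {
  with_zero <- rbind(c(0, 0), c(5, 4), c(101, 87))
  without <- rbind(c(5, 4), c(101, 87))
  expect_equal(suppressMessages(fisher_exact_rxc(with_zero))$p_value,
               fisher_exact_rxc(without)$p_value, tolerance = 1e-12)
})

test_that("degenerate and invalid contingency tables are handled", {
  expect_warning(res <- suppressMessages(
    fisher_exact_rxc(rbind(c(3, 4), c(0, 0)))), "degenerate")
  expect_identical(res$p_value, 1)
  expect_error(fisher_exact_rxc(matrix(c(1.5, 2, 3, 4), 2)), "non-integer")
  expect_error(fisher_exact_rxc(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("Monte-Carlo branch agrees with enumeration within 3 SE", {
  withr::with_seed(52, {
    for (rep in 1:3) {
      tb <- matrix(rpois(6, 4) + 1, 3, 2)
      exact <- fisher_exact_rxc(tb)$p_value
      mc <- fisher_exact_rxc(tb, max_tables = 0, mc_draws = 2e5, seed = rep)
      expect_identical(mc$method, "monte_carlo")
      expect_lt(abs(mc$p_value - exact), 3 * max(mc$mc_se, 1e-6))
    }
  })
  # deterministic given seed
  tb <- matrix(c(8, 3, 4, 9, 2, 7), 3)
  m1 <- fisher_exact_rxc(tb, max_tables = 0, mc_draws = 1e4, seed = 5)
  m2 <- fisher_exact_rxc(tb, max_tables = 0, mc_draws = 1e4, seed = 5)
  expect_identical(m1$p_value, m2$p_value)
})

test_that("pooled t-test matches t.test and handles degenerate input", {
  expect_equal(two_sample_t(c(1, 2, 3, 1, 2, 3),
                            rep(c("a", "b"), each = 3))$p_value, 1)
  withr::with_seed(53, {
    x <- rnorm(20); g <- rep(c("a", "b"), 10)
  })
  ours <- two_sample_t(x, g)
  ref <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$t), unname(ref$statistic), tolerance = 1e-12)

  # missing values excluded pairwise
  xm <- c(x, NA); gm <- c(g, "a")
  expect_equal(two_sample_t(xm, gm)$p_value, ours$p_value)

  # zero pooled variance
  expect_identical(two_sample_t(c(5, 5, 5, 5), c("a", "a", "b", "b"))$p_value, 1)
  zt <- two_sample_t(c(5, 5, 7, 7), c("a", "a", "b", "b"))
  expect_identical(zt$p_value, 0)
  expect_true(zt$degenerate)
  expect_error(two_sample_t(1:3, c("a", "b", "c")), "two groups")
})

test_that("t-test power at a 1-SD shift matches the closed form", {
  n <- 50; delta <- 1; alpha <- 0.05
  ncp <- delta / sqrt(2 / n)
  tcrit <- qt(1 - alpha / 2, df = 2 * n - 2)
  power_theory <- pt(-tcrit, df = 2 * n - 2, ncp = ncp) +
    1 - pt(tcrit, df = 2 * n - 2, ncp = ncp)
  withr::with_seed(54, {
    rej <- vapply(1:400, function(i) {
      v <- c(rnorm(n), rnorm(n, delta))
      two_sample_t(v, rep(c("a", "b"), each = n))$p_value < alpha
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - power_theory),
            3 * sqrt(power_theory * (1 - power_theory) / 400))
})

test_that("association report computes tests and prevalences per column", {
  labels <- rep(c(1L, 2L), c(70, 66))
  # males: 37 subtype 1, 23 subtype 2; females: 33 and 43
  sex <- c(rep("Male", 37), rep("Female", 33), rep("Male", 23), rep("Female", 43))
  mmse <- c(rnorm(70, 14, 3), rnorm(66, 12, 3))
  meta <- data.frame(sample_id = sprintf("s%03d", 1:136), sex = factor(sex),
                     mmse = mmse, single = factor(rep("x", 136)))
  attr(meta, "schema") <- c(sex = "categorical", mmse = "continuous",
                            single = "categorical")
  class(meta) <- c("metadata_table", "data.frame")
  assign <- subtype_assignment(setNames(labels, meta$sample_id),
                               rep(0.5, 136))
  rep_ <- suppressMessages(association_report(assign, meta))
  expect_identical(rep_$results$sex$test, "fisher_exact")
  expect_equal(rep_$results$sex$p_value,
               fisher.test(table(sex, labels))$p.value, tolerance = 1e-8)
  expect_equal(unname(rep_$results$sex$prevalence_pct["Male", "1"]), 61.7)
  expect_identical(rep_$results$mmse$test, "t_test")
  expect_identical(rep_$results$single$test, "skipped")
  expect_error(association_report(assign,
    within(meta, sample_id <- paste0("x", sample_id))), "overlap")
})

test_that("hypergeometric ORA follows the closed formulas", {
  universe <- sprintf("u%03d", 1:500)
  set10 <- universe[1:10]
  query <- c(universe[1:5], universe[101:145])   # n = 50, overlap 5
  ora <- hypergeometric_ora(query, universe, list(S = set10))
  expect_equal(ora$fold_enrichment, 5)
  expect_equal(ora$p_value, phyper(4, 10, 490, 50, lower.tail = FALSE))

  # query = universe: every set at fold 1, p 1
  ora_full <- hypergeometric_ora(universe, universe,
                                 list(A = set10, B = universe[30:60]))
  expect_true(all(ora_full$fold_enrichment == 1))
  expect_true(all(ora_full$p_value == 1))

  expect_error(hypergeometric_ora(c("zz"), universe, list(S = set10)),
               "subset")
  expect_error(hypergeometric_ora(character(), universe, list(S = set10)),
               "empty query")
})
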