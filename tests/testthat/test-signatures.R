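test_that("silhouette widths match the defining formulas", {
  # 1-D: {0, 0.2} vs {10, 10.2}
  X <- matrix(c(0, 0.2, 10, 10.2), 1,
              dimnames = list("g", c("a", "b", "c", "d")))
  s <- silhouette_scores(X, c(1, 1, 2, 2))
  expect_equal(unname(s["a"]), (10.1 - 0.2) / 10.1, tolerance = 1e-12)

  # a sample equidistant between clusters: a = b -> s = 0
  Xe <- matrix(c(0, 2, 4), 1, dimnames = list("g", c("a", "b", "c")))
  se <- silhouette_scores(Xe, c(1, 1, 2))
  expect_equal(unname(se["b"]), 0)

  # a sample mislabeled into the far cluster scores negative
  Xm <- matrix(c(0, 0.1, 0.2, 10, 10.1), 1,
               dimnames = list("g", sprintf("s%d", 1:5)))
  sm <- silhouette_scores(Xm, c(1, 1, 2, 2, 2))
  expect_lt(sm["s3"], 0)

  expect_error(silhouette_scores(X, rep(1, 4)), "2 clusters")
})

test_that("silhouette agrees with the brute-force oracle to 1e-12", {
  withr::with_seed(41, {
    for (rep in 1:3) {
      X <- matrix(rnorm(5 * 20), 5, 20,
                  dimnames = list(NULL, sprintf("s%02d", 1:20)))
      labels <- sample(1:3, 20, replace = TRUE)
      expect_equal(unname(silhouette_scores(X, labels)),
                   silhouette_brute(X, labels), tolerance = 1e-12)
    }
  })
})

test_that("core mask keeps strictly positive silhouettes", {
  expect_identical(core_sample_mask(c(0.5, -0.1, 0.3)), c(TRUE, FALSE, TRUE))
  expect_identical(core_sample_mask(c(0, 1e-12)), c(FALSE, TRUE))
  expect_true(all(core_sample_mask(c(0.1, 0.9))))
})

test_that("planted mislabeled samples are flagged non-core", {
  sim <- small_cohort(seed = 42, log2fc = 3, n_samples = 80)
  expr <- suppressMessages(preprocess_counts(sim$counts, quick_config()))
  labels <- sim$truth$label
  withr::with_seed(1, flip <- sample(length(labels), 4))   # 5% mislabeled
  labels[flip] <- 3L - labels[flip]
  s <- silhouette_scores(expr, labels)
  expect_gt(mean(!core_sample_mask(s)[flip]), 0.8)
})

test_that("differential expression recovers planted effects and handles ties", {
  sim <- small_cohort(seed = 43, log2fc = 2, n_genes = 400, n_samples = 80,
                      n_sig = 40)
  cpm <- normalize_cpm(sim$counts)
  de <- differential_expression(cpm, sim$truth$label, pair = c(1, 2))
  expect_s3_class(de, "de_table")
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  planted <- unlist(sim$truth$signature_genes)
  hits <- de$gene[de$fdr <= 0.05 & abs(de$log2_fold_change) >= log2(1.5)]
  expect_gt(mean(planted %in% hits), 0.9)

  # a gene identical in both groups: p = 1, log2FC = 0
  X <- rbind(flat = rep(c(5, 5), each = 4),
             diff = rep(c(100, 2), each = 4))
  colnames(X) <- sprintf("s%d", 1:8)
  d2 <- differential_expression(X, rep(c(1, 2), each = 4), c(1, 2))
  expect_equal(d2[d2$gene == "flat", "p_value"], 1)
  expect_equal(d2[d2$gene == "flat", "log2_fold_change"], 0)
  expect_true(d2[d2$gene == "flat", "degenerate"])
  expect_equal(d2[d2$gene == "diff", "p_value"], 0)
})

test_that("BH adjustment is monotone and threshold sets nest", {
  withr::with_seed(44, p <- runif(200)^2)
  fdr <- p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(fdr[ord]) >= -1e-12))
  sim <- small_cohort(seed = 45)
  cpm <- normalize_cpm(sim$counts)
  de <- differential_expression(cpm, sim$truth$label, c(1, 2))
  set_strict <- de$gene[de$fdr <= 0.01]
  set_loose <- de$gene[de$fdr <= 0.10]
  expect_true(all(set_strict %in% set_loose))
})

test_that("signature definition applies both gates and assigns disjointly", {
  de <- structure(data.frame(
    gene = c("g_pass", "g_fc_fail", "g_fdr_fail"),
    mean_1 = c(100, 100, 300), mean_2 = c(50, 80, 90),
    log2_fold_change = log2(c(101 / 51, 1.4, 3)),
    p_value = c(0.001, 0.001, 0.01),
    fdr = c(0.04, 0.04, 0.06),
    up_in = c(1, 1, 1), degenerate = FALSE,
    stringsAsFactors = FALSE), class = c("de_table", "data.frame"))
  X <- rbind(g_pass = c(100, 100, 50, 50),
             g_fc_fail = c(100, 100, 80, 80),
             g_fdr_fail = c(300, 300, 90, 90))
  colnames(X) <- sprintf("s%d", 1:4)
  labels <- c(1, 1, 2, 2)
  expect_warning(sigs <- define_signatures(de, 1.5, 0.05, X = X,
                                           labels = labels),
                 "empty signature")
  expect_identical(sigs$signatures[["1"]]$gene, "g_pass")
  expect_identical(nrow(sigs$signatures[["2"]]), 0L)

  # disjointness on real simulated output, any k
  sim <- small_cohort(seed = 46)
  cpm <- normalize_cpm(sim$counts)
  de2 <- differential_expression(cpm, sim$truth$label, c(1, 2))
  s2 <- define_signatures(de2, 1.5, 0.05, X = cpm, labels = sim$truth$label)
  expect_length(intersect(s2$signatures[["1"]]$gene,
                          s2$signatures[["2"]]$gene), 0)
  # ordered by ascending FDR
  for (t in names(s2$signatures))
    expect_false(is.unsorted(s2$signatures[[t]]$fdr))
})

test_that("the specified DE engine agrees in direction with an NB engine", {
  # independent cross-check: edgeR's exact NB test on the same planted data
  # should call the same genes' directions
  sim <- small_cohort(seed = 47, log2fc = 2, n_genes = 200, n_samples = 60,
                      n_sig = 20)
  cpm <- normalize_cpm(sim$counts)
  de <- differential_expression(cpm, sim$truth$label, c(1, 2))
  y <- edgeR::DGEList(counts = sim$counts,
                      group = factor(sim$truth$label))
  y <- edgeR::estimateDisp(edgeR::calcNormFactors(y))
  et <- edgeR::exactTest(y, pair = c("2", "1"))$table   # logFC of 1 vs 2
  top <- de$gene[de$fdr < 1e-4]
  expect_gt(length(top), 10)
  expect_true(all(sign(de$log2_fold_change[match(top, de$gene)]) ==
                    sign(et[top, "logFC"])))
})
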