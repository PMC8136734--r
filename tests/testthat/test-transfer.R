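# a small signature set over two planted blocks, built by hand
toy_signatures <- function(genes1, genes2) {
  structure(list(
    signatures = list(
      "1" = data.frame(gene = genes1, log2_fold_change = 1,
                       fdr = seq(0.001, 0.01, length.out = length(genes1))),
      "2" = data.frame(gene = genes2, log2_fold_change = 1,
                       fdr = seq(0.001, 0.01, length.out = length(genes2)))),
    universe = c(genes1, genes2)), class = "signature_set")
}

# expression where block 1 genes are high in cluster-A samples and block 2
# genes high in cluster-B samples
toy_validation <- function(n_a = 6, n_b = 6, seed = 1) {
  g1 <- sprintf("g1_%d", 1:8); g2 <- sprintf("g2_%d", 1:8)
  withr::with_seed(seed, {
    m <- matrix(rexp(16 * (n_a + n_b), 1 / 10), 16,
                dimnames = list(c(g1, g2),
                                sprintf("v%02d", seq_len(n_a + n_b))))
  })
  m[g1, seq_len(n_a)] <- m[g1, seq_len(n_a)] + 60
  m[g2, n_a + seq_len(n_b)] <- m[g2, n_a + seq_len(n_b)] + 60
  list(expr = m, sigs = toy_signatures(g1, g2),
       truth = rep(c("1", "2"), c(n_a, n_b)))
}

test_that("signature projection subsets, warns on misses, and min-shifts", {
  tv <- toy_validation()
  proj <- project_signatures(tv$expr, tv$sigs)
  expect_identical(rownames(proj$matrix), signature_genes(tv$sigs))
  expect_length(proj$missing_genes, 0)
  expect_identical(proj$source_scale_tag, "asis")

  # 2 of 16 genes absent -> warning, rows shrink
  expect_warning(p2 <- project_signatures(tv$expr[-c(1, 9), ], tv$sigs),
                 "absent")
  expect_identical(nrow(p2$matrix), 14L)
  expect_identical(p2$missing_genes, c("g1_1", "g2_1"))

  # negative (log-ratio-like) input is min-shifted per gene to exactly 0
  neg <- tv$expr - 40
  p3 <- project_signatures(neg, tv$sigs)
  expect_true(all(p3$matrix >= 0))
  shifted <- apply(neg, 1, min) < 0
  expect_true(all(abs(apply(p3$matrix, 1, min)[shifted]) < 1e-12))
  expect_identical(p3$source_scale_tag, "minshifted")

  # <50% matched is an error
  expect_error(project_signatures(tv$expr[1:6, ], tv$sigs), "50%")
})

test_that("identity assignment matches planted clusters and is permutation invariant", {
  tv <- toy_validation()
  proj <- project_signatures(tv$expr, tv$sigs)
  labels <- rep(c(1L, 2L), c(6, 6))
  id <- assign_subtype_identity(proj, labels, tv$sigs)
  expect_identical(unname(id$map), c("1", "2"))
  expect_identical(unname(id$sample_subtype), tv$truth)
  expect_identical(dim(id$score_matrix), c(2L, 2L))

  # renumber clusters: per-sample subtype naming unchanged
  id_sw <- assign_subtype_identity(proj, 3L - labels, tv$sigs)
  expect_identical(unname(id_sw$sample_subtype), tv$truth)

  # positive per-gene rescaling leaves the assignment unchanged
  sc <- proj
  sc$matrix <- proj$matrix * runif(nrow(proj$matrix), 0.5, 2)
  id_sc <- assign_subtype_identity(sc, labels, tv$sigs)
  expect_identical(id_sc$map, id$map)

  expect_error(assign_subtype_identity(proj, rep(1L, 12), tv$sigs),
               "must equal")
})

test_that("projected clustering recovers the planted validation split", {
  tv <- toy_validation(n_a = 10, n_b = 10, seed = 3)
  proj <- project_signatures(tv$expr, tv$sigs)
  cfg <- analysis_config(k_candidates = 2:3, n_nmf_runs = 8, base_seed = 4)
  sel <- suppressMessages(cluster_projected(proj, cfg))
  expect_identical(sel$k, 2L)
  id <- assign_subtype_identity(proj, sel$labels, tv$sigs)
  expect_gte(mean(id$sample_subtype == tv$truth), 0.95)
  # determinism under a fixed seed
  sel2 <- suppressMessages(cluster_projected(proj, cfg))
  expect_identical(sel$labels, sel2$labels)
})

test_that("the signature heatmap is written deterministically", {
  tv <- toy_validation()
  proj <- project_signatures(tv$expr, tv$sigs)
  labels <- rep(c(1L, 2L), c(6, 6))
  f <- withr::local_tempfile(fileext = ".png")
  plot_signature_heatmap(proj, labels, tv$sigs, f)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 0)
})
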