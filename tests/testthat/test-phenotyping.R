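test_that("variant mean profiles are per-variant cell averages", {
  counts <- matrix(c(2L, 0L, 4L,   # cell 1 (V1)
                     6L, 0L, 0L,   # cell 2 (V1)
                     1L, 1L, 1L),  # cell 3 (V2)
                   nrow = 3)
  scr <- make_mini_screen(counts, variant = c("V1", "V1", "V2"))
  scr <- lognormalize(scr, pipeline_config())
  ln <- as.matrix(SummarizedExperiment::assay(scr, "logcounts"))
  prof <- variant_mean_profiles(scr)
  expect_equal(prof["V1", ], (ln[, 1] + ln[, 2]) / 2)
  expect_equal(prof["V2", ], ln[, 3])   # single-cell variant = that cell
})

test_that("variant clustering merges identical profiles first and orders
           leaves by T2", {
  set.seed(13)
  base <- rnorm(20)
  prof <- rbind(A = base + rnorm(20, sd = 1.5),
                B = base, C = base,       # identical pair
                D = -base)
  t2 <- c(A = 5, B = 1, C = 2, D = 50)
  hc <- hcluster_variants(prof, t2, k = 2)
  merged_first <- hc$hclust$merge[1, ]
  expect_setequal(rownames(prof)[-merged_first], c("B", "C"))
  expect_equal(hc$clusters[["B"]], hc$clusters[["C"]])

  # profiles on an arc in correlation space (pairwise correlation decays
  # with index distance) with increasing t2: leaves come out in t2 order
  u1 <- rnorm(40); u2 <- rnorm(40)
  u1 <- u1 - mean(u1); u2 <- u2 - mean(u2)
  u2 <- u2 - u1 * sum(u1 * u2) / sum(u1^2)
  ang <- c(0, 0.3, 0.6, 0.9, 1.2)
  chain <- t(vapply(ang, function(a) cos(a) * u1 + sin(a) * u2,
                    numeric(40)))
  rownames(chain) <- paste0("V", 1:5)
  t2c <- c(V1 = 1, V2 = 2, V3 = 3, V4 = 4, V5 = 5)
  hcc <- hcluster_variants(chain, t2c)
  expect_equal(hcc$order, paste0("V", 1:5))

  flat <- rbind(X = rep(1, 5), Y = rnorm(5))
  expect_error(hcluster_variants(flat, c(X = 1, Y = 2)), "zero-variance")
})

test_that("planted classes separate in profile space", {
  cfg <- sim_config(n_genes = 400, n_cells_per_variant = 50,
                    n_variants_per_class = c(wt_like = 4, lof_like = 4,
                                             hypomorphic = 4),
                    module_size = 40, n_mito = 10, n_ribo = 20, seed = 14)
  sim <- simulate_screen(cfg)
  pc <- pipeline_config(n_hvg = 300, seed = 14)
  scr <- lognormalize(qc_filter(sim$screen, pc), pc)
  hv <- select_hvg(scr, pc)
  labels <- SummarizedExperiment::colData(scr)$variant
  prof <- variant_mean_profiles(scr, labels, hv$genes)
  prof <- prof[!rownames(prof) %in% c("WT", "LoF"), ]
  t2_fake <- stats::setNames(seq_len(nrow(prof)), rownames(prof))
  hc <- hcluster_variants(prof, t2_fake, k = 3)
  truth <- sim$truth$variant_class[rownames(prof)]
  expect_gte(ari(hc$clusters, truth), 0.9)

  # gene clustering: identical gene columns co-cluster
  gp <- cbind(prof, dup1 = prof[, 1], dup2 = prof[, 1])
  gc <- hcluster_genes(gp, k = 5)
  expect_equal(gc$clusters[["dup1"]], gc$clusters[["dup2"]])
  expect_equal(gc$clusters[[colnames(prof)[1]]], gc$clusters[["dup1"]])
})

test_that("enrichment log-ORs behave on hand tables and permutations", {
  # balanced 2x2 [[10,10],[10,10]]
  part <- rep(c("k1", "k2"), each = 20)
  cls <- rep(rep(c("x", "y"), each = 10), 2)
  e <- enrichment_logor(part, cls)
  row <- e[e$cluster == "k1" & e$class == "x", ]
  expect_equal(row$log_or, 0)
  expect_equal(row$p_value, 1)

  # class confined to one cluster: corrected finite log-OR, flagged
  part2 <- rep(c("k1", "k2"), each = 10)
  cls2 <- c(rep("only", 10), rep("other", 10))
  e2 <- enrichment_logor(part2, cls2)
  r2 <- e2[e2$cluster == "k1" & e2$class == "only", ]
  expect_true(r2$corrected)
  expect_true(is.finite(r2$log_or) && r2$log_or > 0)

  # balanced random labels -> log-ORs centred near 0
  set.seed(15)
  lors <- replicate(50, {
    p <- sample(rep(1:2, 30)); k <- sample(rep(c("a", "b"), 30))
    enrichment_logor(p, k)$log_or[1]
  })
  expect_lt(abs(mean(lors)), 0.2)

  # agreement with the exact hypergeometric enumeration (fisher.test)
  set.seed(16)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    p <- sample(c("in", "out"), n, replace = TRUE)
    k <- sample(c("c1", "c2"), n, replace = TRUE)
    if (length(unique(p)) < 2 || length(unique(k)) < 2) next
    e3 <- enrichment_logor(p, k)
    r3 <- e3[e3$cluster == "in" & e3$class == "c1", ]
    ft <- fisher.test(matrix(c(r3$a, r3$c, r3$b, r3$d), 2))
    expect_equal(r3$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("rank DE finds planted shifts and nothing else", {
  set.seed(17)
  n_genes <- 200; shifted <- 1:50
  # inject the normalised layer directly: 50 genes shifted by 1 in group B
  ln <- matrix(rnorm(n_genes * 120), n_genes, 120)
  ln[shifted, 61:120] <- ln[shifted, 61:120] + 1
  scr <- make_mini_screen(matrix(1L, n_genes, 120),
                          variant = rep(c("A", "B"), each = 60))
  SummarizedExperiment::assay(scr, "logcounts") <-
    Matrix::Matrix(ln, sparse = TRUE, dimnames = dimnames(scr))
  de <- rank_de(scr, which(rep(c(TRUE, FALSE), each = 60)),
                which(rep(c(FALSE, TRUE), each = 60)))
  hits <- which(de$significant)
  expect_gte(length(intersect(hits, shifted)), 45)
  expect_lte(length(setdiff(hits, shifted)), 0.05 * (n_genes - 50) + 3)

  # identical groups: nothing significant; all-tied gene gets p = 1
  de0 <- rank_de(scr, 1:30, 1:30)
  expect_false(any(de0$significant))
  expect_true(all(de0$fdr >= de0$p_value - 1e-12))
})

test_that("the full chain is calibrated on a null screen", {
  cfg <- sim_config(n_genes = 400, n_cells_per_variant = 100,
                    n_variants_per_class = c(wt_like = 4, lof_like = 4,
                                             hypomorphic = 4),
                    module_size = 30, n_mito = 10, n_ribo = 20,
                    lof_shift_magnitude = 0, hypo_ortho_magnitude = 0,
                    seed = 18)
  sim <- simulate_screen(cfg)
  pc <- pipeline_config(n_hvg = 300, seed = 18)
  ph <- phenotype_screen(sim$screen, pc, sim$truth$modules$s_genes,
                         sim$truth$modules$g2m_genes)
  # with no planted effects, nearly all variants look WT-like/indeterminate
  expect_gte(mean(ph$calls$call %in% c("WT-like", "indeterminate")), 0.75)
  # and cluster enrichments of the (meaningless) classes stay near zero
  cl <- cluster_graph(SingleCellExperiment::reducedDim(ph$screen, "PCA"),
                      resolution = 0.3, pc)
  cls <- sim$truth$variant_class[
    SummarizedExperiment::colData(ph$screen)$variant]
  enr <- enrichment_logor(cl, cls)
  expect_gt(min(enr$p_value), 1e-4)
  if (length(unique(cl)) > 1) {
    # standardised log-ORs centred on zero under the null (restricted to
    # well-populated tables, where the 0.5-correction bias is negligible)
    ok <- pmin(enr$a, enr$b, enr$c, enr$d) >= 3
    if (sum(ok) >= 5) {
      z <- enr$log_or[ok] / sqrt(1 / enr$a[ok] + 1 / enr$b[ok] +
                                 1 / enr$c[ok] + 1 / enr$d[ok])
      expect_lt(abs(mean(z)), 0.6)
    }
  } else {
    # a featureless screen collapses to one community: every 2x2 is
    # degenerate and carries no evidence
    expect_true(all(enr$p_value == 1))
  }
})
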