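# QC thresholds scaled to a hand-built 12-gene fixture
mini_cfg <- pipeline_config(min_genes = 3, max_genes = 20, max_mito = 0.2,
                            min_gene_cells = 1, min_cells_per_variant = 1,
                            n_hvg = 5, n_pcs = 2, n_neighbors = 2)

test_that("QC drops exactly the cells its rules name", {
  counts <- matrix(5L, 12, 6)
  counts[3:12, 1] <- 0L           # cell 1: only 2 detected genes (< 3)
  counts[1, 2] <- 15L             # cell 2: mito gene = 15/70 > 20%
  mito <- c(TRUE, rep(FALSE, 11))
  scr <- make_mini_screen(counts, variant = rep("V1", 6),
                          n_barcodes = c(1L, 1L, 2L, 1L, 1L, 1L),
                          mito = mito)
  out <- qc_filter(scr, mini_cfg)
  expect_equal(colnames(out), c("c004", "c005", "c006"))

  # all-pass fixture is untouched; QC is idempotent
  clean <- make_mini_screen(matrix(5L, 12, 6), variant = rep("V1", 6))
  expect_equal(dim(qc_filter(clean, mini_cfg)), dim(clean))
  once <- qc_filter(scr, mini_cfg)
  twice <- qc_filter(once, mini_cfg)
  expect_identical(colnames(once), colnames(twice))
  expect_identical(rownames(once), rownames(twice))
})

test_that("variants under the cell floor are removed wholesale", {
  counts <- matrix(5L, 12, 12)
  scr <- make_mini_screen(counts,
                          variant = rep(c("V1", "V2"), c(9, 3)))
  cfg <- pipeline_config(min_genes = 3, max_genes = 50, max_mito = 0.2,
                         min_gene_cells = 1, min_cells_per_variant = 4,
                         n_neighbors = 2)
  out <- qc_filter(scr, cfg)
  expect_setequal(unique(SummarizedExperiment::colData(out)$variant), "V1")
  expect_error(qc_filter(make_mini_screen(matrix(0L, 12, 3),
                                          variant = rep("V1", 3)), cfg),
               "all cells")
})

test_that("log-normalisation follows ln(1 + count * SF / total)", {
  counts <- matrix(0L, 3, 2)
  counts[1, 1] <- 10L; counts[2, 1] <- 990L
  counts[1, 2] <- 20L; counts[2, 2] <- 1980L  # cell 2 = cell 1 at 2x depth
  scr <- make_mini_screen(counts, variant = c("V1", "V1"))
  scr <- lognormalize(scr, pipeline_config())
  ln <- SummarizedExperiment::assay(scr, "logcounts")
  expect_equal(ln[1, 1], log(101), tolerance = 1e-12)
  expect_equal(ln[3, 1], 0)
  # depth invariance
  expect_equal(as.numeric(ln[, 1]), as.numeric(ln[, 2]), tolerance = 1e-12)
})

test_that("HVG ranking prefers variable genes and bans mito/ribo", {
  set.seed(4)
  n_cells <- 80
  counts <- matrix(rpois(40 * n_cells, 5), 40, n_cells)
  counts[7, ] <- 5L                                  # constant gene
  counts[9, ] <- rpois(n_cells, c(1, 60))            # planted bimodal gene
  mito <- rep(FALSE, 40); mito[c(2, 9 + 31)] <- FALSE
  mito[2] <- TRUE; ribo <- rep(FALSE, 40); ribo[3] <- TRUE
  counts[2, ] <- rpois(n_cells, c(1, 80))            # variable but mito
  scr <- make_mini_screen(counts, variant = rep("V1", n_cells),
                          mito = mito, ribo = ribo)
  scr <- lognormalize(scr, pipeline_config())
  hv <- select_hvg(scr, pipeline_config(n_hvg = 10), n_bins = 4)
  expect_length(hv$genes, 10)
  expect_true("G009" %in% hv$genes)
  expect_false(any(c("G002", "G003") %in% hv$genes))
  expect_false("G007" %in% hv$genes)

  # stable under gene reordering
  perm <- sample(nrow(scr))
  hv2 <- select_hvg(scr[perm, ], pipeline_config(n_hvg = 10), n_bins = 4)
  expect_setequal(hv$genes, hv2$genes)
})

test_that("cell-cycle regression removes the planted factor", {
  cfg <- sim_config(n_genes = 300, n_cells_per_variant = 60,
                    n_variants_per_class = c(wt_like = 2, lof_like = 2,
                                             hypomorphic = 2),
                    module_size = 30, n_mito = 10, n_ribo = 20,
                    cc_magnitude = 1, seed = 6)
  sim <- simulate_screen(cfg)
  # min_genes scaled to the 300-gene simulation
  pc <- pipeline_config(n_hvg = 200, n_pcs = 10, min_genes = 50, seed = 6)
  scr <- lognormalize(qc_filter(sim$screen, pc), pc)
  hv <- select_hvg(scr, pc)
  scr <- score_and_regress_cell_cycle(hv$screen, sim$truth$modules$s_genes,
                                      sim$truth$modules$g2m_genes, pc)
  cc <- sim$truth$cc_score[colnames(scr)]
  # the scores track the latent factor before regression...
  expect_gt(cor(SummarizedExperiment::colData(scr)$cc_s_score, cc), 0.5)
  # ...and the scaled layer no longer does
  scaled <- S4Vectors::metadata(scr)$scaled
  cc_genes <- intersect(rownames(scaled), sim$truth$modules$cell_cycle)
  if (length(cc_genes) > 0) {
    cors <- apply(scaled[cc_genes, , drop = FALSE], 1, cor, y = cc)
    expect_lt(max(abs(cors)), 0.12)
  }
  expect_true(all(abs(scaled) <= pc$clip + 1e-9))
})

test_that("identical cells give zero scores and an all-zero scaled layer", {
  counts <- matrix(rep(c(4L, 7L, 0L, 2L, 9L, 1L), 8), 6, 8)
  scr <- make_mini_screen(counts, variant = rep("V1", 8))
  scr <- lognormalize(scr, pipeline_config())
  expect_warning(
    scr <- score_and_regress_cell_cycle(scr, s_genes = "G001",
                                        g2m_genes = "G002",
                                        pipeline_config()),
    "zero-variance")
  cd <- SummarizedExperiment::colData(scr)
  expect_equal(diff(range(cd$cc_s_score)), 0)
  expect_true(all(S4Vectors::metadata(scr)$scaled == 0))
  expect_error(score_and_regress_cell_cycle(scr, character(0), "G002"),
               "non-empty")
})

test_that("PCA finds planted structure with a deterministic convention", {
  set.seed(10)
  # rank-1 data: one direction of variance
  u <- rnorm(40); v <- rnorm(30)
  scaled <- outer(v, u)                      # genes x cells
  scr <- make_mini_screen(matrix(1L, 30, 40), variant = rep("V1", 40))
  S4Vectors::metadata(scr)$scaled <- scaled
  rownames(S4Vectors::metadata(scr)$scaled) <- rownames(scr)
  out <- suppressWarnings(run_pca(scr, pipeline_config(n_pcs = 5)))
  ve <- S4Vectors::metadata(out)$pca_var_explained
  expect_gt(ve[1], 0.999)
  expect_true(all(diff(ve) <= 1e-12))

  # cell reordering permutes embedding rows (up to nothing else)
  perm <- sample(40)
  scr2 <- scr[, perm]
  S4Vectors::metadata(scr2)$scaled <- scaled[, perm]
  out2 <- suppressWarnings(run_pca(scr2, pipeline_config(n_pcs = 5)))
  e1 <- SingleCellExperiment::reducedDim(out, "PCA")
  e2 <- SingleCellExperiment::reducedDim(out2, "PCA")
  expect_equal(e2, e1[perm, ], tolerance = 1e-8)
})

test_that("graph clustering separates planted blobs", {
  set.seed(12)
  emb <- rbind(matrix(rnorm(200, 0), 100, 2),
               matrix(rnorm(200, 8), 100, 2))
  rownames(emb) <- sprintf("c%03d", 1:200)
  cl <- cluster_graph(emb, resolution = 0.3,
                      pipeline_config(n_neighbors = 10))
  expect_equal(length(unique(cl)), 2)
  expect_gte(ari(cl, rep(1:2, each = 100)), 0.99)

  one <- cluster_graph(matrix(rnorm(200), 100, 2), resolution = 0.05,
                       pipeline_config(n_neighbors = 15))
  expect_equal(length(unique(one)), 1)
  expect_error(cluster_graph(emb[1:5, ], 0.3,
                             pipeline_config(n_neighbors = 10)),
               "below the cell count")

  # the induced partition ignores row order
  perm <- sample(200)
  cl2 <- cluster_graph(emb[perm, ], resolution = 0.3,
                       pipeline_config(n_neighbors = 10))
  expect_gte(ari(cl2, rep(1:2, each = 100)[perm]), 0.99)
})
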