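#' Default processing parameters for the single-cell chain
#'
#' @param min_genes,max_genes detected-gene bounds per cell (200 / 5000).
#' @param max_mito maximum mitochondrial read fraction (0.20; cells strictly
#'   above are dropped).
#' @param min_gene_cells a gene must be detected in at least this many cells
#'   (3).
#' @param min_cells_per_variant variants below this cell count in every
#'   condition are dropped (10).
#' @param scale_factor log-normalisation scale factor (1e4).
#' @param n_hvg highly variable genes kept (2000).
#' @param n_pcs principal components (20).
#' @param resolution_cells,resolution_variants modularity resolutions for
#'   cell- and variant-level graph clustering (0.3 / 0.8).
#' @param n_neighbors kNN graph degree (20).
#' @param alpha significance level for phenotype calls (0.05).
#' @param clip z-score clipping bound for the scaled layer (10).
#' @param seed integer seed used by the seeded steps (control gene draw,
#'   randomized SVD, graph clustering).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_genes = 200, max_genes = 5000,
                            max_mito = 0.20, min_gene_cells = 3,
                            min_cells_per_variant = 10, scale_factor = 1e4,
                            n_hvg = 2000, n_pcs = 20,
                            resolution_cells = 0.3,
                            resolution_variants = 0.8, n_neighbors = 20,
                            alpha = 0.05, clip = 10, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0,1)")
  if (any(c(cfg$min_genes, cfg$max_genes, cfg$scale_factor, cfg$n_hvg,
            cfg$n_pcs, cfg$n_neighbors) <= 0)) {
    stop("thresholds must be positive")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Quality-control filtering of cells, genes and variants
#'
#' Applies, to a fixed point, the screen QC rules: drop cells without a
#' single unambiguous construct barcode; drop cells with fewer than
#' `min_genes` or more than `max_genes` detected genes, or with a
#' mitochondrial read fraction above `max_mito`; drop genes detected in
#' fewer than `min_gene_cells` cells; drop all cells of variants whose cell
#' count stays below `min_cells_per_variant` in every condition. Because
#' gene and cell filters interact, the rules are iterated until nothing
#' changes, which also makes the operation idempotent.
#'
#' @param screen `SingleCellExperiment` with integer assay `counts`,
#'   rowData flag `mito`, and colData `variant` (and optionally
#'   `n_barcodes`, `condition`).
#' @param cfg a [pipeline_config()].
#' @return the filtered `SingleCellExperiment`.
#' @export
qc_filter <- function(screen, cfg = pipeline_config()) {
  cd <- SummarizedExperiment::colData(screen)
  if ("n_barcodes" %in% names(cd)) {
    screen <- screen[, cd$n_barcodes == 1L]
  } else {
    screen <- screen[, !(cd$variant %in% c("none", "multi"))]
  }
  repeat {
    counts <- SummarizedExperiment::assay(screen, "counts")
    rd <- SummarizedExperiment::rowData(screen)
    cd <- SummarizedExperiment::colData(screen)

    detected <- Matrix::colSums(counts > 0)
    total <- Matrix::colSums(counts)
    mito_frac <- if (any(rd$mito)) {
      Matrix::colSums(counts[rd$mito, , drop = FALSE]) / pmax(total, 1)
    } else rep(0, ncol(screen))
    keep_cell <- detected >= cfg$min_genes & detected <= cfg$max_genes &
      mito_frac <= cfg$max_mito

    keep_gene <- Matrix::rowSums(counts[, keep_cell, drop = FALSE] > 0) >=
      cfg$min_gene_cells

    # variant-level floor: enough cells in at least one condition
    cd_k <- cd[keep_cell, , drop = FALSE]
    cond <- if ("condition" %in% names(cd_k)) cd_k$condition else
      rep("all", nrow(cd_k))
    tab <- table(cd_k$variant, cond)
    bad_var <- if (nrow(tab) == 0) character(0) else
      rownames(tab)[apply(tab, 1, max) < cfg$min_cells_per_variant]
    keep_cell[keep_cell] <- !(cd_k$variant %in% bad_var)

    if (all(keep_cell) && all(keep_gene)) break
    screen <- screen[keep_gene, keep_cell]
    if (ncol(screen) == 0) stop("all cells filtered")
  }
  screen
}

#' Depth-normalised log expression
#'
#' `logcounts = ln(1 + count * scale_factor / cell_total)`: counts scaled to
#' a common depth then natural-log transformed. Invariant to per-cell
#' sequencing depth.
#'
#' @param screen QC'd `SingleCellExperiment`.
#' @param cfg a [pipeline_config()] (provides `scale_factor`).
#' @return `screen` with assay `logcounts` added.
#' @export
lognormalize <- function(screen, cfg = pipeline_config()) {
  counts <- SummarizedExperiment::assay(screen, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("cell with zero total counts")
  ln <- counts %*% Matrix::Diagonal(x = cfg$scale_factor / total)
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(counts)
  SummarizedExperiment::assay(screen, "logcounts") <- ln
  screen
}

#' Highly variable genes by binned dispersion
#'
#' Genes are ranked by a standardized variance: genes are split into
#' `n_bins` equal-frequency bins of mean log-expression and the log
#' variance is z-scored within each bin, which removes the mean-variance
#' trend without any curve fitting. Mitochondrial and ribosomal genes are
#' excluded before ranking; constant genes rank last. The top
#' `min(n_hvg, eligible)` gene ids are returned and flagged in
#' `rowData(screen)$hvg` when the screen is updated by reference semantics
#' (the function returns the updated object).
#'
#' @param screen `SingleCellExperiment` with assay `logcounts`.
#' @param cfg a [pipeline_config()].
#' @param n_bins mean-expression bins (default 20).
#' @return list with `screen` (rowData gains logical `hvg`) and `genes`
#'   (character vector of selected gene ids, ranked).
#' @export
select_hvg <- function(screen, cfg = pipeline_config(), n_bins = 20) {
  ln <- SummarizedExperiment::assay(screen, "logcounts")
  rd <- SummarizedExperiment::rowData(screen)
  eligible <- !(rd$mito %in% TRUE) & !(rd$ribo %in% TRUE)

  mu <- Matrix::rowMeans(ln)
  ex2 <- Matrix::rowMeans(ln^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(ln) / max(ncol(ln) - 1, 1)

  z <- rep(-Inf, nrow(ln))
  idx <- which(eligible & v > 0)
  if (length(idx)) {
    nb <- max(1, min(n_bins, floor(length(idx) / 2)))
    br <- unique(stats::quantile(mu[idx], probs = seq(0, 1, length.out =
                                                        nb + 1)))
    bin <- cut(mu[idx], breaks = br, include.lowest = TRUE)
    lv <- log(v[idx])
    for (b in levels(bin)) {
      sel <- bin == b
      s <- stats::sd(lv[sel])
      z[idx[sel]] <- if (is.na(s) || s == 0) 0 else
        (lv[sel] - mean(lv[sel])) / s
    }
  }
  z[!eligible] <- -Inf
  # deterministic tie-break by gene id keeps the choice order-invariant
  ord <- order(-z, rownames(ln))
  n_take <- min(cfg$n_hvg, sum(eligible))
  genes <- rownames(ln)[ord[seq_len(n_take)]]
  rd$hvg <- rownames(ln) %in% genes
  SummarizedExperiment::rowData(screen) <- rd
  list(screen = screen, genes = genes)
}

#' Cell-cycle scoring, regression and per-gene scaling
#'
#' Per-cell S and G2M scores are the mean log-normalised expression of the
#' marker genes minus the mean of a size-matched random control gene set
#' (drawn seeded from the non-marker genes). Each HVG's expression is then
#' residualised by ordinary least squares on the two scores (covariates
#' with zero variance are dropped with a warning) and z-scored per gene,
#' clipping at `+/- clip`.
#'
#' @param screen `SingleCellExperiment` with `logcounts` and (ideally)
#'   rowData `hvg` from [select_hvg()]; without the flag all genes are
#'   scaled.
#' @param s_genes,g2m_genes character vectors of marker gene ids.
#' @param cfg a [pipeline_config()] (provides `seed` and `clip`).
#' @return `screen` with colData `cc_s_score`, `cc_g2m_score` and a dense
#'   scaled matrix (genes x cells, HVG rows) stored in
#'   `metadata(screen)$scaled`.
#' @export
score_and_regress_cell_cycle <- function(screen, s_genes, g2m_genes,
                                         cfg = pipeline_config()) {
  if (length(s_genes) == 0 || length(g2m_genes) == 0) {
    stop("marker lists must be non-empty")
  }
  ln <- SummarizedExperiment::assay(screen, "logcounts")
  s_genes <- intersect(s_genes, rownames(ln))
  g2m_genes <- intersect(g2m_genes, rownames(ln))
  if (length(s_genes) == 0 || length(g2m_genes) == 0) {
    stop("no marker genes found in the screen")
  }
  local_rng(cfg$seed)
  pool <- setdiff(rownames(ln), c(s_genes, g2m_genes))
  ctrl_s <- sample(pool, min(length(s_genes), length(pool)))
  ctrl_g2m <- sample(pool, min(length(g2m_genes), length(pool)))

  score <- function(markers, ctrl) {
    Matrix::colMeans(ln[markers, , drop = FALSE]) -
      Matrix::colMeans(ln[ctrl, , drop = FALSE])
  }
  s_score <- score(s_genes, ctrl_s)
  g2m_score <- score(g2m_genes, ctrl_g2m)

  rd <- SummarizedExperiment::rowData(screen)
  rows <- if ("hvg" %in% names(rd) && any(rd$hvg)) which(rd$hvg) else
    seq_len(nrow(ln))
  y <- as.matrix(ln[rows, , drop = FALSE])   # genes x cells, dense

  covs <- list(s = s_score, g2m = g2m_score)
  keep <- vapply(covs, function(v) stats::sd(v) > 0, logical(1))
  if (!all(keep)) {
    warning("zero-variance cell-cycle covariate dropped: ",
            paste(names(covs)[!keep], collapse = ", "))
  }
  x <- cbind(intercept = rep(1, ncol(ln)))
  if (any(keep)) x <- cbind(x, do.call(cbind, covs[keep]))
  # OLS residuals for all genes at once: Y' - X (X'X)^-1 X' Y'
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, t(y))
  resid <- t(y) - x %*% beta                 # cells x genes

  sds <- apply(resid, 2, stats::sd)
  sds[sds == 0] <- 1
  scaled <- sweep(sweep(resid, 2, colMeans(resid), "-"), 2, sds, "/")
  scaled[scaled > cfg$clip] <- cfg$clip
  scaled[scaled < -cfg$clip] <- -cfg$clip
  scaled <- t(scaled)                        # genes x cells

  cd <- SummarizedExperiment::colData(screen)
  cd$cc_s_score <- s_score
  cd$cc_g2m_score <- g2m_score
  SummarizedExperiment::colData(screen) <- cd
  S4Vectors::metadata(screen)$scaled <- scaled
  screen
}

#' PCA embedding of the scaled HVG matrix
#'
#' Truncated SVD (irlba, seeded; exact SVD for small problems) of the
#' cell x gene scaled matrix. Components are ordered by decreasing
#' explained variance and follow a deterministic sign convention: the
#' largest-magnitude gene loading of each component is positive.
#'
#' @param screen `SingleCellExperiment` carrying `metadata(.)$scaled` from
#'   [score_and_regress_cell_cycle()].
#' @param cfg a [pipeline_config()] (`n_pcs`, `seed`).
#' @return `screen` with `reducedDim(., "PCA")` (cells x n_pcs) and
#'   `metadata(.)$pca_var_explained`.
#' @export
run_pca <- function(screen, cfg = pipeline_config()) {
  scaled <- S4Vectors::metadata(screen)$scaled
  if (is.null(scaled)) stop("run score_and_regress_cell_cycle() first")
  x <- t(scaled)                             # cells x genes
  x <- sweep(x, 2, colMeans(x), "-")
  n_pcs <- cfg$n_pcs
  if (n_pcs >= min(dim(x))) {
    n_pcs <- min(dim(x)) - 1L
    warning("fewer cells/genes than requested components; using ", n_pcs)
  }
  local_rng(cfg$seed)
  sv <- if (min(dim(x)) <= max(3 * n_pcs, 50)) {
    s <- svd(x, nu = n_pcs, nv = n_pcs)
    list(u = s$u, d = s$d[seq_len(n_pcs)], v = s$v)
  } else {
    irlba::irlba(x, nv = n_pcs)
  }
  # sign convention: dominant loading positive
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  emb <- sv$u %*% diag(sv$d, n_pcs)
  rownames(emb) <- colnames(screen)
  colnames(emb) <- sprintf("PC%d", seq_len(n_pcs))
  SingleCellExperiment::reducedDim(screen, "PCA") <- emb
  total_var <- sum(apply(x, 2, stats::var))
  S4Vectors::metadata(screen)$pca_var_explained <-
    sv$d^2 / (nrow(x) - 1) / total_var
  screen
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbour graph in the embedding (Euclidean, exact
#' search) and partitions it by modularity optimisation (Leiden) at the
#' given resolution. Labels are renumbered 1..k by decreasing cluster size.
#'
#' @param embedding numeric matrix, observations x dimensions.
#' @param resolution modularity resolution parameter.
#' @param cfg a [pipeline_config()] (`n_neighbors`, `seed`).
#' @return integer vector of cluster labels (named by embedding rownames).
#' @export
cluster_graph <- function(embedding, resolution, cfg = pipeline_config()) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (cfg$n_neighbors >= n) stop("n_neighbors must be below the cell count")
  nn <- RANN::nn2(embedding, k = cfg$n_neighbors + 1)$nn.idx[, -1,
                                                             drop = FALSE]
  edges <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  local_rng(cfg$seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(memb)])
  names(out) <- rownames(embedding)
  out
}
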