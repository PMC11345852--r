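#' Simulate a variant-barcoded single-cell screen
#'
#' Draws a gene x cell UMI count matrix from a negative binomial model.
#' Per-gene baseline means are log-normal; effects are applied on the
#' log-mean scale so counts stay integer and the dispersion keeps its
#' meaning. Cells of LoF-like variants and the LoF control receive the full
#' LoF-module shift; hypomorphic cells receive `hypo_partial_fraction` of it
#' plus the orthogonal-module shift; WT-like cells and the WT control
#' receive no shift. A per-cell standard-normal latent cell-cycle score
#' scales the designated cell-cycle gene set, and a log-normal per-cell
#' depth factor scales all genes. Each cell carries 0, 1 or 2 construct
#' barcodes according to the configured fractions; only single-barcode cells
#' get a variant call (the truth record keeps the real identity of every
#' cell). Replicate and dox/nodox condition flags are emitted; with
#' `nodox_shrinkage < 1` the planted effects are attenuated in the nodox
#' condition.
#'
#' @param config a [sim_config()].
#' @return list with `screen` (a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with assay `counts`, rowData flags `mito`/`ribo`, and colData
#'   `variant`, `n_barcodes`, `replicate`, `condition`, `true_variant`) and
#'   `truth` (list: `variant_class`, `growth_rate`, `modules` with the
#'   planted gene sets incl. `s_genes`/`g2m_genes` marker halves of the
#'   cell-cycle set, and `cell_variant`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_rng(cfg$seed)

  nv <- cfg$n_variants_per_class
  classes <- rep(c("wt_like", "lof_like", "hypomorphic"),
                 c(nv[["wt_like"]], nv[["lof_like"]], nv[["hypomorphic"]]))
  variants <- sprintf("V%03d", seq_along(classes))
  all_ids <- c("WT", "LoF", variants)
  all_classes <- c("control_WT", "control_LoF", classes)
  names(all_classes) <- all_ids

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  # disjoint gene blocks: mito | ribo | lof module | ortho module | cc set
  idx <- seq_len(cfg$n_genes)
  mito_idx <- idx[seq_len(cfg$n_mito)]
  ribo_idx <- idx[cfg$n_mito + seq_len(cfg$n_ribo)]
  off <- cfg$n_mito + cfg$n_ribo
  lof_idx <- idx[off + seq_len(cfg$module_size)]
  ortho_idx <- idx[off + cfg$module_size + seq_len(cfg$module_size)]
  cc_idx <- idx[off + 2 * cfg$module_size + seq_len(cfg$module_size)]
  symbols <- genes
  symbols[mito_idx] <- sprintf("MT-%04d", mito_idx)
  symbols[ribo_idx] <- sprintf("RPL%04d", ribo_idx)

  meanlog <- log(cfg$nb_mean) - cfg$nb_mean_sdlog^2 / 2
  base_log_mu <- stats::rnorm(cfg$n_genes, meanlog, cfg$nb_mean_sdlog)

  n_cells <- cfg$n_cells_per_variant * length(all_ids)
  true_variant <- rep(all_ids, each = cfg$n_cells_per_variant)
  cell_class <- all_classes[true_variant]
  cell_id <- sprintf("cell%05d", seq_len(n_cells))

  condition <- ifelse(stats::runif(n_cells) < cfg$frac_nodox, "nodox", "dox")
  replicate <- sample(rep_len(1:2, n_cells))
  u <- stats::runif(n_cells)
  n_barcodes <- ifelse(u < cfg$frac_no_barcode, 0L,
                ifelse(u < cfg$frac_no_barcode + cfg$frac_multi_barcode,
                       2L, 1L))
  variant_call <- ifelse(n_barcodes == 1L, true_variant,
                         ifelse(n_barcodes == 0L, "none", "multi"))

  shrink <- ifelse(condition == "nodox", cfg$nodox_shrinkage, 1)
  lof_amt <- numeric(n_cells)
  lof_amt[cell_class %in% c("lof_like", "control_LoF")] <-
    cfg$lof_shift_magnitude
  lof_amt[cell_class == "hypomorphic"] <-
    cfg$lof_shift_magnitude * cfg$hypo_partial_fraction
  ortho_amt <- numeric(n_cells)
  ortho_amt[cell_class == "hypomorphic"] <- cfg$hypo_ortho_magnitude
  lof_amt <- lof_amt * shrink
  ortho_amt <- ortho_amt * shrink

  cc_score <- stats::rnorm(n_cells)
  size_fac <- stats::rnorm(n_cells, 0, cfg$cell_size_sdlog)

  # log-mean matrix assembled gene-block-wise to limit copies
  log_mu <- matrix(base_log_mu, cfg$n_genes, n_cells)
  log_mu <- sweep(log_mu, 2, size_fac, "+")
  log_mu[lof_idx, ] <- sweep(log_mu[lof_idx, , drop = FALSE], 2, lof_amt,
                             "+")
  log_mu[ortho_idx, ] <- sweep(log_mu[ortho_idx, , drop = FALSE], 2,
                               ortho_amt, "+")
  log_mu[cc_idx, ] <- sweep(log_mu[cc_idx, , drop = FALSE], 2,
                            cfg$cc_magnitude * cc_score, "+")

  counts <- matrix(stats::rnbinom(length(log_mu), mu = exp(log_mu),
                                  size = cfg$nb_dispersion),
                   cfg$n_genes, n_cells)
  rm(log_mu)
  dimnames(counts) <- list(genes, cell_id)
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  screen <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = genes, symbol = symbols,
                                   mito = idx %in% mito_idx,
                                   ribo = idx %in% ribo_idx,
                                   row.names = genes),
    colData = S4Vectors::DataFrame(cell_id = cell_id,
                                   variant = variant_call,
                                   n_barcodes = n_barcodes,
                                   replicate = replicate,
                                   condition = condition,
                                   true_variant = true_variant,
                                   row.names = cell_id))

  gr_class <- cfg$growth_rates[c("wt_like", "lof_like", "hypomorphic")]
  base_gr <- c(control_WT = unname(gr_class["wt_like"]),
               control_LoF = unname(gr_class["lof_like"]),
               wt_like = unname(gr_class["wt_like"]),
               lof_like = unname(gr_class["lof_like"]),
               hypomorphic = unname(gr_class["hypomorphic"]))
  growth_rate <- base_gr[all_classes] +
    stats::rnorm(length(all_ids), 0, cfg$growth_rate_sd)
  names(growth_rate) <- all_ids

  truth <- list(
    variant_class = all_classes,
    growth_rate = growth_rate,
    modules = list(lof = genes[lof_idx], hypo_ortho = genes[ortho_idx],
                   cell_cycle = genes[cc_idx],
                   s_genes = genes[cc_idx[seq_len(cfg$module_size %/% 2)]],
                   g2m_genes = genes[cc_idx[(cfg$module_size %/% 2 + 1):
                                            cfg$module_size]],
                   mito = genes[mito_idx], ribo = genes[ribo_idx]),
    cell_variant = stats::setNames(true_variant, cell_id),
    cc_score = stats::setNames(cc_score, cell_id))

  list(screen = screen, truth = truth)
}
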