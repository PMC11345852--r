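#' Phenotype every variant of a screen end to end
#'
#' Runs the whole single-cell chain -- QC, log-normalisation, HVG
#' selection, cell-cycle scoring/regression, PCA -- then scores each
#' variant against the WT and LoF control cells with Hotelling's
#' T-squared on the top principal components and applies the significance
#' rule of [assign_phenotype()].
#'
#' @param screen raw `SingleCellExperiment` (as from [simulate_screen()]).
#' @param cfg a [pipeline_config()].
#' @param s_genes,g2m_genes cell-cycle marker gene ids.
#' @param wt_id,lof_id control variant labels (defaults `"WT"`, `"LoF"`).
#' @return object of class `variant_phenotypes`: list with `screen` (the
#'   processed object, embedding in `reducedDim(., "PCA")`), `t2` (long
#'   data.frame of all control comparisons), `calls` (data.frame `variant`,
#'   `p_wt`, `p_lof`, `p_wt_adj`, `p_lof_adj`, `call`), `hvg`, and `cfg`.
#' @export
phenotype_screen <- function(screen, cfg = pipeline_config(), s_genes,
                             g2m_genes, wt_id = "WT", lof_id = "LoF") {
  screen <- qc_filter(screen, cfg)
  screen <- lognormalize(screen, cfg)
  hv <- select_hvg(screen, cfg)
  screen <- score_and_regress_cell_cycle(hv$screen, s_genes, g2m_genes, cfg)
  screen <- run_pca(screen, cfg)

  emb <- SingleCellExperiment::reducedDim(screen, "PCA")
  variants <- SummarizedExperiment::colData(screen)$variant
  t2 <- score_all_variants(emb, variants, wt_id = wt_id, lof_id = lof_id)

  wide <- merge(t2[t2$control == "WT", c("variant", "t2", "p_value")],
                t2[t2$control == "LoF", c("variant", "t2", "p_value")],
                by = "variant", suffixes = c("_wt", "_lof"))
  calls <- data.frame(variant = wide$variant,
                      t2_wt = wide$t2_wt, t2_lof = wide$t2_lof,
                      p_wt = wide$p_value_wt, p_lof = wide$p_value_lof,
                      p_wt_adj = bh_fdr(wide$p_value_wt),
                      p_lof_adj = bh_fdr(wide$p_value_lof),
                      call = assign_phenotype(wide$p_value_wt,
                                              wide$p_value_lof, cfg$alpha),
                      stringsAsFactors = FALSE)
  out <- list(screen = screen, t2 = t2, calls = calls, hvg = hv$genes,
              cfg = cfg)
  class(out) <- "variant_phenotypes"
  out
}

#' @export
print.variant_phenotypes <- function(x, ...) {
  cat(sprintf("variant_phenotypes: %d variants, %d cells, alpha = %g\n",
              nrow(x$calls), ncol(x$screen), x$cfg$alpha))
  print(table(x$calls$call))
  invisible(x)
}

#' @export
summary.variant_phenotypes <- function(object, ...) {
  cat("Phenotype calls (T2 vs WT and LoF controls):\n")
  print(table(object$calls$call))
  cat("\nT2 vs WT, five-number summary:\n")
  print(summary(object$calls$t2_wt))
  cat("\nStrongest deviations from WT:\n")
  print(utils::head(object$calls[order(-object$calls$t2_wt),
                                 c("variant", "t2_wt", "p_wt", "call")]))
  invisible(object)
}
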