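#' Configuration for the synthetic variant screen
#'
#' Collects every knob of the screen simulator with defaults that emulate a
#' scaled-down variant-overexpression Perturb-seq experiment: negative
#' binomial UMI counts with log-normally distributed per-gene means, three
#' planted phenotype classes (no shift; a loss-of-function gene-module
#' shift; a partial LoF shift plus an orthogonal module shift), a cell-cycle
#' nuisance factor, imperfect barcode assignment, and growth-rate-driven
#' barcode abundance across timepoints.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_cells_per_variant cells simulated per library element
#'   (default 150).
#' @param n_variants_per_class named counts for the planted classes
#'   `wt_like`, `lof_like`, `hypomorphic` (default 20 each; the WT and LoF
#'   control constructs are always added on top).
#' @param nb_mean target mean count per gene (default 2); per-gene baseline
#'   means are drawn log-normally around it with `nb_mean_sdlog` spread.
#' @param nb_mean_sdlog log-sd of the per-gene baseline means (default 1.2).
#' @param nb_dispersion negative binomial size parameter (default 2).
#' @param module_size genes per planted module (LoF module, orthogonal
#'   hypomorphic module, cell-cycle set; disjoint; default 50).
#' @param lof_shift_magnitude log-scale mean shift on the LoF module for
#'   LoF-like variants and the LoF control (default 1).
#' @param hypo_partial_fraction fraction of the LoF shift applied to
#'   hypomorphic variants (default 0.5).
#' @param hypo_ortho_magnitude log-scale shift on the orthogonal module for
#'   hypomorphic variants (default 1).
#' @param cc_magnitude amplitude of the per-cell latent cell-cycle factor on
#'   the cell-cycle gene set (default 0.5).
#' @param cell_size_sdlog log-sd of the per-cell depth factor (default 0.3).
#' @param frac_multi_barcode,frac_no_barcode probabilities of a cell
#'   carrying two or zero detected construct barcodes (default 0.05 each).
#' @param growth_rates named per-class relative growth rates per day
#'   (defaults `wt_like = 0`, `hypomorphic = 0.05`, `lof_like = 0.10`; the
#'   WT control grows like `wt_like`, the LoF control like `lof_like`).
#' @param growth_rate_sd per-variant jitter of the class growth rate
#'   (default 0.02).
#' @param timepoints days sampled in the fitness timecourse (must include
#'   the day-2 baseline; default `c(2, 7, 14)`).
#' @param reads_per_sample sequencing depth of each timecourse sample
#'   (default 2.5e5).
#' @param n_replicates biological replicates (default 2).
#' @param frac_nodox fraction of cells in the no-knockdown condition
#'   (default 0.5).
#' @param nodox_shrinkage multiplicative attenuation of all planted effects
#'   in the nodox condition (default 1 = condition-independent effects).
#' @param n_mito,n_ribo genes flagged mitochondrial / ribosomal (defaults
#'   20 / 80; kept outside the planted modules).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_variant = 150,
                       n_variants_per_class = c(wt_like = 20, lof_like = 20,
                                                hypomorphic = 20),
                       nb_mean = 2,
                       nb_mean_sdlog = 1.2,
                       nb_dispersion = 2,
                       module_size = 50,
                       lof_shift_magnitude = 1,
                       hypo_partial_fraction = 0.5,
                       hypo_ortho_magnitude = 1,
                       cc_magnitude = 0.5,
                       cell_size_sdlog = 0.3,
                       frac_multi_barcode = 0.05,
                       frac_no_barcode = 0.05,
                       growth_rates = c(wt_like = 0, lof_like = 0.10,
                                        hypomorphic = 0.05),
                       growth_rate_sd = 0.02,
                       timepoints = c(2, 7, 14),
                       reads_per_sample = 2.5e5,
                       n_replicates = 2,
                       frac_nodox = 0.5,
                       nodox_shrinkage = 1,
                       n_mito = 20,
                       n_ribo = 80,
                       seed = 1) {
  cfg <- as.list(environment())
  cls <- c("wt_like", "lof_like", "hypomorphic")
  if (!all(cls %in% names(cfg$n_variants_per_class))) {
    stop("n_variants_per_class needs entries wt_like, lof_like, hypomorphic")
  }
  if (!all(cls %in% names(cfg$growth_rates))) {
    stop("growth_rates needs entries wt_like, lof_like, hypomorphic")
  }
  fracs <- c(cfg$hypo_partial_fraction, cfg$frac_multi_barcode,
             cfg$frac_no_barcode, cfg$frac_nodox)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_multi_barcode + cfg$frac_no_barcode > 1) {
    stop("barcode fractions must sum to at most 1")
  }
  if (3 * cfg$module_size + cfg$n_mito + cfg$n_ribo > cfg$n_genes) {
    stop("module sizes exceed n_genes")
  }
  if (!2 %in% cfg$timepoints) stop("timepoints must include day 2")
  if (cfg$nb_dispersion <= 0 || cfg$nb_mean <= 0) {
    stop("nb_mean and nb_dispersion must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  nv <- sum(x$n_variants_per_class)
  cat(sprintf(paste0("sim_config: %d genes, %d perturbation variants ",
                     "(+WT, +LoF), %d cells/variant, seed %d\n"),
              x$n_genes, nv, x$n_cells_per_variant, x$seed))
  cat(sprintf("  shifts: LoF %.2f, hypo %.2f x LoF + %.2f ortho; cc %.2f\n",
              x$lof_shift_magnitude, x$hypo_partial_fraction,
              x$hypo_ortho_magnitude, x$cc_magnitude))
  invisible(x)
}
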