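#' Mean expression profile of each variant
#'
#' Row `v` is the per-gene mean of the log-normalised expression over the
#' cells assigned to variant `v`, restricted to the given gene set.
#'
#' @param screen `SingleCellExperiment` with assay `logcounts`.
#' @param labels per-cell variant labels (defaults to `colData(.)$variant`).
#' @param genes gene ids to keep (defaults to the HVG flag, else all).
#' @return matrix, variants (sorted by id) x genes.
#' @export
variant_mean_profiles <- function(screen, labels = NULL, genes = NULL) {
  ln <- SummarizedExperiment::assay(screen, "logcounts")
  if (is.null(labels)) labels <- SummarizedExperiment::colData(screen)$variant
  labels <- as.character(labels)
  if (length(labels) != ncol(ln)) stop("one label per cell required")
  if (is.null(genes)) {
    rd <- SummarizedExperiment::rowData(screen)
    genes <- if ("hvg" %in% names(rd) && any(rd$hvg))
      rownames(ln)[rd$hvg] else rownames(ln)
  }
  ln <- ln[genes, , drop = FALSE]
  ids <- sort(unique(labels))
  prof <- t(vapply(ids, function(v) {
    Matrix::rowMeans(ln[, labels == v, drop = FALSE])
  }, numeric(nrow(ln))))
  rownames(prof) <- ids
  prof
}

#' Hierarchical clustering of variants on profile correlation
#'
#' Distance `1 - Pearson correlation` between variant mean-expression
#' profiles, agglomerated with the chosen linkage. Dendrogram leaves are
#' reordered (within the flips the tree allows) towards increasing
#' T-squared-vs-WT score, and the tree is cut into `k` groups.
#'
#' @param profiles variants x genes matrix from [variant_mean_profiles()].
#' @param t2_wt_scores named numeric vector of T2-vs-WT scores (names must
#'   cover the profile rownames; variants missing a score get the median).
#' @param k number of groups from the cut (default 3).
#' @param linkage hclust method (default "average").
#' @return list with `hclust`, `dendrogram` (leaf-reordered), `order`
#'   (variant ids in leaf order) and `clusters` (named integer vector).
#' @export
hcluster_variants <- function(profiles, t2_wt_scores, k = 3,
                              linkage = "average") {
  if (nrow(profiles) < 2) stop("need at least 2 variants")
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance profile for variant(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = linkage)
  w <- t2_wt_scores[hc$labels]
  w[is.na(w)] <- stats::median(t2_wt_scores, na.rm = TRUE)
  dend <- stats::reorder(stats::as.dendrogram(hc), wts = w, agglo.FUN = mean)
  list(hclust = hc, dendrogram = dend, order = labels(dend),
       clusters = stats::cutree(hc, k = k))
}

#' Hierarchical clustering of genes on Manhattan distance
#'
#' Genes (columns of the variant profile matrix) are clustered by Manhattan
#' distance between their across-variant expression vectors.
#'
#' @param profiles variants x genes matrix.
#' @param k number of gene groups (default 10).
#' @param linkage hclust method (default "average").
#' @return list with `hclust` and `clusters` (named integer vector).
#' @export
hcluster_genes <- function(profiles, k = 10, linkage = "average") {
  d <- stats::dist(t(profiles), method = "manhattan")
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, clusters = stats::cutree(hc, k = min(k, ncol(profiles))))
}

#' Cluster-class enrichment by exact 2x2 tests
#'
#' For every (cluster, class) pair, tabulates membership against class and
#' reports the log of the sample odds ratio (with the Haldane-Anscombe 0.5
#' correction when a zero cell occurs, flagged) and the exact two-sided
#' p-value of [fisher_cmle()]. Positive log odds ratios indicate
#' enrichment of the class in the cluster, negative depletion.
#'
#' @param partition_labels vector of cluster labels.
#' @param class_labels aligned vector of class labels.
#' @return data.frame: `cluster`, `class`, `a`, `b`, `c`, `d`, `log_or`,
#'   `corrected` (Haldane-Anscombe applied), `p_value`, `direction`.
#' @export
enrichment_logor <- function(partition_labels, class_labels) {
  if (length(partition_labels) != length(class_labels)) {
    stop("label vectors must be aligned")
  }
  cl <- as.character(partition_labels)
  cs <- as.character(class_labels)
  rows <- list()
  for (ci in sort(unique(cl))) {
    for (cj in sort(unique(cs))) {
      a <- sum(cl == ci & cs == cj)
      b <- sum(cl == ci & cs != cj)
      c_ <- sum(cl != ci & cs == cj)
      d <- sum(cl != ci & cs != cj)
      zero <- any(c(a, b, c_, d) == 0)
      lor <- if (zero) {
        log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5)))
      } else {
        log(a * d / (b * c_))
      }
      p <- fisher_cmle(c(a, b, c_, d))$p_value
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = ci, class = cj, a = a, b = b, c = c_, d = d,
                   log_or = lor, corrected = zero, p_value = p,
                   direction = ifelse(lor > 0, "enriched", "depleted"),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-based differential expression between two cell groups
#'
#' Per-gene two-sided Mann-Whitney (Wilcoxon rank-sum) test on the
#' log-normalised layer, Benjamini-Hochberg adjusted. Genes tied across all
#' cells get p = 1.
#'
#' @param screen `SingleCellExperiment` with assay `logcounts`.
#' @param cells_a,cells_b column indices or names of the two groups.
#' @param fdr significance threshold on the adjusted p (default 0.05).
#' @return data.frame `gene`, `delta` (mean A - mean B), `p_value`, `fdr`,
#'   `significant`.
#' @export
rank_de <- function(screen, cells_a, cells_b, fdr = 0.05) {
  ln <- SummarizedExperiment::assay(screen, "logcounts")
  a <- as.matrix(ln[, cells_a, drop = FALSE])
  b <- as.matrix(ln[, cells_b, drop = FALSE])
  if (ncol(a) == 0 || ncol(b) == 0) stop("both groups must be non-empty")
  p <- vapply(seq_len(nrow(ln)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (length(unique(c(xa, xb))) == 1L) return(1)
    suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
  }, numeric(1))
  q <- bh_fdr(p)
  data.frame(gene = rownames(ln), delta = rowMeans(a) - rowMeans(b),
             p_value = p, fdr = q, significant = q < fdr,
             stringsAsFactors = FALSE)
}
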