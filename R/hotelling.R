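#' Hotelling two-sample T-squared test
#'
#' The multivariate generalisation of the pooled two-sample t-test.
#' With sample mean difference `d` and pooled covariance `S` (denominator
#' `n1 + n2 - 2`),
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2} d' S^{-1} d,}
#' calibrated through
#' \deqn{F = T^2 \frac{n_1 + n_2 - p - 1}{p (n_1 + n_2 - 2)}}
#' which follows an F distribution with `(p, n1 + n2 - p - 1)` degrees of
#' freedom under equal means and a common Gaussian covariance.
#'
#' A numerically singular pooled covariance is ridged by adding
#' `1e-6 * trace(S)/p` to the diagonal (with a warning); tests on such data
#' are still reported but flagged.
#'
#' @param x1,x2 numeric matrices, observations in rows, the same number of
#'   columns. Vectors are treated as single-column matrices.
#' @return object of class `t2_result`: list with `t2`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `n1`, `n2`, `p_dim`, `valid` (FALSE when
#'   `n1 + n2 <= p + 1` so the F calibration is undefined), and `ridged`.
#' @examples
#' hotelling_t2(matrix(0:2), matrix(3:5))  # univariate: T2 = 13.5
#' @export
hotelling_t2 <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("samples must share dimension")
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  res <- list(n1 = n1, n2 = n2, p_dim = p, df1 = p, df2 = n1 + n2 - p - 1,
              ridged = FALSE)
  class(res) <- "t2_result"
  if (n1 < 2 || n2 < 2 || n1 + n2 <= p + 1) {
    res$valid <- FALSE
    res$t2 <- res$f_stat <- res$p_value <- NA_real_
    return(res)
  }
  res$valid <- TRUE
  d <- colMeans(x1) - colMeans(x2)
  s1 <- stats::cov(x1); s2 <- stats::cov(x2)
  sp <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
  ch <- tryCatch(chol(sp), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    eps <- 1e-6 * sum(diag(sp)) / p
    if (eps <= 0) eps <- 1e-12
    sp <- sp + diag(eps, p)
    ch <- chol(sp)
    res$ridged <- TRUE
    warning("singular pooled covariance; ridge added to the diagonal")
  }
  z <- backsolve(ch, d, transpose = TRUE)
  res$t2 <- (n1 * n2 / (n1 + n2)) * sum(z^2)
  res$f_stat <- res$t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  res$p_value <- stats::pf(res$f_stat, res$df1, res$df2, lower.tail = FALSE)
  res
}

#' @export
print.t2_result <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("Hotelling T2: invalid (n1=%d, n2=%d, p=%d)\n",
                x$n1, x$n2, x$p_dim))
    return(invisible(x))
  }
  cat(sprintf("Hotelling T2 = %.4g, F(%d, %d) = %.4g, p = %.3g%s\n",
              x$t2, x$df1, x$df2, x$f_stat, x$p_value,
              if (isTRUE(x$ridged)) " [ridged]" else ""))
  invisible(x)
}

#' Score every variant against the WT and LoF control cells
#'
#' Runs [hotelling_t2()] twice per non-control variant on the rows of a cell
#' embedding (typically the top 20 PCs): once against the wild-type control
#' cells and once against the loss-of-function control cells. Higher scores
#' mean larger deviation from that control's transcriptional state.
#'
#' @param embedding numeric matrix, cells x dimensions.
#' @param variants character/factor vector of per-cell variant labels, one
#'   per embedding row.
#' @param wt_id,lof_id labels of the control variants.
#' @return data.frame with one row per (variant, control) pair: `variant`,
#'   `control` ("WT"/"LoF"), `n1`, `n2`, `t2`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `valid`.
#' @export
score_all_variants <- function(embedding, variants, wt_id = "WT",
                               lof_id = "LoF") {
  embedding <- as.matrix(embedding)
  variants <- as.character(variants)
  if (length(variants) != nrow(embedding)) {
    stop("one variant label per embedding row required")
  }
  if (!wt_id %in% variants || !lof_id %in% variants) {
    stop("WT and LoF control cells must be present in the embedding")
  }
  refs <- list(WT = embedding[variants == wt_id, , drop = FALSE],
               LoF = embedding[variants == lof_id, , drop = FALSE])
  ids <- setdiff(sort(unique(variants)), c(wt_id, lof_id))
  rows <- lapply(ids, function(v) {
    xv <- embedding[variants == v, , drop = FALSE]
    do.call(rbind, lapply(names(refs), function(ctl) {
      h <- hotelling_t2(xv, refs[[ctl]])
      data.frame(variant = v, control = ctl, n1 = h$n1, n2 = h$n2,
                 t2 = h$t2, f_stat = h$f_stat, df1 = h$df1, df2 = h$df2,
                 p_value = h$p_value, valid = h$valid,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phenotype call from the two control comparisons
#'
#' Applies the significance rule at level `alpha` to the T-squared p-values
#' of a variant against the WT and LoF controls:
#' indistinguishable from WT but different from LoF is `WT-like`; the mirror
#' image is `LoF-like`; different from both controls is `hypomorphic`;
#' different from neither is `indeterminate`.
#'
#' @param p_wt,p_lof numeric vectors of p-values (recycled to equal length).
#' @param alpha significance level, default 0.05 on the raw p-values.
#' @return character vector of calls.
#' @examples
#' assign_phenotype(c(0.30, 1e-6, 0.5), c(1e-5, 1e-6, 0.5), 0.05)
#' @export
assign_phenotype <- function(p_wt, p_lof, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  n <- max(length(p_wt), length(p_lof))
  p_wt <- rep_len(p_wt, n); p_lof <- rep_len(p_lof, n)
  if (any(!is.finite(p_wt) | !is.finite(p_lof))) stop("p-values must be finite")
  sig_wt <- p_wt < alpha
  sig_lof <- p_lof < alpha
  out <- rep("indeterminate", n)
  out[!sig_wt & sig_lof] <- "WT-like"
  out[sig_wt & !sig_lof] <- "LoF-like"
  out[sig_wt & sig_lof] <- "hypomorphic"
  out
}
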