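#' Exact 2x2 inference with the conditional-MLE odds ratio
#'
#' Completes a 2x2 contingency table with the odds ratio that maximises the
#' Fisher noncentral hypergeometric likelihood conditional on both margins
#' (the estimator printed by standard exact-test software), together with the
#' exact two-sided p-value under the null odds ratio of 1.
#'
#' The table is laid out as
#' \preformatted{          positive  negative
#'  exposed         a         b
#'  unexposed       c         d}
#' Conditional on the margins, the count in cell `a` follows a Fisher
#' noncentral hypergeometric distribution with parameter `psi` (the odds
#' ratio). The conditional MLE solves `E[A | margins, psi] = a`; the
#' expectation is strictly increasing in `log(psi)`, so the root is found by
#' monotone bisection on `log(psi)` in `[-36, 36]` to an absolute tolerance
#' of 1e-9 on the expectation. When `a` sits on the boundary of its support
#' the MLE degenerates to 0 or `Inf`. The two-sided p-value sums the null
#' (`psi = 1`) probabilities of all tables whose probability does not exceed
#' that of the observed table (relative tie tolerance 1 + 1e-7).
#'
#' Hypergeometric weights are evaluated in log space (via `lchoose`) so that
#' totals of several hundred do not overflow.
#'
#' @param table 2x2 numeric matrix of counts, or a length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @return An object of class `contingency_table`: a list with the counts
#'   `a,b,c,d`, `psi_hat` (conditional-MLE odds ratio; 0 or `Inf` on boundary
#'   tables), `log_or` (its log), `p_value` (exact two-sided), `boundary`
#'   (logical), and `degenerate` (`TRUE` when a margin is zero, in which case
#'   `psi_hat` is `NA` and `p_value` is 1).
#' @examples
#' fisher_cmle(matrix(c(7, 1, 31, 40), 2, byrow = TRUE))
#' fisher_cmle(c(5, 5, 5, 5))
#' @export
fisher_cmle <- function(table) {
  x <- as.numeric(table)
  if (length(x) != 4 || any(!is.finite(x)) || any(x < 0) ||
      any(x != round(x))) {
    stop("'table' must hold four finite non-negative integer counts")
  }
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  }
  m1 <- a + b            # exposed row total
  m2 <- c + d
  k  <- a + c            # positive column total
  n  <- m1 + m2

  out <- list(a = a, b = b, c = c, d = d)
  class(out) <- "contingency_table"

  if (m1 == 0 || m2 == 0 || k == 0 || k == n) {
    out$psi_hat <- NA_real_
    out$log_or <- NA_real_
    out$p_value <- 1
    out$boundary <- FALSE
    out$degenerate <- TRUE
    return(out)
  }

  lo <- max(0, k - m2)
  hi <- min(m1, k)
  support <- lo:hi
  lw0 <- lchoose(m1, support) + lchoose(m2, k - support)

  cond_mean <- function(log_psi) {
    lw <- lw0 + support * log_psi
    w <- exp(lw - max(lw))
    sum(support * w) / sum(w)
  }

  out$degenerate <- FALSE
  if (a == lo) {
    out$psi_hat <- 0
    out$boundary <- TRUE
  } else if (a == hi) {
    out$psi_hat <- Inf
    out$boundary <- TRUE
  } else {
    f <- function(lp) cond_mean(lp) - a
    root <- stats::uniroot(f, interval = c(-36, 36), tol = 1e-12)$root
    # polish until the conditional expectation matches a to 1e-9
    for (i in 1:5) {
      if (abs(f(root)) < 1e-9) break
      h <- 1e-6
      deriv <- (f(root + h) - f(root - h)) / (2 * h)
      if (!is.finite(deriv) || deriv <= 0) break
      root <- root - f(root) / deriv
    }
    out$psi_hat <- exp(root)
    out$boundary <- FALSE
  }
  out$log_or <- log(out$psi_hat)

  # exact two-sided p under psi = 1: probability-ordering convention
  lp_null <- lw0 - log_sum_exp(lw0)
  p_obs <- lp_null[support == a]
  keep <- lp_null <= p_obs + log1p(1e-7)
  out$p_value <- min(1, exp(log_sum_exp(lp_null[keep])))
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 exact inference (conditional-MLE odds ratio)\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("positive", "negative")))
  print(m)
  if (isTRUE(x$degenerate)) {
    cat("degenerate margin: odds ratio undefined, p = 1\n")
  } else {
    cat(sprintf("psi_hat = %.4g%s, two-sided p = %.4g\n", x$psi_hat,
                if (isTRUE(x$boundary)) " (boundary)" else "", x$p_value))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"` so the whole
#' package shares one multiple-testing entry point.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, monotone in the input order statistics and
#'   capped at 1.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' ROC and precision-recall summaries for a score
#'
#' AUROC is computed by the tie-corrected Mann-Whitney rank formula (midranks
#' for tied scores). AUPR uses step interpolation of precision over recall:
#' thresholds sweep the distinct score values from high to low and each
#' recall increment contributes the precision attained at that threshold.
#'
#' @param scores numeric vector, larger = more positive-like.
#' @param labels binary vector (0/1, logical, or a 2-level factor whose second
#'   level is the positive class).
#' @return list with `auroc`, `aupr`, and a data.frame `curve` holding
#'   threshold, tpr/recall, fpr, and precision at each distinct score.
#' @export
roc_pr <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse ties: cumulative counts at each distinct threshold
  idx <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[idx]
  fp <- cumsum(1 - y)[idx]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  fpr <- fp / n0
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, aupr = aupr,
       curve = data.frame(threshold = s[idx], recall = recall,
                          precision = precision, fpr = fpr))
}
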