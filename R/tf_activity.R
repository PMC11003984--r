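## TF activity inference from target-gene expression, activity
## correlations, and the differential-expression stage.

#' Infer per-sample TF activities from target expression
#'
#' The activity of a TF is a signed aggregate of the standardized
#' expression of its target genes: each target row is z-scored across
#' samples, weighted +1 or -1 by the sign of its Spearman correlation with
#' the TF's own expression row, and the weighted rows are averaged.  When
#' the TF itself is not measured, orientation falls back to the first
#' principal direction of the target matrix, with the overall sign chosen
#' so the activity correlates non-negatively with the majority of targets.
#' The estimator is behind this single function so alternative activity
#' models can be swapped in.
#'
#' @param expr An [expression_set()].
#' @param db A `tf_target_db`.
#' @param tfs TFs to infer (default: all TFs in `db`).
#' @return Numeric TFs x samples matrix.
#' @export
infer_activity <- function(expr, db, tfs = db_tfs(db)) {
  mat <- expr$expr
  act <- matrix(NA_real_, length(tfs), ncol(mat),
                dimnames = list(tfs, colnames(mat)))
  for (tf in tfs) {
    if (!tf %in% db$tf) stop("TF absent from database: ", tf)
    targets <- intersect(db_targets(db, tf), rownames(mat))
    targets <- setdiff(targets, tf)  # activity reflects targets, not self
    if (length(targets) == 0)
      stop("TF has no target present in the expression matrix: ", tf)
    z <- t(apply(mat[targets, , drop = FALSE], 1, zscore))
    if (tf %in% rownames(mat)) {
      anchor <- mat[tf, ]
      w <- vapply(targets, function(g) {
        r <- suppressWarnings(cor(mat[g, ], anchor, method = "spearman"))
        if (is.na(r) || r == 0) 1 else sign(r)
      }, 0)
    } else {
      pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
      w <- vapply(pc$rotation[, 1], function(v) if (v == 0) 1 else sign(v), 0)
      a <- colMeans(z * w)
      agree <- vapply(seq_along(targets), function(i) {
        r <- suppressWarnings(cor(a, z[i, ], method = "spearman"))
        if (is.na(r)) 0 else sign(r)
      }, 0)
      if (sum(agree) < 0) w <- -w
    }
    act[tf, ] <- colMeans(z * w)
  }
  act
}

# z-score a vector; zero-variance vectors map to zeros
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Spearman correlation matrix of TF activities
#'
#' @param act TFs x samples activity matrix with at least 3 samples.
#' @return Symmetric TF x TF correlation matrix with unit diagonal.
#'   Correlations that are undefined because an activity row is constant
#'   are recorded as 0 with a warning.
#' @export
activity_spearman <- function(act) {
  if (ncol(act) < 3) stop("at least 3 samples are required")
  rho <- suppressWarnings(cor(t(act), method = "spearman"))
  if (anyNA(rho)) {
    warning("constant activity row(s); undefined correlations set to 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Two-group differential expression (Welch t + Benjamini-Hochberg)
#'
#' Per-gene Welch two-sample t-test between control and case samples with
#' Benjamini-Hochberg adjustment.  This stage is pluggable: a precomputed
#' differential-expression table can be supplied anywhere a DEG list is
#' consumed.  Genes with zero variance in both groups are excluded with a
#' warning.
#'
#' @param expr An [expression_set()] with at least 2 samples per group.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame (gene, statistic, p_value, p_adjusted, significant),
#'   ordered by adjusted p-value.
#' @export
differential_genes <- function(expr, alpha = 0.05) {
  g1 <- expr$expr[, expr$labels == "control", drop = FALSE]
  g2 <- expr$expr[, expr$labels == "case", drop = FALSE]
  if (ncol(g1) < 2 || ncol(g2) < 2)
    stop("each group needs at least 2 samples")
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, function(x) sum((x - mean(x))^2)) / (n1 - 1)
  v2 <- apply(g2, 1, function(x) sum((x - mean(x))^2)) / (n2 - 1)
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate))
    warning(sum(degenerate), " zero-variance gene(s) excluded")
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  out <- data.frame(gene = rownames(expr$expr), statistic = stat,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[!degenerate, , drop = FALSE]
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$gene), ]
  rownames(out) <- NULL
  out
}
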