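## Context-specific TF-target database construction: selection of
## accessibility-derived targets and merging with the curated database.

#' Select ATAC-derived targets for each TF
#'
#' For each TF, the genes whose binding probability is strictly above
#' `threshold` form the probable target pool of size `n_genes`.  If
#' `n_genes < n_tsh` all of them are kept; otherwise the top
#' `round(n_tsh + (n_genes - n_tsh) * top_frac)` genes by descending
#' probability are kept (rounding half away from zero; ties in probability
#' broken by gene identifier for determinism).  TFs with no passing gene
#' are absent from the result.
#'
#' @param binding A [binding_table()].
#' @param threshold Binding probability threshold in `[0, 1]`.
#' @param n_tsh Pool size below which all passing genes are kept
#'   (default 50).
#' @param top_frac Fraction used to extend the kept count beyond `n_tsh`
#'   (default 0.01, i.e. the top 1 percent of the pool overflow).
#' @return A `tf_target_db` with provenance `"atac"`.
#' @export
select_atac_targets <- function(binding, threshold, n_tsh = 50,
                                top_frac = 0.01) {
  stopifnot(threshold >= 0, threshold <= 1, n_tsh >= 0,
            top_frac > 0, top_frac <= 1)
  keep <- binding$probability > threshold
  if (!any(keep)) return(tf_target_db())
  sub <- binding[keep, , drop = FALSE]
  pieces <- lapply(split(seq_len(nrow(sub)), sub$tf), function(idx) {
    probs <- sub$probability[idx]
    genes <- sub$gene[idx]
    ord <- order(-probs, genes)
    n_genes <- length(idx)
    n_target <- if (n_genes < n_tsh) n_genes
                else round_half_away(n_tsh + (n_genes - n_tsh) * top_frac)
    sel <- ord[seq_len(min(n_target, n_genes))]
    data.frame(tf = sub$tf[idx][sel], target = genes[sel],
               probability = probs[sel], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  tf_target_db(out$tf, out$target, provenance = "atac",
               probability = out$probability)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Merge two TF-target databases
#'
#' Per-TF set union of targets.  When the same (TF, target) pair occurs in
#' both inputs its provenance is recorded as `"both"`; a curated binding
#' probability of `NA` is replaced by the ATAC probability when available.
#' The operation is commutative and associative at the set level.
#'
#' @param curated,atac `tf_target_db` objects.
#' @return A merged `tf_target_db`.
#' @export
merge_dbs <- function(curated, atac) {
  all <- rbind(as.data.frame(curated), as.data.frame(atac))
  if (nrow(all) == 0) return(tf_target_db())
  key <- paste(all$tf, all$target, sep = "\r")
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    idx <- match(dup_keys, key[first])
    for (i in seq_along(dup_keys)) {
      rows <- which(key == dup_keys[[i]])
      provs <- unique(all$provenance[rows])
      out$provenance[idx[i]] <- if (length(provs) > 1) "both" else provs
      pr <- all$probability[rows]
      pr <- pr[!is.na(pr)]
      if (length(pr)) out$probability[idx[i]] <- pr[[1]]
    }
  }
  rownames(out) <- NULL
  class(out) <- c("tf_target_db", "data.frame")
  out
}

#' Drop TFs with too few targets
#'
#' Retains only TFs with at least `min_targets` targets (default 8) in the
#' database.
#'
#' @param db A `tf_target_db`.
#' @param min_targets Minimum target-set size (default 8).
#' @return Filtered `tf_target_db`.
#' @export
filter_min_targets <- function(db, min_targets = 8) {
  stopifnot(min_targets >= 1)
  if (nrow(db) == 0) return(db)
  counts <- table(db$tf)
  keep_tfs <- names(counts)[counts >= min_targets]
  out <- db[db$tf %in% keep_tfs, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tf_target_db", "data.frame")
  out
}

#' Restrict a database to targets present in an expression matrix
#'
#' Applied before the minimum-target filter so that target counts reflect
#' genes actually measured.
#'
#' @param db A `tf_target_db`.
#' @param genes Character vector of measured genes.
#' @return Restricted `tf_target_db`.
#' @export
restrict_db_to_genes <- function(db, genes) {
  out <- db[db$target %in% genes, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tf_target_db", "data.frame")
  out
}

#' Build the merged context-specific database in one call
#'
#' Convenience wrapper: select ATAC targets at a threshold, merge with the
#' curated database, optionally restrict to measured genes, and apply the
#' minimum-target filter.
#'
#' @inheritParams select_atac_targets
#' @param curated Curated `tf_target_db`.
#' @param genes Optional character vector of measured genes.
#' @param min_targets Minimum target-set size (default 8).
#' @return A `tf_target_db`.
#' @export
build_merged_db <- function(curated, binding, threshold, n_tsh = 50,
                            top_frac = 0.01, genes = NULL, min_targets = 8) {
  atac <- select_atac_targets(binding, threshold, n_tsh, top_frac)
  merged <- merge_dbs(curated, atac)
  if (!is.null(genes)) merged <- restrict_db_to_genes(merged, genes)
  filter_min_targets(merged, min_targets)
}
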