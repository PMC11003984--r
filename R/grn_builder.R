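## Candidate GRN enumeration over the hyperparameter grid.

#' Combine ranked TF lists
#'
#' Union of the top-`k` TFs of each ranked list, optionally restricted to
#' TFs surviving the minimum-target filter of a merged database.  If `k`
#' exceeds a list's length the whole list is used with a warning.
#'
#' @param ranked_lists List of character vectors, each ranked best-first.
#' @param k Number of TFs to take from each list.
#' @param db Optional `tf_target_db`; when given, only its TFs are kept.
#' @return Character vector of TFs (first-appearance order).
#' @export
combine_tf_lists <- function(ranked_lists, k, db = NULL) {
  stopifnot(k >= 1, length(ranked_lists) >= 1)
  picked <- unlist(lapply(ranked_lists, function(l) {
    if (length(l) == 0) stop("empty ranked TF list")
    if (k > length(l)) {
      warning("k = ", k, " exceeds list length ", length(l),
              "; using the whole list")
      l
    } else {
      l[seq_len(k)]
    }
  }), use.names = FALSE)
  tfs <- unique(picked)
  if (!is.null(db)) tfs <- tfs[tfs %in% db_tfs(db)]
  tfs
}

#' Build one candidate network from activities and the target database
#'
#' A directed edge A -> B is created iff B is a target of A in `db` and the
#' absolute Spearman correlation of their activities is strictly above
#' `cutoff`; the edge sign is the sign of the correlation.  Self-loops are
#' excluded by default (a row's correlation with itself is 1 and carries no
#' information).  The largest weakly connected component is then retained
#' if it holds at least `min_frac` of the TFs with any retained edge;
#' otherwise, or when it has fewer than `min_tfs` TFs, the candidate is
#' discarded (`NULL`).
#'
#' @param tfs Character vector of TFs in play.
#' @param db A `tf_target_db`.
#' @param corr TF x TF activity correlation matrix covering `tfs`.
#' @param cutoff Absolute-correlation threshold in `[0, 1)`.
#' @param min_tfs Minimum component size (default 15).
#' @param min_frac Minimum fraction of the network's TFs that the largest
#'   component must hold (default 0.8).
#' @param allow_self_loops Keep TF self-edges from the database
#'   (default `FALSE`).
#' @return A `gene_network`, or `NULL` when the candidate is discarded.
#' @export
build_candidate <- function(tfs, db, corr, cutoff, min_tfs = 15,
                            min_frac = 0.8, allow_self_loops = FALSE) {
  if (!all(tfs %in% rownames(corr)))
    stop("correlation matrix does not cover all TFs")
  sub <- db[db$tf %in% tfs & db$target %in% tfs, , drop = FALSE]
  if (!allow_self_loops) sub <- sub[sub$tf != sub$target, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  rho <- corr[cbind(sub$tf, sub$target)]
  keep <- abs(rho) > cutoff
  sub <- sub[keep, , drop = FALSE]
  rho <- rho[keep]
  if (nrow(sub) == 0) return(NULL)
  edges <- data.frame(from = sub$tf, to = sub$target,
                      sign = ifelse(rho >= 0, "activation", "inhibition"),
                      provenance = ifelse(sub$provenance == "both", "curated",
                                          sub$provenance),
                      correlation = rho, stringsAsFactors = FALSE)
  nodes <- union(edges$from, edges$to)
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = TRUE,
                                     vertices = nodes)
  comp <- igraph::components(g, mode = "weak")
  biggest <- which.max(comp$csize)
  members <- names(comp$membership)[comp$membership == biggest]
  if (length(members) < min_frac * length(nodes)) return(NULL)
  if (length(members) < min_tfs) return(NULL)
  edges <- edges[edges$from %in% members & edges$to %in% members, ,
                 drop = FALSE]
  gene_network(sort(members), edges)
}

#' Enumerate candidate GRNs over the hyperparameter grid
#'
#' For each (binding threshold, TFs-per-list k) pair the merged database,
#' combined TF set, activities, and activity correlations are rebuilt;
#' then one candidate is attempted per correlation cutoff.  Discarded
#' combinations are omitted.  The result is deterministic given the
#' inputs.
#'
#' @param ranked_lists List of ranked TF character vectors.
#' @param expr An [expression_set()].
#' @param curated Curated `tf_target_db`.
#' @param binding A [binding_table()].
#' @param binding_grid Numeric vector of binding probability thresholds
#'   (default the eleven values 0.05-0.20 used for candidate construction).
#' @param k_grid Integer vector of per-list TF counts (default
#'   `c(5, 10, 15, 20)`).
#' @param cutoff_grid Numeric vector of activity correlation cutoffs
#'   (default `seq(0, 0.95, by = 0.05)`).
#' @param n_tsh,top_frac Target-selection rule (see
#'   [select_atac_targets()]).
#' @param min_targets Minimum target count per TF (default 8).
#' @param min_tfs,min_frac Candidate retention rule (see
#'   [build_candidate()]).
#' @return List of candidates; each element has `id`, `hyper` (list with
#'   `binding_threshold`, `k`, `cutoff`), `network`, and `activity` (the
#'   TF x sample activity matrix restricted to network nodes).
#' @export
enumerate_candidates <- function(ranked_lists, expr, curated, binding,
                                 binding_grid = c(0.05, 0.06, 0.07, 0.08,
                                                  0.09, 0.10, 0.12, 0.14,
                                                  0.16, 0.18, 0.20),
                                 k_grid = c(5, 10, 15, 20),
                                 cutoff_grid = seq(0, 0.95, by = 0.05),
                                 n_tsh = 50, top_frac = 0.01,
                                 min_targets = 8, min_tfs = 15,
                                 min_frac = 0.8) {
  stopifnot(length(binding_grid) > 0, length(k_grid) > 0,
            length(cutoff_grid) > 0)
  out <- list()
  for (bt in binding_grid) {
    db <- tryCatch(
      build_merged_db(curated, binding, bt, n_tsh, top_frac,
                      genes = rownames(expr$expr), min_targets = min_targets),
      error = function(e) stop("binding threshold ", bt, ": ",
                               conditionMessage(e)))
    if (nrow(db) == 0) next
    for (k in k_grid) {
      tfs <- suppressWarnings(combine_tf_lists(ranked_lists, k, db))
      tfs <- tfs[vapply(tfs, function(tf)
        length(setdiff(intersect(db_targets(db, tf), rownames(expr$expr)),
                       tf)) > 0, TRUE)]
      if (length(tfs) < 2) next
      act <- tryCatch(infer_activity(expr, db, tfs),
                      error = function(e)
                        stop("binding threshold ", bt, ", k = ", k, ": ",
                             conditionMessage(e)))
      corr <- activity_spearman(act)
      for (cutoff in cutoff_grid) {
        net <- build_candidate(tfs, db, corr, cutoff, min_tfs, min_frac)
        if (is.null(net)) next
        id <- sprintf("b%.3g_k%d_c%.3g", bt, k, cutoff)
        out[[length(out) + 1L]] <- list(
          id = id,
          hyper = list(binding_threshold = bt, k = k, cutoff = cutoff),
          network = net,
          activity = act[net$nodes, , drop = FALSE])
      }
    }
  }
  out
}
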