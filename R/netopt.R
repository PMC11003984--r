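## Candidate GRN scoring: permutation-null state assignment, accuracy and
## flexibility metrics, combined ranking, and top-rank stability testing.

#' Assign ensemble models to experimental states
#'
#' Each (converged) model profile is compared with the standardized TF
#' activity profiles of the experimental samples.  For each state the
#' observed statistic is the Euclidean distance to the nearest same-state
#' sample; the null distribution is built from `n_null` gene-label
#' permutations of the model's own profile (one permutation set per model,
#' shared across states), and the p-value is the fraction of null
#' distances less than or equal to the observed one (no smoothing).  A
#' model is assigned to the state with the smallest p-value when that
#' p-value is at most `alpha`, and is otherwise unassigned.  Ties in
#' p-value are broken by the smaller observed distance, then toward
#' control.
#'
#' @param ensemble A `racipe_ensemble` (its standardized `expr` is used).
#' @param activity TF x sample activity matrix over exactly the ensemble's
#'   genes; rows are z-scored internally.
#' @param labels Factor/character per sample (`control`/`case`), named by
#'   sample or in column order of `activity`.
#' @param n_null Number of gene-shuffle null profiles per model
#'   (default 1000).
#' @param alpha Assignment significance level (default 0.05).
#' @param seed Seed for the permutation stream.
#' @return Object of class `state_assignment`: per-model `state` factor
#'   (levels control, case, unassigned; over converged models), p-value
#'   and distance matrices, and the call settings.
#' @export
assign_states <- function(ensemble, activity, labels, n_null = 1000,
                          alpha = 0.05, seed = 1) {
  genes <- ensemble$genes
  if (!setequal(rownames(activity), genes))
    stop("gene-set mismatch between ensemble and activity matrix")
  activity <- activity[genes, , drop = FALSE]
  if (!is.null(names(labels))) labels <- labels[colnames(activity)]
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(activity),
            all(labels %in% c("control", "case")))
  act_z <- t(apply(activity, 1, zscore))
  samples <- t(act_z)                        # samples x genes
  state_code <- ifelse(labels == "control", 0L, 1L)

  models <- ensemble$expr[ensemble$converged, , drop = FALSE]
  set.seed(seed)
  res <- assign_null_pvals(models, samples, state_code, as.integer(n_null))
  pv <- res$pvals
  dm <- res$dmin
  colnames(pv) <- colnames(dm) <- c("control", "case")
  pick <- ifelse(pv[, 1] < pv[, 2], 1L,
          ifelse(pv[, 2] < pv[, 1], 2L,
          ifelse(dm[, 1] <= dm[, 2], 1L, 2L)))
  best_p <- pv[cbind(seq_len(nrow(pv)), pick)]
  state <- ifelse(best_p <= alpha, c("control", "case")[pick], "unassigned")
  structure(list(state = factor(state,
                                levels = c("control", "case", "unassigned")),
                 pvals = pv, dmin = dm, alpha = alpha, n_null = n_null,
                 seed = seed, n_converged = nrow(models),
                 n_total = nrow(ensemble$expr)),
            class = "state_assignment")
}

#' State proportions of an assignment
#'
#' @param assignment A `state_assignment`.
#' @return Named numeric vector (control, case, unassigned) summing to 1.
#' @export
state_proportions <- function(assignment) {
  n <- length(assignment$state)
  if (n == 0) stop("empty assignment")
  tab <- table(assignment$state) / n
  c(control = unname(tab[["control"]]), case = unname(tab[["case"]]),
    unassigned = unname(tab[["unassigned"]]))
}

#' Accuracy of a network's ensemble
#'
#' Fraction of the (converged) models assigned to either experimental
#' state; equivalently one minus the unassigned proportion.
#'
#' @param assignment A `state_assignment`.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(assignment) {
  p <- state_proportions(assignment)
  unname(p[["control"]] + p[["case"]])
}

#' Flexibility of a network
#'
#' Mean, over all single-gene knockdowns, of the Euclidean shift of the
#' two-state model proportions:
#' `f = (1/n) * sum_i sqrt((m_ctrl^u - m_ctrl^KDi)^2 +
#'                          (m_case^u - m_case^KDi)^2)`.
#'
#' @param unperturbed_props Named proportions of the unperturbed ensemble
#'   (needs `control` and `case`).
#' @param kd_props List of such vectors, one per knocked-down TF.
#' @return Scalar flexibility (in `[0, sqrt(2)]`).
#' @export
flexibility <- function(unperturbed_props, kd_props) {
  if (length(kd_props) == 0) stop("no knockdown proportions supplied")
  devs <- vapply(kd_props, function(p) {
    sqrt((unperturbed_props[["control"]] - p[["control"]])^2 +
           (unperturbed_props[["case"]] - p[["case"]])^2)
  }, 0)
  mean(devs)
}

#' Score one candidate network
#'
#' Simulates the random-parameter ensemble, assigns states against the
#' candidate's activity profiles, computes the accuracy, then re-simulates
#' one knockdown per network TF to compute the flexibility.  All seeds are
#' derived from `seed` and the network topology, so identical topologies
#' receive identical ensembles.
#'
#' @param network A `gene_network`.
#' @param activity TF x sample activity matrix over the network's nodes.
#' @param labels Sample state labels (`control`/`case`).
#' @param ranges A [sampling_ranges()].
#' @param n_models Ensemble size.
#' @param n_null,alpha Assignment settings (defaults 1000, 0.05).
#' @param seed Master seed.
#' @param kd_factor Knockdown strength (default 0.95).
#' @param keep_ensemble Keep the unperturbed ensemble and assignment in
#'   the result (default `FALSE`).
#' @return List with `accuracy`, `flexibility`, `proportions`,
#'   `kd_proportions`, and optionally `ensemble`/`assignment`.
#' @export
score_candidate <- function(network, activity, labels,
                            ranges = sampling_ranges(), n_models = 10000,
                            n_null = 1000, alpha = 0.05, seed = 1,
                            kd_factor = 0.95, keep_ensemble = FALSE) {
  h <- hash_topology(network)
  ens <- simulate_ensemble(network, ranges, n_models,
                           seed = derive_seed(seed, "sim", h))
  asn <- assign_states(ens, activity, labels, n_null, alpha,
                       seed = derive_seed(seed, "assign", h))
  props <- state_proportions(asn)
  kd_props <- lapply(network$nodes, function(tf) {
    kd <- simulate_knockdown(ens, tf, kd_factor)
    state_proportions(assign_states(kd, activity, labels, n_null, alpha,
                                    seed = derive_seed(seed, "assign", h,
                                                       tf)))
  })
  names(kd_props) <- network$nodes
  out <- list(accuracy = accuracy(asn),
              flexibility = flexibility(props, kd_props),
              proportions = props, kd_proportions = kd_props)
  if (keep_ensemble) {
    out$ensemble <- ens
    out$assignment <- asn
  }
  out
}

#' Rank candidates by combined accuracy and flexibility
#'
#' Rank index 1 goes to the highest accuracy and, separately, to the
#' highest flexibility; the combined index is the sum of the two rank
#' indices and candidates are returned in ascending combined order.  Ties
#' are broken deterministically: within each metric by candidate id; in
#' the final order by higher accuracy, then fewer edges, then id.
#'
#' @param scores Data frame with columns `id`, `accuracy`, `flexibility`,
#'   and (for tie-breaking) `n_edges`.
#' @return The data frame with `accuracy_rank`, `flexibility_rank`, and
#'   `combined_index` added, ordered best first.
#' @export
rank_candidates <- function(scores) {
  stopifnot(nrow(scores) >= 1)
  n <- nrow(scores)
  acc_rank <- integer(n)
  acc_rank[order(-scores$accuracy, scores$id)] <- seq_len(n)
  flex_rank <- integer(n)
  flex_rank[order(-scores$flexibility, scores$id)] <- seq_len(n)
  scores$accuracy_rank <- acc_rank
  scores$flexibility_rank <- flex_rank
  scores$combined_index <- acc_rank + flex_rank
  if (is.null(scores$n_edges)) scores$n_edges <- NA_integer_
  ord <- order(scores$combined_index, -scores$accuracy, scores$n_edges,
               scores$id)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stability of the top-ranked candidates under repeated simulation
#'
#' Re-scores each candidate over `n_repeats` independent ensembles,
#' re-ranks within each repeat, and tests (two-sided t-test) whether the
#' first candidate's combined scores differ from each rival's.
#'
#' @param candidates List of candidate objects (elements `id`, `network`,
#'   `activity`), best-ranked first.
#' @param labels Sample state labels.
#' @param ranges,n_models,n_null,alpha,kd_factor Scoring settings.
#' @param n_repeats Number of repeats (default 10).
#' @param seed Master seed; per-repeat, per-topology seeds are derived
#'   from it.
#' @return List with `scores` (repeats x candidates matrix of combined
#'   indices), `p_values` (top vs each rival), and `stable` (all
#'   p < 0.05).
#' @export
rerank_stability <- function(candidates, labels, ranges = sampling_ranges(),
                             n_models = 10000, n_null = 1000, alpha = 0.05,
                             kd_factor = 0.95, n_repeats = 10, seed = 1) {
  stopifnot(length(candidates) >= 2, n_repeats >= 2)
  ids <- vapply(candidates, `[[`, "", "id")
  combined <- matrix(NA_real_, n_repeats, length(candidates),
                     dimnames = list(NULL, ids))
  for (r in seq_len(n_repeats)) {
    sc <- do.call(rbind, lapply(candidates, function(cand) {
      s <- score_candidate(cand$network, cand$activity, labels, ranges,
                           n_models, n_null, alpha,
                           seed = derive_seed(seed, "stab", r),
                           kd_factor = kd_factor)
      data.frame(id = cand$id, accuracy = s$accuracy,
                 flexibility = s$flexibility, stringsAsFactors = FALSE)
    }))
    # tie-averaged ranks: candidates with equal metrics must receive equal
    # combined scores, or the t-test would see an artifactual id effect
    combined[r, sc$id] <- rank(-sc$accuracy, ties.method = "average") +
      rank(-sc$flexibility, ties.method = "average")
  }
  pvals <- vapply(seq_along(candidates)[-1], function(j) {
    a <- combined[, 1]
    b <- combined[, j]
    if (all(a == b)) return(1)
    if (sd(a - b) == 0) return(0)  # constant nonzero difference
    tryCatch(t.test(a, b)$p.value, error = function(e) 1)
  }, 0)
  names(pvals) <- ids[-1]
  list(scores = combined, p_values = pvals, stable = all(pvals < 0.05))
}
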