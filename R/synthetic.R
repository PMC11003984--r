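## Synthetic inputs with the statistical structure the framework assumes:
## a planted bistable GRN (two mutually inhibiting, internally activating
## TF modules), two well-separated expression states, a noisy binding
## table, a curated database with dropout and spurious entries, and
## jittered ranked TF lists standing in for external selection methods.

#' Generate a planted bistable regulatory system
#'
#' TFs are split into two modules, A and B.  Within a module each TF
#' activates its two successors (circularly); across modules each TF
#' inhibits two TFs of the other module — the minimal motif whose random
#' ensemble reproduces a two-cluster expression structure.  Each TF also
#' regulates `targets_per_tf` private target genes (mostly activating; a
#' minority of targets are repressed so sign inference is exercised).
#' Module-A genes are high in the control state and low in the case
#' state; module-B genes the opposite.  The curated database is the set
#' of planted regulons subjected to entry dropout plus spurious extra
#' entries; the binding table gives planted pairs probabilities in
#' (0.5, 1) and background pairs probabilities in (0, 0.3), so every
#' threshold in the usual 0.05-0.20 grid separates them.  Decoy TFs with
#' random regulons and noise expression are added to exercise the
#' filtering stages without polluting the planted signal.
#'
#' @param n_tfs Number of planted TFs (default 20; at least 15 so that
#'   candidates can survive the minimum-size rule).
#' @param targets_per_tf Private target genes per TF (default 20).
#' @param effect_size Between-state centroid separation in units of
#'   `noise_sd` (default 2).
#' @param noise_sd Per-gene Gaussian noise SD on the log2 scale
#'   (default 1).
#' @param dropout Per-entry probability that a planted pair is missing
#'   from the curated database (and, independently, from the binding
#'   table); default 0.05.
#' @param spurious_rate Expected fraction of spurious extra entries per
#'   regulon (default 0.02).
#' @param n_decoys Decoy TFs (default 10).
#' @param decoy_targets Targets per decoy regulon (default 12).
#' @param seed Seed (default 1).
#' @return Object of class `planted_system`.
#' @export
make_planted_system <- function(n_tfs = 20, targets_per_tf = 20,
                                effect_size = 2, noise_sd = 1,
                                dropout = 0.05, spurious_rate = 0.02,
                                n_decoys = 10, decoy_targets = 12,
                                seed = 1) {
  if (n_tfs < 4) stop("need at least 4 TFs to plant two modules")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (spurious_rate < 0 || spurious_rate >= 1)
    stop("spurious_rate must lie in [0, 1)")
  set.seed(seed)

  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  n_a <- ceiling(n_tfs / 2)
  modules <- setNames(rep(c("A", "B"), c(n_a, n_tfs - n_a)), tfs)
  mod_a <- tfs[modules == "A"]
  mod_b <- tfs[modules == "B"]

  # Mutual inhibition between the modules is dense (three cross-module
  # inhibitions per TF) while in-module activation is sparse (one edge for
  # the first three TFs of each module): under the maximum-production
  # normalization a gene whose excitatory inputs are silent is produced at
  # G / prod(lambda+), so activator-gated genes default off and dense
  # in-module activation would collapse both modules; inhibition-dominant
  # coupling keeps the two single-module-high attractors strong.
  succ <- function(v, i, off) v[(i + off - 1) %% length(v) + 1]
  edges <- list()
  add <- function(from, to, sign)
    data.frame(from = from, to = to, sign = sign, stringsAsFactors = FALSE)
  for (i in seq_along(mod_a)) {
    edges[[length(edges) + 1]] <-
      add(mod_a[i], c(succ(mod_b, i, 0), succ(mod_b, i, 1),
                      succ(mod_b, i, 2)), "inhibition")
    if (i <= min(3, length(mod_a) - 1))
      edges[[length(edges) + 1]] <- add(mod_a[i], succ(mod_a, i, 1),
                                        "activation")
  }
  for (i in seq_along(mod_b)) {
    edges[[length(edges) + 1]] <-
      add(mod_b[i], c(succ(mod_a, i, 0), succ(mod_a, i, 1),
                      succ(mod_a, i, 2)), "inhibition")
    if (i <= min(3, length(mod_b) - 1))
      edges[[length(edges) + 1]] <- add(mod_b[i], succ(mod_b, i, 1),
                                        "activation")
  }
  edges <- do.call(rbind, edges)
  edges <- edges[edges$from != edges$to, ]
  edges <- edges[!duplicated(edges[c("from", "to")]), ]
  edges$provenance <- "curated"
  edges$correlation <- ifelse(edges$sign == "activation", 1, -1)
  truth <- gene_network(tfs, edges)

  # private target genes and regulation signs
  target_genes <- lapply(tfs, function(tf)
    sprintf("T%s_%02d", sub("^TF", "", tf), seq_len(targets_per_tf)))
  names(target_genes) <- tfs
  reg_sign <- lapply(tfs, function(tf)
    setNames(ifelse(runif(targets_per_tf) < 0.9, 1, -1), target_genes[[tf]]))
  names(reg_sign) <- tfs

  regulons <- lapply(tfs, function(tf)
    c(truth$edges$to[truth$edges$from == tf], target_genes[[tf]]))
  names(regulons) <- tfs

  decoys <- if (n_decoys > 0) sprintf("DTF%02d", seq_len(n_decoys))
            else character()
  target_pool <- unlist(target_genes, use.names = FALSE)
  decoy_regulons <- lapply(decoys, function(d)
    sample(target_pool, decoy_targets))
  names(decoy_regulons) <- decoys
  all_regulons <- c(regulons, decoy_regulons)
  all_genes <- unique(c(tfs, decoys, target_pool))

  # curated database: dropout + spurious entries
  curated_rows <- lapply(names(all_regulons), function(tf) {
    tg <- all_regulons[[tf]]
    tg <- tg[runif(length(tg)) >= dropout]
    n_spur <- rbinom(1, length(all_regulons[[tf]]), spurious_rate)
    pool <- setdiff(all_genes, c(tf, tg))
    if (n_spur > 0) tg <- c(tg, sample(pool, min(n_spur, length(pool))))
    if (length(tg) == 0) return(NULL)
    data.frame(tf = tf, target = tg, stringsAsFactors = FALSE)
  })
  curated_df <- do.call(rbind, curated_rows)
  curated <- tf_target_db(curated_df$tf, curated_df$target,
                          provenance = "curated")

  # binding table: planted pairs high, background pairs low
  binding_rows <- lapply(names(all_regulons), function(tf) {
    tg <- all_regulons[[tf]]
    tg <- tg[runif(length(tg)) >= dropout]
    bg_pool <- setdiff(all_genes, c(tf, all_regulons[[tf]]))
    bg <- sample(bg_pool, min(2 * targets_per_tf, length(bg_pool)))
    data.frame(tf = tf, gene = c(tg, bg),
               probability = c(runif(length(tg), 0.5, 1),
                               runif(length(bg), 0, 0.3)),
               stringsAsFactors = FALSE)
  })
  binding_df <- do.call(rbind, binding_rows)
  binding <- binding_table(binding_df$tf, binding_df$gene,
                           binding_df$probability)

  # state centroids on the log2 scale around a common baseline
  half <- effect_size * noise_sd / 2
  centroid <- setNames(rep(0, length(all_genes)), all_genes)
  for (tf in tfs) {
    msign <- if (modules[[tf]] == "A") 1 else -1
    centroid[tf] <- msign * half
    centroid[target_genes[[tf]]] <- msign * half * reg_sign[[tf]]
  }

  structure(list(network = truth, tfs = tfs, modules = modules,
                 decoys = decoys, regulons = all_regulons,
                 reg_sign = reg_sign, curated = curated, binding = binding,
                 genes = all_genes, centroid = centroid,
                 baseline = 7, effect_size = effect_size,
                 noise_sd = noise_sd, dropout = dropout,
                 spurious_rate = spurious_rate, seed = seed),
            class = "planted_system")
}

#' @export
print.planted_system <- function(x, ...) {
  cat(sprintf(paste0("planted_system: %d TFs (+%d decoys), %d edges, ",
                     "effect size %g SD, seed %d\n"),
              length(x$tfs), length(x$decoys), nrow(x$network$edges),
              x$effect_size, x$seed))
  invisible(x)
}

#' Sample a two-state expression matrix from a planted system
#'
#' Per-gene Gaussian noise around the state centroids on the log2 scale.
#'
#' @param sys A `planted_system`.
#' @param n_control,n_case Samples per state (defaults 11 and 9,
#'   emulating a small two-group case/control design).
#' @param seed Seed (default derived from the system seed).
#' @return An [expression_set()].
#' @export
emit_expression <- function(sys, n_control = 11, n_case = 9,
                            seed = derive_seed(sys$seed, "expr")) {
  stopifnot(n_control >= 2, n_case >= 2)
  set.seed(seed)
  samples <- c(sprintf("ctrl_%02d", seq_len(n_control)),
               sprintf("case_%02d", seq_len(n_case)))
  labels <- setNames(rep(c("control", "case"), c(n_control, n_case)),
                     samples)
  state_sign <- rep(c(1, -1), c(n_control, n_case))
  n_genes <- length(sys$genes)
  expr <- matrix(NA_real_, n_genes, length(samples),
                 dimnames = list(sys$genes, samples))
  for (j in seq_along(samples)) {
    expr[, j] <- sys$baseline + state_sign[j] * sys$centroid +
      rnorm(n_genes, 0, sys$noise_sd)
  }
  expression_set(expr, labels)
}

#' Binding table of a planted system
#' @param sys A `planted_system`.
#' @return The [binding_table()] generated with the system.
#' @export
emit_binding_table <- function(sys) sys$binding

#' Curated TF-target database of a planted system
#' @param sys A `planted_system`.
#' @return The curated `tf_target_db` generated with the system.
#' @export
emit_curated_db <- function(sys) sys$curated

#' Jittered ranked TF lists emulating external selection methods
#'
#' Planted TFs come first (base order by identifier), perturbed by
#' `noise_swaps` random adjacent transpositions per list; decoy TFs follow
#' in shuffled order.
#'
#' @param sys A `planted_system`.
#' @param n_methods Number of lists (default 3).
#' @param noise_swaps Adjacent swaps applied per list (default 2); 0
#'   yields identical lists.
#' @param seed Seed (default derived from the system seed).
#' @return List of ranked character vectors.
#' @export
emit_ranked_tf_lists <- function(sys, n_methods = 3, noise_swaps = 2,
                                 seed = derive_seed(sys$seed, "lists")) {
  set.seed(seed)
  lapply(seq_len(n_methods), function(m) {
    ranked <- sys$tfs
    if (noise_swaps > 0 && length(ranked) > 1) {
      for (s in seq_len(noise_swaps)) {
        i <- sample(length(ranked) - 1, 1)
        ranked[c(i, i + 1)] <- ranked[c(i + 1, i)]
      }
    }
    decoys <- if (length(sys$decoys) > 1) sample(sys$decoys) else sys$decoys
    c(ranked, decoys)
  })
}

#' Write all fixtures of a planted system to a directory
#'
#' Emits `expr.tsv`, `labels.tsv`, `binding.tsv`, `curated.gmt`,
#' `tf_lists/method<i>.txt`, and `truth_network.tsv`.
#'
#' @param sys A `planted_system`.
#' @param dir Output directory (created if needed).
#' @param n_control,n_case Samples per state for the expression matrix.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(sys, dir, n_control = 11, n_case = 9) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- emit_expression(sys, n_control, n_case)
  write_expression(expr, file.path(dir, "expr.tsv"),
                   file.path(dir, "labels.tsv"))
  write_binding_table(sys$binding, file.path(dir, "binding.tsv"))
  sets <- split(sys$curated$target, sys$curated$tf)
  write_gmt(sets, file.path(dir, "curated.gmt"), "planted regulon")
  dir.create(file.path(dir, "tf_lists"), showWarnings = FALSE)
  lists <- emit_ranked_tf_lists(sys)
  for (i in seq_along(lists))
    writeLines(lists[[i]], file.path(dir, "tf_lists",
                                     sprintf("method%d.txt", i)))
  write_network(sys$network, file.path(dir, "truth_network.tsv"))
  invisible(dir)
}
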