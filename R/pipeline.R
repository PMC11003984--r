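## End-to-end orchestration: one validated config drives candidate
## enumeration, scoring, ranking, stability checking, and the knockdown /
## annotation report.

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (paths are loaded with
#' the package readers at run time).  Grids must be non-empty; referenced
#' files must exist.
#'
#' @param expr An [expression_set()] or a path to an expression TSV.
#' @param labels_path Label TSV path (required when `expr` is a path).
#' @param curated Curated `tf_target_db`, or path to a GMT file.
#' @param binding A [binding_table()] or path to a binding TSV.
#' @param ranked_lists List of ranked TF vectors, or character vector of
#'   paths to one-TF-per-line files.
#' @param binding_grid,k_grid,cutoff_grid Hyperparameter grids (defaults
#'   as in [enumerate_candidates()]).
#' @param n_tsh,top_frac,min_targets,min_tfs,min_frac Database and
#'   candidate rules.
#' @param ranges A [sampling_ranges()].
#' @param n_models Ensemble size per candidate (default 10000).
#' @param n_null,alpha State-assignment settings (defaults 1000, 0.05).
#' @param kd_factor Knockdown strength (default 0.95).
#' @param ridge_penalty Ridge penalty of the perturbation state mapper.
#' @param stability_repeats Repeats for the top-rank stability check
#'   (default 10; 0 disables it).
#' @param stability_top_n Candidates entering the stability check
#'   (default 10).
#' @param pathways Named list of pathway gene sets, a GMT path, or `NULL`
#'   to skip pathway annotation.
#' @param degs Optional precomputed differentially-expressed gene list (a
#'   character vector, or a path to a one-gene-per-line file), overriding
#'   the built-in Welch/BH stage.
#' @param deg_alpha Adjusted-p cutoff of the differential-expression
#'   stage (default 0.05; ignored when `degs` is supplied).
#' @param annotation_p_max Fisher annotation threshold (default 0.1).
#' @param seed Master seed; all stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expr, labels_path = NULL, curated, binding,
                            ranked_lists,
                            binding_grid = c(0.05, 0.06, 0.07, 0.08, 0.09,
                                             0.10, 0.12, 0.14, 0.16, 0.18,
                                             0.20),
                            k_grid = c(5, 10, 15, 20),
                            cutoff_grid = seq(0, 0.95, by = 0.05),
                            n_tsh = 50, top_frac = 0.01, min_targets = 8,
                            min_tfs = 15, min_frac = 0.8,
                            ranges = sampling_ranges(), n_models = 10000,
                            n_null = 1000, alpha = 0.05, kd_factor = 0.95,
                            ridge_penalty = 1, stability_repeats = 10,
                            stability_top_n = 10, pathways = NULL,
                            degs = NULL, deg_alpha = 0.05,
                            annotation_p_max = 0.1, seed = 1) {
  if (length(binding_grid) == 0 || length(k_grid) == 0 ||
      length(cutoff_grid) == 0)
    stop("hyperparameter grids must be non-empty")
  if (seed != as.integer(seed)) stop("seed must be an integer")
  for (p in c(if (is.character(expr)) expr, labels_path,
              if (is.character(curated)) curated,
              if (is.character(binding)) binding,
              if (is.character(ranked_lists)) ranked_lists,
              if (is.character(pathways)) pathways,
              if (is.character(degs) && length(degs) == 1) degs)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  if (is.character(expr) && is.null(labels_path))
    stop("labels_path is required when expr is a file path")
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_config_inputs <- function(config) {
  if (is.character(config$expr))
    config$expr <- read_expression(config$expr, config$labels_path)
  if (is.character(config$curated))
    config$curated <- sets_to_db(read_gmt(config$curated), "curated")
  if (is.character(config$binding))
    config$binding <- read_binding_table(config$binding)
  if (is.character(config$ranked_lists))
    config$ranked_lists <- lapply(config$ranked_lists, readLines)
  if (is.character(config$pathways))
    config$pathways <- read_gmt(config$pathways)
  if (is.character(config$degs) && length(config$degs) == 1 &&
      file.exists(config$degs))
    config$degs <- readLines(config$degs)
  config
}

activity_checksum <- function(act) {
  sprintf("%.8e", sum(act * seq_along(act)) + 31 * sum(abs(act)))
}

#' Enumerate, score, and rank candidate networks
#'
#' Runs the full optimization: candidate enumeration over the grid,
#' scoring of every candidate (with per-topology simulation reuse —
#' candidates sharing a topology and activity profile are simulated
#' once), combined ranking, and an optional stability check of the top
#' candidates over repeated ensembles.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `grn_optimization`: `scores` (ranked table),
#'   `optimal` network, `optimal_id`, `candidates`, `stability` (or
#'   `NULL`), and a `provenance` block (seed, grids, counts).
#' @export
run_optimize <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- resolve_config_inputs(config)
  labels <- config$expr$labels

  candidates <- enumerate_candidates(
    config$ranked_lists, config$expr, config$curated, config$binding,
    binding_grid = config$binding_grid, k_grid = config$k_grid,
    cutoff_grid = config$cutoff_grid, n_tsh = config$n_tsh,
    top_frac = config$top_frac, min_targets = config$min_targets,
    min_tfs = config$min_tfs, min_frac = config$min_frac)
  if (length(candidates) == 0)
    stop("zero surviving candidates: every hyperparameter combination was ",
         "discarded by the largest-component (>= ", 100 * config$min_frac,
         "% of TFs) or minimum-size (>= ", config$min_tfs, " TFs) rule; ",
         "consider widening the correlation-cutoff grid")

  keys <- vapply(candidates, function(cand)
    paste(hash_topology(cand$network), activity_checksum(cand$activity)),
    "")
  cache <- new.env(parent = emptyenv())
  scores <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    key <- keys[[i]]
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, score_candidate(
        cand$network, cand$activity, labels, config$ranges,
        config$n_models, config$n_null, config$alpha, seed = config$seed,
        kd_factor = config$kd_factor), envir = cache)
    }
    s <- get(key, envir = cache)
    data.frame(id = cand$id,
               binding_threshold = cand$hyper$binding_threshold,
               k = cand$hyper$k, cutoff = cand$hyper$cutoff,
               n_tfs = length(cand$network$nodes),
               n_edges = nrow(cand$network$edges),
               accuracy = s$accuracy, flexibility = s$flexibility,
               m_control = s$proportions[["control"]],
               m_case = s$proportions[["case"]],
               m_unassigned = s$proportions[["unassigned"]],
               sim_key = key, stringsAsFactors = FALSE)
  }))
  ranked <- rank_candidates(scores)

  names(candidates) <- vapply(candidates, `[[`, "", "id")
  stability <- NULL
  if (config$stability_repeats >= 2 && nrow(ranked) >= 2) {
    top_ids <- head(ranked$id, config$stability_top_n)
    stability <- rerank_stability(
      candidates[top_ids], labels, config$ranges, config$n_models,
      config$n_null, config$alpha, config$kd_factor,
      n_repeats = config$stability_repeats, seed = config$seed)
  }

  optimal_id <- ranked$id[[1]]
  structure(list(scores = ranked, optimal = candidates[[optimal_id]]$network,
                 optimal_id = optimal_id,
                 optimal_activity = candidates[[optimal_id]]$activity,
                 optimal_hyper = candidates[[optimal_id]]$hyper,
                 candidates = candidates, stability = stability,
                 labels = labels,
                 provenance = list(
                   seed = config$seed,
                   binding_grid = config$binding_grid,
                   k_grid = config$k_grid, cutoff_grid = config$cutoff_grid,
                   n_models = config$n_models, n_null = config$n_null,
                   n_candidates = length(candidates),
                   n_unique_simulations = length(unique(keys)))),
            class = "grn_optimization")
}

#' @export
print.grn_optimization <- function(x, ...) {
  cat(sprintf(paste0("grn_optimization: %d candidates (%d unique ",
                     "simulations); optimal %s: %d TFs, %d edges, ",
                     "accuracy %.3f, flexibility %.4f\n"),
              x$provenance$n_candidates, x$provenance$n_unique_simulations,
              x$optimal_id, x$scores$n_tfs[[1]], x$scores$n_edges[[1]],
              x$scores$accuracy[[1]], x$scores$flexibility[[1]]))
  invisible(x)
}

#' Knockdown screening and annotation report for the optimal network
#'
#' Simulates the optimal network's unperturbed ensemble, trains the ridge
#' state mapper on distance/null-assigned models, screens all single
#' knockdowns plus the automatic double-knockdown pairs, projects the top
#' significant pairs into the unperturbed PCA space, and (when pathway
#' sets are configured) annotates each network TF with its most
#' representative pathway.
#'
#' @param config A [pipeline_config()].
#' @param optimal A `grn_optimization` result, or a list with elements
#'   `network` and `activity` (TF x sample activity of the network).
#' @return Object of class `grn_perturbation`: `screen` (all KD rows),
#'   `destabilizers` (ranked singles), `significant_pairs`, `pca`,
#'   `annotation` (or `NULL`), `baseline` proportions, and the `mapper`.
#' @export
run_perturb <- function(config, optimal) {
  stopifnot(inherits(config, "pipeline_config"))
  config <- resolve_config_inputs(config)
  if (inherits(optimal, "grn_optimization")) {
    net <- optimal$optimal
    act <- optimal$optimal_activity
    hyper <- optimal$optimal_hyper
  } else {
    net <- optimal$network
    act <- optimal$activity
    hyper <- optimal$hyper
  }
  labels <- config$expr$labels
  h <- hash_topology(net)

  ens <- simulate_ensemble(net, config$ranges, config$n_models,
                           seed = derive_seed(config$seed, "perturb", h))
  asn <- assign_states(ens, act, labels, config$n_null, config$alpha,
                       seed = derive_seed(config$seed, "perturb-assign", h))
  mapper <- train_state_mapper(ens, asn, config$ridge_penalty)
  screen <- kd_screen(net, ens, mapper, kd_sets = NULL,
                      kd_factor = config$kd_factor)
  destab <- rank_destabilizers(screen)
  pairs <- screen[screen$n_genes == 2, , drop = FALSE]
  sig <- pairs[pairs$chisq_p < 0.05, , drop = FALSE]
  sig <- sig[order(sig$chisq_p), , drop = FALSE]

  top_pairs <- head(sig$kd, 3)
  perturbed <- lapply(top_pairs, function(kd) {
    genes <- strsplit(kd, "+", fixed = TRUE)[[1]]
    simulate_knockdown(ens, genes, config$kd_factor)$expr
  })
  names(perturbed) <- top_pairs
  pca <- project_pca(ens$expr[ens$converged, , drop = FALSE], perturbed)

  annotation <- NULL
  if (!is.null(config$pathways)) {
    bt <- if (!is.null(hyper)) hyper$binding_threshold
          else config$binding_grid[[1]]
    db <- build_merged_db(config$curated, config$binding, bt,
                          config$n_tsh, config$top_frac,
                          genes = rownames(config$expr$expr),
                          min_targets = config$min_targets)
    degs <- if (!is.null(config$degs)) {
      config$degs
    } else {
      deg_tab <- differential_genes(config$expr, config$deg_alpha)
      deg_tab$gene[deg_tab$significant]
    }
    regulons <- lapply(setNames(net$nodes, net$nodes), regulon_degs,
                       db = db, degs = degs)
    universe <- unique(c(unlist(regulons, use.names = FALSE),
                         unlist(lapply(config$pathways, intersect, degs),
                                use.names = FALSE)))
    annotation <- fisher_annotate(regulons, config$pathways, universe,
                                  config$annotation_p_max)
  }

  structure(list(screen = screen, destabilizers = destab,
                 significant_pairs = sig, pca = pca,
                 annotation = annotation,
                 baseline = mapper_proportions(predict(mapper, ens)),
                 assignment = asn, mapper = mapper, network = net),
            class = "grn_perturbation")
}

#' @export
print.grn_perturbation <- function(x, ...) {
  cat(sprintf(paste0("grn_perturbation: %d KD conditions (%d singles, ",
                     "%d pairs); %d significant pairs (chi-squared ",
                     "p < 0.05)\n"),
              nrow(x$screen), sum(x$screen$n_genes == 1),
              sum(x$screen$n_genes == 2), nrow(x$significant_pairs)))
  invisible(x)
}

#' Run optimization and perturbation end to end
#'
#' @param config A [pipeline_config()].
#' @return List with `optimization` and `perturbation` results.
#' @export
run_pipeline <- function(config) {
  opt <- run_optimize(config)
  per <- run_perturb(config, opt)
  list(optimization = opt, perturbation = per)
}
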