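## Knockdown screening on the optimal GRN: ridge-based state mapping,
## proportion shifts, chi-squared significance, and PCA projection.

#' Train a ridge state mapper on labeled unperturbed models
#'
#' Ridge regression (via [MASS::lm.ridge()]) of the class indicator
#' (control = 0, case = 1) on the standardized log2 steady states of the
#' assigned (non-unassigned) unperturbed models; predictions are
#' thresholded at 0.5.  The training standardization (per-gene mean and
#' SD of the unperturbed log2 states) is stored so that knockdown
#' profiles are mapped in the same space.
#'
#' @param ensemble The unperturbed `racipe_ensemble`.
#' @param assignment Its `state_assignment`.
#' @param ridge_penalty Ridge penalty on standardized features
#'   (default 1).
#' @param seed Unused placeholder for interface symmetry; the fit is
#'   deterministic.
#' @return Object of class `state_mapper` with coefficients, centering
#'   and scaling vectors, the 0.5 threshold, and training metadata.
#' @export
train_state_mapper <- function(ensemble, assignment, ridge_penalty = 1,
                               seed = NULL) {
  conv <- which(ensemble$converged)
  state <- assignment$state
  keep <- state != "unassigned"
  if (sum(state == "control" & keep) < 10 ||
      sum(state == "case" & keep) < 10)
    stop("need at least 10 assigned models per class to train the mapper")
  lg <- log2(ensemble$states[conv, , drop = FALSE])[keep, , drop = FALSE]
  center <- colMeans(lg)
  scale <- apply(lg, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  x <- sweep(sweep(lg, 2, center), 2, scale, "/")
  y <- as.numeric(state[keep] == "case")
  fit <- MASS::lm.ridge(y ~ x, lambda = ridge_penalty)
  beta <- coef(fit)
  structure(list(intercept = unname(beta[1]),
                 coefficients = setNames(unname(beta[-1]), ensemble$genes),
                 center = center, scale = scale, threshold = 0.5,
                 ridge_penalty = ridge_penalty,
                 n_control = sum(y == 0), n_case = sum(y == 1)),
            class = "state_mapper")
}

#' Map ensemble profiles to the two states with a trained mapper
#'
#' @param object A `state_mapper`.
#' @param ensemble A `racipe_ensemble` (unperturbed or knockdown); only
#'   converged models are mapped.
#' @param ... Unused.
#' @return Factor of predicted states (`control`/`case`) over converged
#'   models.
#' @export
predict.state_mapper <- function(object, ensemble, ...) {
  lg <- log2(ensemble$states[ensemble$converged, , drop = FALSE])
  x <- sweep(sweep(lg[, names(object$coefficients), drop = FALSE], 2,
                   object$center), 2, object$scale, "/")
  score <- object$intercept + drop(x %*% object$coefficients)
  factor(ifelse(score >= object$threshold, "case", "control"),
         levels = c("control", "case"))
}

mapper_proportions <- function(pred) {
  n <- length(pred)
  c(control = sum(pred == "control") / n, case = sum(pred == "case") / n)
}

#' Chi-squared significance of a knockdown's state shift
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x 2 table
#' of (control, case) model counts for the unperturbed versus knockdown
#' condition.  A zero row or column margin makes the statistic undefined;
#' p = 1 is returned with a warning.
#'
#' @param unperturbed_counts,kd_counts Length-2 integer vectors
#'   (control, case).
#' @return The p-value.
#' @export
kd_significance <- function(unperturbed_counts, kd_counts) {
  tab <- rbind(unperturbed = unperturbed_counts, kd = kd_counts)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 state table; returning p = 1")
    return(1)
  }
  if (all(tab[1, ] == tab[2, ])) return(1)
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

#' Single/double knockdown screen over a network
#'
#' Simulates each knockdown set, maps the resulting profiles with the
#' ridge state mapper, and reports state proportions and the chi-squared
#' significance of the shift against the unperturbed mapper proportions.
#' When `kd_sets` is `NULL` the default screen is run: all single
#' knockdowns first, then all unordered pairs among the union of the top
#' five and bottom five single knockdowns ranked by control-state
#' proportion (descending).
#'
#' @param net A `gene_network`.
#' @param ensemble The unperturbed `racipe_ensemble` of `net`.
#' @param mapper A trained `state_mapper`.
#' @param kd_sets Optional list of size-1/2 character vectors.
#' @param kd_factor Knockdown strength (default 0.95).
#' @return Data frame with one row per knockdown set: `kd` (genes joined
#'   by `+`), `n_genes`, `m_control`, `m_case`, `chisq_p`.
#' @export
kd_screen <- function(net, ensemble, mapper, kd_sets = NULL,
                      kd_factor = 0.95) {
  base_pred <- predict(mapper, ensemble)
  base_counts <- c(sum(base_pred == "control"), sum(base_pred == "case"))

  screen_one <- function(genes) {
    unknown <- setdiff(genes, net$nodes)
    if (length(unknown))
      stop("unknown gene(s) in knockdown set: ",
           paste(unknown, collapse = ", "))
    kd_ens <- simulate_knockdown(ensemble, genes, kd_factor)
    pred <- predict(mapper, kd_ens)
    props <- mapper_proportions(pred)
    counts <- c(sum(pred == "control"), sum(pred == "case"))
    data.frame(kd = paste(genes, collapse = "+"),
               n_genes = length(genes),
               m_control = props[["control"]], m_case = props[["case"]],
               chisq_p = kd_significance(base_counts, counts),
               stringsAsFactors = FALSE)
  }

  if (is.null(kd_sets)) {
    singles <- do.call(rbind, lapply(net$nodes, screen_one))
    ord <- order(-singles$m_control, singles$kd)
    ranked <- singles$kd[ord]
    stars <- unique(c(head(ranked, 5), tail(ranked, 5)))
    pair_sets <- if (length(stars) >= 2)
      combn(sort(stars), 2, simplify = FALSE) else list()
    pairs <- if (length(pair_sets))
      do.call(rbind, lapply(pair_sets, screen_one)) else NULL
    out <- rbind(singles, pairs)
  } else {
    out <- do.call(rbind, lapply(kd_sets, screen_one))
  }
  rownames(out) <- NULL
  out
}

#' Rank single knockdowns as state destabilizers
#'
#' Orders single-knockdown results by descending control-state proportion:
#' the head of the list destabilizes the case state (models moved toward
#' control), the tail destabilizes the control state.
#'
#' @param screen Data frame from [kd_screen()].
#' @return The single-KD rows, ordered, with a `rank` column.
#' @export
rank_destabilizers <- function(screen) {
  singles <- screen[screen$n_genes == 1, , drop = FALSE]
  singles <- singles[order(-singles$m_control, singles$kd), , drop = FALSE]
  singles$rank <- seq_len(nrow(singles))
  rownames(singles) <- NULL
  singles
}

#' Project perturbed ensembles into the unperturbed PCA space
#'
#' Principal components are fitted on the unperturbed profile matrix only;
#' perturbed profiles are projected with the same centering and loadings.
#'
#' @param unperturbed_matrix Models x genes matrix.
#' @param perturbed_matrices Named list of models x genes matrices sharing
#'   the gene set.
#' @param n_pcs Number of components to keep (default 2).
#' @return List with `unperturbed` scores, `perturbed` score list,
#'   `rotation`, `center`, and `explained_variance`.
#' @export
project_pca <- function(unperturbed_matrix, perturbed_matrices = list(),
                        n_pcs = 2) {
  if (ncol(unperturbed_matrix) < 2) stop("need at least 2 genes for PCA")
  pc <- prcomp(unperturbed_matrix, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  proj <- function(m) {
    sweep(m[, rownames(rot), drop = FALSE], 2, pc$center) %*% rot
  }
  list(unperturbed = pc$x[, seq_len(n_pcs), drop = FALSE],
       perturbed = lapply(perturbed_matrices, proj),
       rotation = rot, center = pc$center,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2))
}
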