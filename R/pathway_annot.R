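## Pathway annotation of network TFs: Fisher's exact test on the overlap
## between each TF's differentially expressed regulon and each pathway.

#' Differentially expressed genes of a TF's regulon
#'
#' The regulon of a TF is the TF together with its target genes; this
#' returns its intersection with a set of differentially expressed genes.
#'
#' @param tf A TF present in `db`.
#' @param db A `tf_target_db`.
#' @param degs Character vector of differentially expressed genes.
#' @return Character vector.
#' @export
regulon_degs <- function(tf, db, degs) {
  if (!tf %in% db$tf) stop("TF absent from database: ", tf)
  intersect(union(tf, db_targets(db, tf)), degs)
}

#' Annotate TFs with their most representative pathway
#'
#' For each TF, a one-sided (enrichment) Fisher's exact test is run per
#' pathway on the 2 x 2 table of membership in the TF's regulon versus
#' membership in the pathway over the gene universe.  Each TF is annotated
#' with the smallest-p pathway provided `p <= p_max` (default 0.1), and is
#' otherwise unassigned.  P-value ties are broken by alphabetical pathway
#' name.
#'
#' @param regulons Named list: TF -> gene set (e.g. from
#'   [regulon_degs()]).
#' @param pathways Named list: pathway -> gene set.
#' @param universe Character vector of background genes; regulons and
#'   pathways are intersected with it.
#' @param p_max Annotation threshold (default 0.1).
#' @return Data frame (tf, pathway, p_value) with `pathway = NA` for
#'   unassigned TFs.
#' @export
fisher_annotate <- function(regulons, pathways, universe, p_max = 0.1) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  pathways <- lapply(pathways, intersect, universe)
  pw_names <- sort(names(pathways))
  rows <- lapply(names(regulons), function(tf) {
    reg <- intersect(regulons[[tf]], universe)
    best_p <- Inf
    best_pw <- NA_character_
    for (pw in pw_names) {
      set <- pathways[[pw]]
      a <- length(intersect(reg, set))
      b <- length(reg) - a
      c <- length(set) - a
      d <- length(universe) - a - b - c
      p <- fisher.test(matrix(c(a, b, c, d), 2), alternative = "greater")$p.value
      if (p < best_p) {
        best_p <- p
        best_pw <- pw
      }
    }
    data.frame(tf = tf,
               pathway = if (is.finite(best_p) && best_p <= p_max) best_pw
                         else NA_character_,
               p_value = if (is.finite(best_p)) best_p else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
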