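## Core domain types and flat-file readers/writers shared by all stages.
##
## Conventions:
##   * gene_network  - directed signed TF-TF graph (list: nodes, edges df)
##   * tf_target_db  - data.frame(tf, target, provenance, probability)
##   * expression_set- list(expr = genes x samples matrix, labels = factor)
##   * networks on disk: 5-column TSV with sign coded 1 = activation,
##     2 = inhibition (the usual GRN-simulator topology convention)

SIGN_LEVELS <- c("activation", "inhibition")

#' Construct a directed signed TF-TF network
#'
#' @param nodes Character vector of unique TF identifiers.
#' @param edges Data frame with columns `from`, `to`, `sign`
#'   (`"activation"`/`"inhibition"`), `provenance` (`"curated"`/`"atac"`),
#'   and `correlation` (the activity correlation that set the sign).
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node identifiers")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), provenance = character(),
                        correlation = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    need <- c("from", "to", "sign", "provenance", "correlation")
    if (!all(need %in% names(edges)))
      stop("edges must have columns: ", paste(need, collapse = ", "))
    edges <- edges[need]
    if (!all(edges$sign %in% SIGN_LEVELS))
      stop("edge sign must be 'activation' or 'inhibition'")
    if (!all(edges$from %in% nodes) || !all(edges$to %in% nodes))
      stop("every edge endpoint must be a node")
    if (anyDuplicated(edges[c("from", "to")]))
      stop("at most one edge per ordered (source, target) pair")
    bad <- (edges$sign == "activation" & edges$correlation < 0) |
      (edges$sign == "inhibition" & edges$correlation > 0)
    if (any(bad))
      stop("edge sign must agree with the sign of the stored correlation")
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d TFs, %d edges (%d activation, %d inhibition)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activation"),
              sum(x$edges$sign == "inhibition")))
  invisible(x)
}

#' Construct a TF-target database
#'
#' A flat table mapping each TF to its target genes, with per-target
#' provenance (`"curated"`, `"atac"`, or `"both"` after a merge) and an
#' optional binding probability.
#'
#' @param tf,target Character vectors (recycled to equal length).
#' @param provenance Provenance per row.
#' @param probability Optional binding probability in `[0, 1]` (`NA` for
#'   curated entries).
#' @return Object of class `tf_target_db` (a data.frame).
#' @export
tf_target_db <- function(tf = character(), target = character(),
                         provenance = "curated", probability = NA_real_) {
  n <- length(tf)
  df <- data.frame(tf = as.character(tf), target = as.character(target),
                   provenance = rep_len(as.character(provenance), n),
                   probability = rep_len(as.numeric(probability), n),
                   stringsAsFactors = FALSE)
  ok <- is.na(df$probability) | (df$probability >= 0 & df$probability <= 1)
  if (!all(ok)) stop("binding probabilities must lie in [0, 1]")
  if (anyDuplicated(df[c("tf", "target")]))
    stop("duplicate (tf, target) rows")
  class(df) <- c("tf_target_db", "data.frame")
  df
}

#' TFs present in a TF-target database
#' @param db A `tf_target_db`.
#' @return Character vector of TF identifiers.
#' @export
db_tfs <- function(db) unique(db$tf)

#' Target set of one TF
#' @param db A `tf_target_db`.
#' @param tf A TF identifier.
#' @return Character vector of target genes (empty if the TF is absent).
#' @export
db_targets <- function(db, tf) unique(db$target[db$tf == tf])

#' Convert a list of gene sets to a TF-target database
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param provenance Provenance label applied to all rows.
#' @return A `tf_target_db`.
#' @export
sets_to_db <- function(sets, provenance = "curated") {
  if (length(sets) == 0) return(tf_target_db())
  tf_target_db(tf = rep(names(sets), lengths(sets)),
               target = unlist(sets, use.names = FALSE),
               provenance = provenance)
}

#' Construct an expression set
#'
#' @param expr Numeric genes x samples matrix (log2 scale), with row and
#'   column names.
#' @param labels Character/factor vector (or named vector) assigning every
#'   sample to `"control"` or `"case"`.
#' @return Object of class `expression_set` with elements `expr` and
#'   `labels` (factor with levels control, case, in column order).
#' @export
expression_set <- function(expr, labels) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(expr), names(labels))
    if (length(missing))
      stop("samples missing from label file: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(expr)]
  } else if (length(labels) != ncol(expr)) {
    stop("labels must cover every sample")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("control", "case")))
    stop("labels must be 'control' or 'case'")
  labels <- factor(labels, levels = c("control", "case"))
  names(labels) <- colnames(expr)
  structure(list(expr = expr, labels = labels), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$labels == "control"), sum(x$labels == "case")))
  invisible(x)
}

#' Read an expression matrix with sample labels
#'
#' @param path Tab-delimited genes x samples table; first column holds gene
#'   identifiers, header holds sample names.
#' @param labels_path Two-column TSV (sample, label) with label
#'   `control`/`case`; no header required, but a `sample<TAB>label` header
#'   line is tolerated.
#' @return An [expression_set()].
#' @export
read_expression <- function(path, labels_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  mat <- as.matrix(tab[-1])
  if (!is.numeric(mat)) stop("non-numeric expression cell in ", path)
  rownames(mat) <- genes

  lab <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(lab[1, ])), c("sample", "label")))
    lab <- lab[-1, , drop = FALSE]
  labels <- setNames(as.character(lab[[2]]), as.character(lab[[1]]))
  extra <- setdiff(names(labels), colnames(mat))
  if (length(extra))
    stop("unknown sample in label file: ", paste(extra, collapse = ", "))
  expression_set(mat, labels)
}

#' Write an expression set to disk
#' @param x An `expression_set`.
#' @param path,labels_path Output TSV paths for the matrix and the labels.
#' @export
write_expression <- function(x, path, labels_path) {
  df <- data.frame(gene = rownames(x$expr), x$expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(x$labels),
                         label = as.character(x$labels)),
              labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name  description  member1  member2 ...`.  Lines with fewer than three
#' fields are an error; duplicated set names have their members unioned;
#' sets that end up empty are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, " in ", path, " (fewer than 3 fields)")
    name <- fields[[1]]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(trimws(members))]
    if (length(members) == 0) next
    sets[[name]] <- union(sets[[name]], members)
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "coregrn") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(sets)
}

#' Read a TF-gene binding probability table
#'
#' @param path Three-column TSV `tf  gene  probability` with header.
#' @return A `tf_target_db`-shaped table of class `binding_table`
#'   (data.frame with columns tf, gene, probability).
#' @export
read_binding_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("tf", "gene", "probability")
  binding_table(df$tf, df$gene, df$probability)
}

#' Construct a binding table
#' @param tf,gene Character vectors.
#' @param probability Numeric in `[0, 1]`.
#' @return Data frame of class `binding_table`.
#' @export
binding_table <- function(tf, gene, probability) {
  df <- data.frame(tf = as.character(tf), gene = as.character(gene),
                   probability = as.numeric(probability),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$probability)) ||
      any(df$probability < 0 | df$probability > 1))
    stop("binding probabilities must lie in [0, 1]")
  if (anyDuplicated(df[c("tf", "gene")]))
    stop("one row per (TF, gene) pair required")
  class(df) <- c("binding_table", "data.frame")
  df
}

#' Write a binding table
#' @param x A `binding_table`.
#' @param path Output TSV path.
#' @export
write_binding_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Write a network as a Cytoscape-importable edge list
#'
#' Five tab-separated columns: source, interaction (1 = activation,
#' 2 = inhibition), target, provenance, correlation.  Isolated nodes are
#' preserved in a `#nodes:` comment so that read/write round-trips.
#'
#' @param net A `gene_network`.
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes:", paste(net$nodes, collapse = ",")), con)
  writeLines("source\tinteraction\ttarget\tprovenance\tcorrelation", con)
  if (nrow(net$edges)) {
    code <- ifelse(net$edges$sign == "activation", 1L, 2L)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%.10g", net$edges$from, code,
                       net$edges$to, net$edges$provenance,
                       net$edges$correlation), con)
  }
  invisible(net)
}

#' Read a network edge list written by [write_network()]
#' @param path Path to the 5-column TSV.
#' @return A `gene_network`.
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  nodes <- character()
  if (length(lines) && startsWith(lines[[1]], "#nodes:")) {
    spec <- sub("^#nodes:", "", lines[[1]])
    if (nzchar(spec)) nodes <- strsplit(spec, ",", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_network(nodes))
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(gene_network(nodes))
  if (!all(df$interaction %in% c(1L, 2L)))
    stop("unknown sign code in ", path, " (expected 1 or 2)")
  edges <- data.frame(from = df$source, to = df$target,
                      sign = ifelse(df$interaction == 1L, "activation",
                                    "inhibition"),
                      provenance = df$provenance,
                      correlation = df$correlation, stringsAsFactors = FALSE)
  gene_network(union(nodes, union(edges$from, edges$to)), edges)
}
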