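# Interaction network of PTM^mut-harboring genes, patient-level
# co-occurrence of PTM^mut in interacting pairs, and the healthy-sample
# set-difference filter.

#' Build the interaction network of PTM^mut-harboring genes
#'
#' Induces the subgraph of the interaction edge list on the genes harboring
#' at least one PTM^mut. Self-edges are kept as homotypic interactions;
#' PTM^mut genes with no interaction among themselves are excluded.
#' \code{total_degree} counts a homotypic self-interaction once (it has one
#' biological partner), and \code{functional_flag} marks genes whose
#' PTM^mut overlap an annotated functional region.
#'
#' @param ptm_genes Gene symbols harboring PTM^mut.
#' @param interactions Edge list \code{data.frame} (\code{gene_a},
#'   \code{gene_b}), symmetric-deduplicated (see
#'   \code{\link{read_interactions}}).
#' @param functional_genes Optional gene symbols to flag.
#' @return An \code{\link[igraph]{igraph}} graph with vertex attributes
#'   \code{total_degree}, \code{homotypic} and \code{functional_flag}.
#' @export
build_network <- function(ptm_genes, interactions, functional_genes = NULL) {
  ga <- pmin(interactions$gene_a, interactions$gene_b)
  gb <- pmax(interactions$gene_a, interactions$gene_b)
  edges <- unique(data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE))
  keep <- edges$gene_a %in% ptm_genes & edges$gene_b %in% ptm_genes
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  has_loop <- vapply(igraph::V(g)$name, function(v) {
    any(edges$gene_a == v & edges$gene_b == v)
  }, logical(1))
  deg <- igraph::degree(g, loops = FALSE) + as.integer(has_loop)
  igraph::V(g)$total_degree <- unname(deg)
  igraph::V(g)$homotypic <- unname(has_loop)
  igraph::V(g)$functional_flag <- igraph::V(g)$name %in%
    (functional_genes %||% character())
  g
}

#' Export a PTM^mut network
#'
#' Writes the edge list as TSV and the attributed graph as GraphML.
#'
#' @param g Graph from \code{\link{build_network}}.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("gene_a", "gene_b")
  tsv <- file.path(dir, "network_edges.tsv")
  utils::write.table(el, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- file.path(dir, "network.graphml")
  igraph::write_graph(g, gml, format = "graphml")
  invisible(c(tsv, gml))
}

#' Patient-level co-occurrence of PTM^mut in interacting gene pairs
#'
#' One row per (sample, unordered interacting gene pair) in which the sample
#' carries at least one PTM^mut in each of the two genes. Heterodimeric
#' pairs only (self-interactions are ignored here).
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param interactions Edge list \code{data.frame}.
#' @return \code{data.frame} with \code{sample}, \code{gene_a},
#'   \code{gene_b}.
#' @export
patient_cooccurrence <- function(ann, interactions) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  sg <- unique(m[c("sample", "gene")])
  ga <- pmin(interactions$gene_a, interactions$gene_b)
  gb <- pmax(interactions$gene_a, interactions$gene_b)
  edges <- unique(data.frame(gene_a = ga, gene_b = gb,
                             stringsAsFactors = FALSE))
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  gene_samples <- split(sg$sample, sg$gene)
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    common <- intersect(gene_samples[[edges$gene_a[i]]] %||% character(),
                        gene_samples[[edges$gene_b[i]]] %||% character())
    if (length(common)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sort(common), gene_a = edges$gene_a[i],
        gene_b = edges$gene_b[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), gene_a = character(),
               gene_b = character(), stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' Chi-square test on co-occurrence frequencies
#'
#' Two-sided 2x2 chi-square comparing co-occurring vs non-co-occurring
#' counts between the matrisome and the rest of the genome (or any two
#' groups). Degenerate tables give \code{NA} with a warning.
#'
#' @param n_co_a,n_total_a Co-occurring and total counts in group A.
#' @param n_co_b,n_total_b Same for group B.
#' @param correct Yates continuity correction (default \code{FALSE}).
#' @return List with \code{p_value} and the 2x2 \code{table}.
#' @export
cooccurrence_test <- function(n_co_a, n_total_a, n_co_b, n_total_b,
                              correct = FALSE) {
  tab <- rbind(a = c(n_co_a, n_total_a - n_co_a),
               b = c(n_co_b, n_total_b - n_co_b))
  colnames(tab) <- c("co_occurring", "not_co_occurring")
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate co-occurrence table; p-value undefined", call. = FALSE)
    return(list(p_value = NA_real_, table = tab))
  }
  tst <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(p_value = tst$p.value, table = tab)
}

#' Remove PTM^mut observed in healthy samples
#'
#' Set-difference filter: drops every PTM^mut whose key -- by default
#' (gene, position), optionally including the reference/alternate residue or
#' allele -- appears in a normal-sample variant table.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param normals \code{data.frame} of normal-sample variants with at least
#'   the key columns (using \code{gene}, \code{position}, and optionally
#'   \code{alt}).
#' @param key Matching key: \code{c("gene", "position")} (default) or
#'   \code{c("gene", "position", "alt")}.
#' @return List with \code{retained} (PTM^mut rows absent from normals),
#'   \code{n_removed}, \code{n_retained}.
#' @export
healthy_filter <- function(ann, normals, key = c("gene", "position")) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  mk <- list(gene = m$gene, position = m$aa_start, alt = m$alt)
  if (nrow(normals) == 0) {
    return(list(retained = m, n_removed = 0L, n_retained = nrow(m)))
  }
  missing <- setdiff(key, names(normals))
  if (length(missing)) {
    stop_config("normal table lacks key column(s): %s",
                paste(missing, collapse = ", "))
  }
  mut_key <- do.call(paste, c(mk[key], sep = "\r"))
  norm_key <- do.call(paste, c(lapply(key, function(k) normals[[k]]),
                               sep = "\r"))
  keep <- !(mut_key %in% norm_key)
  list(retained = m[keep, , drop = FALSE],
       n_removed = sum(!keep), n_retained = sum(keep))
}
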