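# Per-gene dN/dS at PTM and non-PTM positions, the r_dNdS selection ratio,
# cross-cohort hotspot recurrence, and residue-composition tallies.
#
# dN/dS here is the raw ratio of non-silent to silent mutation counts at a
# set of residue positions -- a selection proxy, not an opportunity-normalized
# codon-model estimate. Silent mutations are assigned to the PTM/non-PTM
# position class by residue index.

# Partition a gene's mutations into PTM-site and non-PTM-site position
# classes. A mutation belongs to the PTM class if its start residue is an
# annotated PTM position of the gene's protein (any type, or the given type).
.position_class <- function(muts, sites, ptm_type = NULL) {
  if (!is.null(ptm_type)) {
    sites <- sites[sites$ptm_type %in% ptm_type, , drop = FALSE]
  }
  keys <- unique(paste(sites$protein_id, sites$position))
  paste(muts$protein_id, muts$aa_start) %in% keys
}

#' Raw dN/dS of one gene at PTM-site or non-PTM-site positions
#'
#' \code{(n_nonsilent + a) / (n_silent + a)} over mutations whose start
#' residue falls in the requested position class, with pseudocount
#' \code{a >= 0} (default 0.5) added to both counts. With \code{a = 0} and no
#' silent mutations the ratio is undefined (\code{NA}).
#'
#' @param muts Mutation table including silent records.
#' @param sites PTM site table.
#' @param gene Gene symbol.
#' @param position_class \code{"ptm_site"} or \code{"non_ptm_site"}.
#' @param pseudocount Non-negative pseudocount \code{a}.
#' @param ptm_type Optional PTM type restriction for the site set.
#' @return Single numeric ratio (or \code{NA}).
#' @export
gene_dnds <- function(muts, sites, gene,
                      position_class = c("ptm_site", "non_ptm_site"),
                      pseudocount = 0.5, ptm_type = NULL) {
  position_class <- match.arg(position_class)
  g <- muts[muts$gene == gene, , drop = FALSE]
  at_ptm <- .position_class(g, sites, ptm_type)
  sel <- if (position_class == "ptm_site") at_ptm else !at_ptm
  n_non <- sum(sel & g$effect != "silent")
  n_sil <- sum(sel & g$effect == "silent")
  if (n_sil + pseudocount == 0) return(NA_real_)
  (n_non + pseudocount) / (n_sil + pseudocount)
}

#' Per-gene r_dNdS records
#'
#' For every gene with annotated PTM sites, computes dN/dS at PTM positions
#' and at non-PTM positions and their ratio
#' \code{r_dnds = dnds_ptm / dnds_nonptm}. Values below 1 indicate stronger
#' purifying selection against PTM-site disruption than against the rest of
#' the protein. Records whose required denominators vanish (with
#' \code{pseudocount = 0}) carry \code{NA}.
#'
#' @param muts Mutation table including silent records.
#' @param sites PTM site table.
#' @param catalog Gene catalog (defines the gene/protein mapping).
#' @param pseudocount Pseudocount added to all four counts (default 0.5; set
#'   0 to disable).
#' @param ptm_type Optional PTM type restriction.
#' @return \code{data.frame} with one row per gene: the four raw counts,
#'   \code{dnds_ptm}, \code{dnds_nonptm}, \code{r_dnds}.
#' @export
compute_rdnds <- function(muts, sites, catalog, pseudocount = 0.5,
                          ptm_type = NULL) {
  genes <- catalog$gene_symbol[catalog$protein_id %in% unique(sites$protein_id)]
  if (!is.null(ptm_type)) {
    keep <- unique(sites$protein_id[sites$ptm_type %in% ptm_type])
    genes <- catalog$gene_symbol[catalog$protein_id %in% keep]
  }
  at_ptm <- .position_class(muts, sites, ptm_type)
  silent <- muts$effect == "silent"
  gf <- factor(muts$gene, levels = genes)
  cnt <- function(mask) as.integer(table(gf[mask]))
  out <- data.frame(
    gene_symbol = genes,
    n_nonsilent_ptm = cnt(at_ptm & !silent),
    n_silent_ptm = cnt(at_ptm & silent),
    n_nonsilent_nonptm = cnt(!at_ptm & !silent),
    n_silent_nonptm = cnt(!at_ptm & silent),
    stringsAsFactors = FALSE
  )
  a <- pseudocount
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out$dnds_ptm <- safe_ratio(out$n_nonsilent_ptm + a, out$n_silent_ptm + a)
  out$dnds_nonptm <- safe_ratio(out$n_nonsilent_nonptm + a,
                                out$n_silent_nonptm + a)
  out$r_dnds <- ifelse(!is.na(out$dnds_ptm) & !is.na(out$dnds_nonptm) &
                         out$dnds_nonptm > 0,
                       out$dnds_ptm / out$dnds_nonptm, NA_real_)
  out
}

#' Summarize r_dNdS over genes
#'
#' The geometric mean (default) is the natural location summary for a ratio
#' statistic: r_dNdS is a ratio of two count ratios, its sampling
#' distribution is right-skewed at realistic per-gene counts, and the
#' arithmetic mean of such ratios is inflated by the reciprocal of small
#' silent counts. On the log scale a neutral cohort centres on 0.
#'
#' @param records A \code{\link{compute_rdnds}} table.
#' @param type \code{"geometric"} or \code{"arithmetic"}.
#' @return Single numeric summary over genes with defined positive r_dNdS.
#' @export
mean_rdnds <- function(records, type = c("geometric", "arithmetic")) {
  type <- match.arg(type)
  r <- records$r_dnds[!is.na(records$r_dnds) & records$r_dnds > 0]
  if (!length(r)) return(NA_real_)
  if (type == "geometric") exp(mean(log(r))) else mean(r)
}

#' Compare r_dNdS between two gene sets
#'
#' Two-sided Mann-Whitney U test on the defined r_dNdS values of the two
#' sets (exact for small samples, as implemented by
#' \code{\link[stats]{wilcox.test}}).
#'
#' @param records A \code{\link{compute_rdnds}} table.
#' @param set_a,set_b Gene-symbol vectors (e.g. matrisome vs rest).
#' @return List with \code{p_value}, \code{median_a}, \code{median_b},
#'   \code{n_a}, \code{n_b}.
#' @export
compare_rdnds <- function(records, set_a, set_b) {
  ra <- records$r_dnds[records$gene_symbol %in% set_a & !is.na(records$r_dnds)]
  rb <- records$r_dnds[records$gene_symbol %in% set_b & !is.na(records$r_dnds)]
  if (length(ra) < 2 || length(rb) < 2) {
    warning("fewer than 2 defined r_dNdS values in a set; comparison skipped",
            call. = FALSE)
    return(list(p_value = NA_real_, median_a = stats::median(ra),
                median_b = stats::median(rb),
                n_a = length(ra), n_b = length(rb)))
  }
  wt <- suppressWarnings(stats::wilcox.test(ra, rb, alternative = "two.sided"))
  list(p_value = wt$p.value, median_a = stats::median(ra),
       median_b = stats::median(rb), n_a = length(ra), n_b = length(rb))
}

#' Cross-cohort PTM^mut hotspots
#'
#' Groups PTM^mut site hits by (gene, position, PTM type) -- or by
#' (gene, position) when \code{match_type = FALSE} -- and keeps groups seen
#' in at least \code{min_cohorts} distinct tumor cohorts. A lysine carrying
#' two PTM types recurrently therefore yields two records at one position.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param min_cohorts Minimum number of distinct cohorts (default 3).
#' @param match_type Require matching PTM type in the group key.
#' @return \code{data.frame} sorted by \code{n_cohorts} (desc) then gene:
#'   \code{gene_symbol}, \code{position}, \code{ptm_type}, \code{n_cohorts},
#'   \code{cohorts} (comma-joined), \code{n_samples}.
#' @export
find_hotspots <- function(ann, min_cohorts = 3, match_type = TRUE) {
  h <- ann$hits
  key_cols <- if (match_type) c("gene", "position", "ptm_type") else
    c("gene", "position")
  if (!nrow(h)) {
    return(data.frame(gene_symbol = character(), position = integer(),
                      ptm_type = character(), n_cohorts = integer(),
                      cohorts = character(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- do.call(paste, c(h[key_cols], sep = "\r"))
  agg <- lapply(split(seq_len(nrow(h)), key), function(ix) {
    co <- sort(unique(h$cancer[ix]))
    data.frame(gene_symbol = h$gene[ix[1]],
               position = h$position[ix[1]],
               ptm_type = if (match_type) h$ptm_type[ix[1]] else NA_character_,
               n_cohorts = length(co),
               cohorts = paste(co, collapse = ","),
               n_samples = length(unique(h$sample[ix])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[out$n_cohorts >= min_cohorts, , drop = FALSE]
  out <- out[order(-out$n_cohorts, out$gene_symbol, out$position,
                   out$ptm_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue composition of PTM^mut reference residues
#'
#' Tallies the reference amino acid of distinct PTM^mut records across the
#' 20 standard residues plus an \code{"unknown"} bucket; percentages sum to
#' 100 over the non-empty table.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @return \code{data.frame} with \code{residue}, \code{n}, \code{pct}
#'   (rows with \code{n > 0} only); empty input gives an empty table.
#' @export
residue_composition <- function(ann) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(residue = character(), n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- ifelse(is.na(m$ref_aa) | !(m$ref_aa %in% amino_acids()),
                "unknown", m$ref_aa)
  tab <- table(factor(res, levels = c(amino_acids(), "unknown")))
  out <- data.frame(residue = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n > 0, , drop = FALSE]
  out$pct <- 100 * out$n / sum(out$n)
  out <- out[order(-out$n, out$residue), ]
  rownames(out) <- NULL
  out
}
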