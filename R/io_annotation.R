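# Readers for the tabular inputs and the core classification step: effect
# class, transition/transversion, and PTM^mut calling by overlap of residue
# footprints with annotated PTM sites.
#
# TSV dialect: tab-separated, UTF-8, header row, "." for missing values.

.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = ".", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_config("missing required column(s) in %s: %s", basename(path),
                paste(missing, collapse = ", "))
  }
  df
}

.drop_rows <- function(df, bad, what) {
  if (any(bad)) {
    warning(sprintf("dropped %d %s row(s) violating invariants",
                    sum(bad), what), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a protein-coordinate somatic mutation table
#'
#' Expects the package's MAF-like TSV schema: \code{sample}, \code{cancer},
#' \code{gene}, \code{protein_id}, \code{aa_start}, \code{aa_end},
#' \code{effect}, \code{variant_kind}, \code{ref}, \code{alt}, \code{ref_aa},
#' \code{sift}, \code{polyphen}. Rows violating the record invariants
#' (\code{aa_end < aa_start}, non-positive positions, unknown effect or
#' variant kind, SNPs without two distinct single bases) are dropped with a
#' warning stating the count. A stable \code{mut_id} is assigned.
#'
#' @param path Path to a TSV file.
#' @return Validated mutation \code{data.frame}.
#' @export
read_mutations <- function(path) {
  req <- c("sample", "cancer", "gene", "protein_id", "aa_start", "aa_end",
           "effect", "variant_kind", "ref", "alt", "ref_aa", "sift", "polyphen")
  df <- .read_tsv(path, req)[, req]
  df$aa_start <- suppressWarnings(as.integer(df$aa_start))
  df$aa_end <- suppressWarnings(as.integer(df$aa_end))
  snp <- !is.na(df$variant_kind) & df$variant_kind == "SNP"
  bad <- is.na(df$aa_start) | is.na(df$aa_end) |
    df$aa_start < 1 | df$aa_end < df$aa_start |
    !(df$effect %in% mutation_effects()) |
    !(df$variant_kind %in% c("SNP", "INS", "DEL")) |
    (snp & (is.na(df$ref) | is.na(df$alt) |
              nchar(df$ref) != 1 | nchar(df$alt) != 1 |
              df$ref == df$alt |
              !(df$ref %in% c("A", "C", "G", "T")) |
              !(df$alt %in% c("A", "C", "G", "T"))))
  df <- .drop_rows(df, bad, "mutation")
  df$mut_id <- seq_len(nrow(df))
  df
}

#' Read a PTM site table
#'
#' Columns \code{protein_id}, \code{position}, \code{ptm_type},
#' \code{residue}; duplicated (protein, position, type) rows are collapsed to
#' one, rows with invalid positions or unknown PTM types dropped with a
#' warning.
#'
#' @param path Path to a TSV file.
#' @return Validated site \code{data.frame}.
#' @export
read_ptm_sites <- function(path) {
  df <- .read_tsv(path, c("protein_id", "position", "ptm_type", "residue"))
  df$position <- suppressWarnings(as.integer(df$position))
  bad <- is.na(df$position) | df$position < 1 | !(df$ptm_type %in% ptm_types())
  df <- .drop_rows(df, bad, "PTM site")
  df[!duplicated(df[c("protein_id", "position", "ptm_type")]), , drop = FALSE]
}

#' Read a gene/protein catalog
#'
#' Enforces the catalog invariants: unique gene symbols; \code{division} is
#' \code{"none"} iff the gene is non-matrisome; category consistent with
#' division; \code{gene_length >= 3 * protein_length}.
#'
#' @param path Path to a TSV file.
#' @return Validated catalog \code{data.frame}.
#' @export
read_catalog <- function(path) {
  req <- c("gene_symbol", "protein_id", "gene_length", "protein_length",
           "is_matrisome", "division", "category")
  df <- .read_tsv(path, req)
  df$gene_length <- suppressWarnings(as.integer(df$gene_length))
  df$protein_length <- suppressWarnings(as.integer(df$protein_length))
  df$is_matrisome <- as.logical(df$is_matrisome)
  div_map <- matrisome_categories()
  bad <- is.na(df$gene_length) | is.na(df$protein_length) |
    df$protein_length < 1 | df$gene_length < 3 * df$protein_length |
    duplicated(df$gene_symbol) |
    (df$is_matrisome != (df$division != "none")) |
    ifelse(df$category == "none", df$division != "none",
           unname(div_map[df$category]) != df$division)
  .drop_rows(df, bad | is.na(bad), "catalog")
}

#' Read domain / region interval tables
#'
#' Intervals are 1-based, inclusive on both ends; degenerate rows
#' (\code{end < start}, non-positive coordinates) are dropped with a warning.
#'
#' @param path Path to a TSV file.
#' @return Validated interval \code{data.frame}.
#' @export
read_domains <- function(path) {
  df <- .read_tsv(path, c("protein_id", "domain_id", "start", "end"))
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start
  .drop_rows(df, bad, "domain")
}

#' @rdname read_domains
#' @export
read_regions <- function(path) {
  df <- .read_tsv(path, c("protein_id", "start", "end", "region_function"))
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1 | df$end < df$start
  .drop_rows(df, bad, "region")
}

#' Read an interaction edge list
#'
#' Two columns \code{gene_a}, \code{gene_b}; edges are undirected and
#' deduplicated after sorting endpoints. Self-edges are kept (homotypic
#' interactions).
#'
#' @param path Path to a TSV file.
#' @return Deduplicated edge \code{data.frame}.
#' @export
read_interactions <- function(path) {
  df <- .read_tsv(path, c("gene_a", "gene_b"))
  ga <- pmin(df$gene_a, df$gene_b)
  gb <- pmax(df$gene_a, df$gene_b)
  out <- unique(data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Classify transitions and transversions
#'
#' A SNP is a transition if it swaps purines (A<->G) or pyrimidines (C<->T),
#' a transversion otherwise; indels are \code{"not_applicable"}.
#'
#' @param ref,alt Single-base allele vectors.
#' @param variant_kind \code{"SNP"}, \code{"INS"} or \code{"DEL"}.
#' @return Character vector over \{transition, transversion, not_applicable\}.
#' @export
classify_titv <- function(ref, alt, variant_kind) {
  out <- rep("not_applicable", length(ref))
  snp <- variant_kind == "SNP" & !is.na(ref) & !is.na(alt)
  pur <- c("A", "G")
  ti <- snp & ((ref %in% pur) == (alt %in% pur))
  out[snp] <- "transversion"
  out[ti] <- "transition"
  out
}

# Residue footprint of a mutation record. SNVs, nonsense, frameshift and
# splice-site mutations occupy the single reported start residue (downstream
# truncation is deliberately NOT counted as PTM disruption); in-frame indels
# span [aa_start, aa_end].
mutation_footprint <- function(muts) {
  fe <- ifelse(muts$effect == "inframe_indel", muts$aa_end, muts$aa_start)
  data.frame(fs = muts$aa_start, fe = fe)
}

#' Call PTM-disrupting mutations
#'
#' A non-silent mutation is a PTM^mut iff its residue footprint (inclusive,
#' 1-based; see Details) contains at least one annotated PTM position of the
#' same protein. Every overlapped (position, PTM type) pair is recorded, so a
#' residue carrying two PTM types yields two hits but one PTM^mut. Silent
#' mutations are never PTM^mut. Mutations on proteins absent from the site
#' table are simply non-PTM^mut.
#'
#' @details The footprint is the single reported residue for SNVs and for
#' truncating (nonsense/frameshift) and splice-site records, and the full
#' \code{[aa_start, aa_end]} interval for in-frame indels. Counting the whole
#' lost tail of a truncation as "disrupted" would let truncations dominate
#' all tallies, so downstream loss is intentionally excluded.
#'
#' @param muts Mutation table (see \code{\link{read_mutations}}).
#' @param sites PTM site table (see \code{\link{read_ptm_sites}}).
#' @return Object of class \code{"ptm_annotation"}: a list with
#'   \code{$mutations} (the input plus \code{titv}, \code{is_ptm_mut},
#'   \code{n_ptm_hits}) and \code{$hits} (one row per overlapped
#'   (mutation, position, ptm_type) with the mutation's sample/cancer/gene
#'   columns joined in).
#' @export
call_ptm_mut <- function(muts, sites) {
  if (is.null(muts$mut_id)) muts$mut_id <- seq_len(nrow(muts))
  fp <- mutation_footprint(muts)
  width <- fp$fe - fp$fs + 1L

  # expand footprints to covered positions and key-join against sites
  idx <- rep(seq_len(nrow(muts)), width)
  pos <- as.integer(unlist(lapply(seq_len(nrow(muts)),
                                  function(i) seq.int(fp$fs[i], fp$fe[i])),
                           use.names = FALSE))
  cov <- data.frame(i = idx, protein_id = muts$protein_id[idx], position = pos,
                    stringsAsFactors = FALSE)
  cov <- cov[muts$effect[cov$i] != "silent", , drop = FALSE]
  hits <- merge(cov, sites[c("protein_id", "position", "ptm_type")],
                by = c("protein_id", "position"))
  hits <- data.frame(
    mut_id = muts$mut_id[hits$i],
    sample = muts$sample[hits$i],
    cancer = muts$cancer[hits$i],
    gene = muts$gene[hits$i],
    protein_id = hits$protein_id,
    position = hits$position,
    ptm_type = hits$ptm_type,
    stringsAsFactors = FALSE
  )
  hits <- unique(hits)
  hits <- hits[order(hits$mut_id, hits$position, hits$ptm_type), ]
  rownames(hits) <- NULL

  ann <- muts
  ann$titv <- classify_titv(muts$ref, muts$alt, muts$variant_kind)
  nh <- table(factor(hits$mut_id, levels = muts$mut_id))
  ann$n_ptm_hits <- as.integer(nh)
  ann$is_ptm_mut <- ann$n_ptm_hits > 0
  structure(list(mutations = ann, hits = hits), class = "ptm_annotation")
}

#' @export
print.ptm_annotation <- function(x, ...) {
  m <- x$mutations
  cat(sprintf(
    "PTM annotation: %d mutations (%d silent), %d PTM^mut (%d site hits)\n",
    nrow(m), sum(m$effect == "silent"), sum(m$is_ptm_mut), nrow(x$hits)))
  invisible(x)
}
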