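# Domain-level PTM^mut ratios, functional-region overlap, fixed-motif window
# scanning, and sequence-context extraction with residue-property profiles.

#' Adhesion and collagen-recognition motifs scanned by default
#'
#' GPP and GFPGER/GLPGER are collagen triple-helix and integrin/DDR
#' recognition motifs, RGD and LDV are integrin-binding motifs, GVD a
#' collagenase-cleavage context.
#'
#' @return Character vector of motif strings.
#' @export
default_motifs <- function() {
  c("GPP", "GVD", "RGD", "LDV", "GFPGER", "GLPGER")
}

# (mut_id, domain_id) pairs: a mutation counts once per domain even when it
# overlaps several instances of the same domain in one protein.
.mutation_domain_pairs <- function(muts, domains) {
  fp <- mutation_footprint(muts)
  rows <- list()
  for (pid in intersect(unique(muts$protein_id), unique(domains$protein_id))) {
    mi <- which(muts$protein_id == pid)
    di <- which(domains$protein_id == pid)
    for (j in di) {
      ov <- mi[fp$fs[mi] <= domains$end[j] & fp$fe[mi] >= domains$start[j]]
      if (length(ov)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mut_id = muts$mut_id[ov], domain_id = domains$domain_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mut_id = integer(), domain_id = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

#' Domain-specific PTM^mut ratios by gene set
#'
#' For every domain and each of the matrisome / rest gene sets, counts the
#' non-silent mutations whose footprint overlaps any instance of that domain
#' and splits them into PTM^mut and non-PTM^mut; the domain-specific ratio is
#' \code{n_ptm_mut / n_non_ptm_mut} (undefined when the denominator is 0).
#' Instances of one domain are pooled across all proteins of the gene set.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param domains Domain interval table.
#' @param catalog Gene catalog with \code{is_matrisome}.
#' @return \code{data.frame} with \code{domain_id}, \code{gene_set},
#'   \code{n_ptm_mut}, \code{n_non_ptm_mut}, \code{ratio}.
#' @export
domain_ratios <- function(ann, domains, catalog) {
  m <- ann$mutations[ann$mutations$effect != "silent", , drop = FALSE]
  pairs <- .mutation_domain_pairs(m, domains)
  m$gene_set <- ifelse(
    catalog$is_matrisome[match(m$protein_id, catalog$protein_id)],
    "matrisome", "rest")
  pairs$gene_set <- m$gene_set[match(pairs$mut_id, m$mut_id)]
  pairs$is_ptm <- m$is_ptm_mut[match(pairs$mut_id, m$mut_id)]

  grid <- expand.grid(domain_id = sort(unique(domains$domain_id)),
                      gene_set = c("matrisome", "rest"),
                      stringsAsFactors = FALSE)
  cnt <- function(mask) {
    if (!any(mask)) return(integer(nrow(grid)))
    t <- table(paste(pairs$domain_id[mask], pairs$gene_set[mask]))
    as.integer(t[match(paste(grid$domain_id, grid$gene_set), names(t))])
  }
  grid$n_ptm_mut <- cnt(pairs$is_ptm)
  grid$n_non_ptm_mut <- cnt(!pairs$is_ptm)
  grid$n_ptm_mut[is.na(grid$n_ptm_mut)] <- 0L
  grid$n_non_ptm_mut[is.na(grid$n_non_ptm_mut)] <- 0L
  grid$ratio <- ifelse(grid$n_non_ptm_mut > 0,
                       grid$n_ptm_mut / grid$n_non_ptm_mut, NA_real_)
  grid[order(grid$domain_id, grid$gene_set), ]
}

#' Differentially PTM^mut-enriched domains
#'
#' Domains whose PTM^mut ratio is at least \code{fold} times higher in the
#' matrisome than in the rest of the genome, or vice versa. Domains for
#' which either set's ratio is undefined are excluded from calling (they
#' remain in the \code{\link{domain_ratios}} table).
#'
#' @param records A \code{\link{domain_ratios}} table.
#' @param fold Fold threshold (default 2).
#' @return Character vector of differential domain ids.
#' @export
differential_domains <- function(records, fold = 2) {
  w <- stats::reshape(records[c("domain_id", "gene_set", "ratio")],
                      idvar = "domain_id", timevar = "gene_set",
                      direction = "wide")
  rm_ <- w$ratio.matrisome
  rr <- w$ratio.rest
  ok <- !is.na(rm_) & !is.na(rr) & rm_ != rr
  sort(w$domain_id[ok & (rm_ >= fold * rr | rr >= fold * rm_)])
}

#' Overlap of PTM^mut with annotated functional regions
#'
#' Flags each PTM^mut whose footprint overlaps at least one functional
#' region of its protein. Mutations on proteins with no region annotation at
#' all form a separate "no information" stratum and are excluded from the
#' denominator of the summary fraction.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param regions Region interval table with \code{region_function} labels.
#' @return List with \code{per_mutation} (\code{mut_id}, \code{stratum} in
#'   \{overlapping, non_overlapping, no_information\}), \code{n_annotated},
#'   \code{n_overlapping}, \code{n_no_information}, and \code{fraction}
#'   (percentage of annotated PTM^mut overlapping a region).
#' @export
region_overlap <- function(ann, regions) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  fp <- mutation_footprint(m)
  annotated_prot <- unique(regions$protein_id)
  stratum <- rep("no_information", nrow(m))
  has_info <- m$protein_id %in% annotated_prot
  stratum[has_info] <- "non_overlapping"
  for (pid in intersect(unique(m$protein_id), annotated_prot)) {
    mi <- which(m$protein_id == pid)
    ri <- which(regions$protein_id == pid)
    hit <- vapply(mi, function(i) {
      any(fp$fs[i] <= regions$end[ri] & fp$fe[i] >= regions$start[ri])
    }, logical(1))
    stratum[mi[hit]] <- "overlapping"
  }
  n_ann <- sum(has_info)
  n_ov <- sum(stratum == "overlapping")
  list(
    per_mutation = data.frame(mut_id = m$mut_id, stratum = stratum,
                              stringsAsFactors = FALSE),
    n_annotated = n_ann,
    n_overlapping = n_ov,
    n_no_information = sum(!has_info),
    fraction = if (n_ann > 0) 100 * n_ov / n_ann else NA_real_
  )
}

#' Scan fixed motifs around a mutated residue
#'
#' Finds every occurrence of the given motifs (exact, case-insensitive
#' string match, overlapping occurrences included) whose span intersects the
#' window \code{[position - window, position + window]}. \code{distance} is
#' the residue gap between the mutated position and the motif span (0 when
#' the position lies inside the motif).
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based mutated residue position (must lie in the
#'   sequence).
#' @param motifs Motif strings (default \code{\link{default_motifs}}).
#' @param window Residue window half-width (default 3); \code{window = 0}
#'   keeps only motifs containing the mutated residue.
#' @return \code{data.frame} with \code{motif}, \code{motif_start},
#'   \code{motif_end}, \code{distance}.
#' @export
motif_scan <- function(sequence, position, motifs = default_motifs(),
                       window = 3) {
  L <- nchar(sequence)
  if (position < 1 || position > L) {
    stop_config("position %d outside sequence of length %d", position, L)
  }
  sq <- toupper(sequence)
  lo <- position - window
  hi <- position + window
  rows <- list()
  for (mo in toupper(motifs)) {
    st <- gregexpr(paste0("(?=", mo, ")"), sq, perl = TRUE)[[1]]
    st <- st[st > 0]
    for (s in st) {
      e <- s + nchar(mo) - 1L
      if (s <= hi && e >= lo) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mo, motif_start = s, motif_end = e,
          distance = max(0L, s - position, position - e),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(motif = character(), motif_start = integer(),
                      motif_end = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$motif_start, out$motif), ]
}

#' Extract the sequence context around a mutated residue
#'
#' Returns the subsequence \code{[max(1, position - flank),
#' min(L, position + flank)]} and the 1-based offset of the mutated residue
#' within it; the window is clipped at the protein ends, so its length is at
#' most \code{2 * flank + 1}.
#'
#' @param sequence Amino-acid sequence string.
#' @param position 1-based mutated residue position.
#' @param flank Half-width in residues (default 10).
#' @return List with \code{context}, \code{offset}, \code{start}, \code{end}.
#' @export
extract_context <- function(sequence, position, flank = 10) {
  L <- nchar(sequence)
  if (position < 1 || position > L) {
    stop_config("position %d outside sequence of length %d", position, L)
  }
  st <- max(1L, position - flank)
  en <- min(L, position + flank)
  list(context = substr(sequence, st, en),
       offset = as.integer(position - st + 1L), start = st, end = en)
}

#' Physicochemical class of an amino acid
#'
#' Fixed partition of the 20 standard residues: polar (S, T, N, Q, Y, C),
#' hydrophobic (A, V, L, I, M, F, W), acidic (D, E), basic (K, R, H),
#' special (G, P). Anything else maps to \code{"unknown"}.
#'
#' @param aa Character vector of one-letter codes.
#' @return Character vector of property classes.
#' @export
residue_property <- function(aa) {
  map <- c(S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar",
           C = "polar",
           A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
           I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
           W = "hydrophobic",
           D = "acidic", E = "acidic",
           K = "basic", R = "basic", H = "basic",
           G = "special", P = "special")
  out <- unname(map[toupper(aa)])
  out[is.na(out)] <- "unknown"
  out
}

#' Residue-property profile of aligned sequence contexts
#'
#' Aligns a set of \code{\link{extract_context}} windows on their mutated
#' residue and tallies, for every relative offset in
#' \code{[-flank, +flank]}, the property-class frequencies of the residues
#' observed there. Percentages sum to 100 within each offset (over contexts
#' long enough to cover it).
#'
#' @param contexts Character vector of context subsequences.
#' @param offsets Integer vector: the mutated-residue offset within each
#'   context.
#' @param flank Half-width used for extraction (default 10).
#' @return Long \code{data.frame} with \code{offset}, \code{property},
#'   \code{n}, \code{pct}.
#' @export
context_property_profile <- function(contexts, offsets, flank = 10) {
  stopifnot(length(contexts) == length(offsets))
  props <- c("polar", "hydrophobic", "acidic", "basic", "special", "unknown")
  rows <- list()
  for (rel in -flank:flank) {
    pos <- offsets + rel
    ok <- pos >= 1 & pos <= nchar(contexts)
    if (!any(ok)) next
    aa <- substr(contexts[ok], pos[ok], pos[ok])
    t <- table(factor(residue_property(aa), levels = props))
    t <- t[t > 0]
    rows[[length(rows) + 1L]] <- data.frame(
      offset = rel, property = names(t), n = as.integer(t),
      pct = 100 * as.integer(t) / sum(t), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
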