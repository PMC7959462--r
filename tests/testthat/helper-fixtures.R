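# Shared fixtures and independent brute-force oracles.
#
# Every oracle here is a deliberately naive reimplementation (double/triple
# loops over rows) kept free of the package's vectorized code paths.

# A small simulated study, annotated.
small_study <- function(seed = 1, n_genes = 40, matrisome_fraction = 0.25,
                        n_cancers = 3, samples_per_cancer = 8,
                        mutation_rate = 15, ...) {
  cfg <- simulation_config(n_genes = n_genes,
                           matrisome_fraction = matrisome_fraction,
                           n_cancers = n_cancers,
                           samples_per_cancer = samples_per_cancer,
                           mutation_rate = mutation_rate, seed = seed, ...)
  st <- simulate_study(cfg)
  st$mutations$mut_id <- seq_len(nrow(st$mutations))
  st$ann <- call_ptm_mut(st$mutations, st$annotations$sites)
  st$config <- cfg
  st
}

# Hand-built mutation rows with sensible defaults.
make_muts <- function(protein_id, aa_start, aa_end = aa_start,
                      effect = "missense", variant_kind = "SNP",
                      sample = "S1", cancer = "CA01",
                      gene = sub("^P", "G", protein_id),
                      ref = "A", alt = "G", ref_aa = "S") {
  df <- data.frame(sample = sample, cancer = cancer, gene = gene,
                   protein_id = protein_id, aa_start = aa_start,
                   aa_end = aa_end, effect = effect,
                   variant_kind = variant_kind, ref = ref, alt = alt,
                   ref_aa = ref_aa, sift = "unknown", polyphen = "unknown",
                   stringsAsFactors = FALSE)
  df$mut_id <- seq_len(nrow(df))
  df
}

make_sites <- function(protein_id, position, ptm_type = "phosphorylation",
                       residue = "S") {
  data.frame(protein_id = protein_id, position = position,
             ptm_type = ptm_type, residue = residue, stringsAsFactors = FALSE)
}

# O(n*m) double loop over mutations x sites; footprint rules restated from
# first principles.
oracle_call_ptm_mut <- function(muts, sites) {
  hits <- list()
  is_ptm <- logical(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    if (muts$effect[i] == "silent") next
    fs <- muts$aa_start[i]
    fe <- if (muts$effect[i] == "inframe_indel") muts$aa_end[i] else fs
    for (j in seq_len(nrow(sites))) {
      if (sites$protein_id[j] == muts$protein_id[i] &&
          sites$position[j] >= fs && sites$position[j] <= fe) {
        is_ptm[i] <- TRUE
        hits[[length(hits) + 1L]] <- data.frame(
          mut_id = muts$mut_id[i], position = sites$position[j],
          ptm_type = sites$ptm_type[j], stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(mut_id = integer(), position = integer(),
               ptm_type = character())
  list(is_ptm_mut = is_ptm, hits = hits)
}

# Per-(protein, type, cancer) recount of distinct hit sites.
oracle_local_burdens <- function(ann, sites, cancers) {
  out <- list()
  combos <- unique(sites[c("protein_id", "ptm_type")])
  for (k in seq_len(nrow(combos))) {
    pid <- combos$protein_id[k]; tp <- combos$ptm_type[k]
    known <- unique(sites$position[sites$protein_id == pid &
                                     sites$ptm_type == tp])
    for (cc in cancers) {
      h <- ann$hits
      hit_pos <- unique(h$position[h$protein_id == pid & h$ptm_type == tp &
                                     h$cancer == cc])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = pid, ptm_type = tp, cancer = cc,
        n_sites_known = length(known), n_sites_hit = length(hit_pos),
        local_burden = 100 * length(hit_pos) / length(known),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$protein_id, df$ptm_type, df$cancer), ]
  rownames(df) <- NULL
  df
}

# Interval-overlap recount of domain-level counts.
oracle_domain_counts <- function(ann, domains, catalog) {
  m <- ann$mutations[ann$mutations$effect != "silent", , drop = FALSE]
  out <- list()
  for (dom in sort(unique(domains$domain_id))) {
    for (set in c("matrisome", "rest")) {
      n_ptm <- 0L; n_non <- 0L
      for (i in seq_len(nrow(m))) {
        mat <- catalog$is_matrisome[catalog$protein_id == m$protein_id[i]]
        if ((set == "matrisome") != mat) next
        fs <- m$aa_start[i]
        fe <- if (m$effect[i] == "inframe_indel") m$aa_end[i] else fs
        d <- domains[domains$domain_id == dom &
                       domains$protein_id == m$protein_id[i], , drop = FALSE]
        touched <- any(d$start <= fe & d$end >= fs)
        if (touched) {
          if (m$is_ptm_mut[i]) n_ptm <- n_ptm + 1L else n_non <- n_non + 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        domain_id = dom, gene_set = set, n_ptm_mut = n_ptm,
        n_non_ptm_mut = n_non, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Exhaustive substring scan.
oracle_motif_scan <- function(sequence, position, motifs, window) {
  sq <- toupper(sequence)
  rows <- list()
  for (mo in toupper(motifs)) {
    w <- nchar(mo)
    for (s in seq_len(nchar(sq) - w + 1)) {
      if (substr(sq, s, s + w - 1) == mo &&
          s <= position + window && (s + w - 1) >= position - window) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mo, motif_start = s, motif_end = s + w - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(motif = character(),
                                       motif_start = integer(),
                                       motif_end = integer()))
  df <- do.call(rbind, rows)
  df[order(df$motif_start, df$motif), ]
}

# Triple loop: samples x edges x membership.
oracle_cooccurrence <- function(ann, interactions) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  rows <- list()
  for (smp in sort(unique(m$sample))) {
    genes <- unique(m$gene[m$sample == smp])
    for (i in seq_len(nrow(interactions))) {
      a <- min(interactions$gene_a[i], interactions$gene_b[i])
      b <- max(interactions$gene_a[i], interactions$gene_b[i])
      if (a != b && a %in% genes && b %in% genes) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, gene_a = a, gene_b = b, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(sample = character(),
                                       gene_a = character(),
                                       gene_b = character()))
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$sample, df$gene_a, df$gene_b), ]
  rownames(df) <- NULL
  df
}

# Closed-form 2x2 chi-square (no continuity correction), 1 df.
oracle_chisq_p <- function(tab) {
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}
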