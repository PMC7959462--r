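# Synthetic cohort generator
#
# Emulates the full input bundle the analysis consumes: a gene/protein catalog
# split into matrisome divisions and categories, PTM sites with
# category-dependent type frequencies, protein sequences, domain and
# functional-region intervals, an interaction edge list, and tumor cohorts
# with per-site selection against PTM positions, a silent/non-silent mix,
# transition/transversion structure, and injected recurrent hotspots.

#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator into a validated list. Defaults encode
#' a desk-scale pan-cancer study: 200 genes of which ~5\% are matrisome
#' (mirroring the genome-wide matrisome proportion), 5 tumor cohorts of 50
#' samples, ~40 somatic mutations per sample, a somatic transition/transversion
#' ratio of 2, and 30\% silent calls.
#'
#' @param n_genes Number of genes (>= 10).
#' @param matrisome_fraction Fraction of genes belonging to the matrisome.
#' @param n_cancers Number of tumor cohorts.
#' @param samples_per_cancer Samples per cohort.
#' @param mutation_rate Expected somatic mutations per sample (Poisson mean).
#' @param ptm_selection_s Per-site selection coefficient in [0, 1]: the
#'   probability that a non-silent candidate mutation landing on an annotated
#'   PTM position is rejected and redrawn. 0 is neutral, 1 removes all
#'   non-injected PTM-site mutations.
#' @param selection_scope Either \code{"all"} (selection acts on every gene's
#'   PTM sites) or \code{"matrisome"} (selection acts on matrisome PTM sites
#'   only, the regime used for parameter-recovery checks).
#' @param silent_fraction Probability that a mutation is silent.
#' @param titv_ratio Transition/transversion ratio among SNVs; the transition
#'   probability is \code{titv_ratio / (titv_ratio + 1)}.
#' @param ptm_site_density Expected PTM sites per residue. The default 0.12 is
#'   a deliberately annotation-dense regime so that per-gene site and burden
#'   statistics are well conditioned at desk-scale cohort sizes.
#' @param ptm_type_profile Named list mapping each matrisome category (and
#'   \code{"none"} for the rest of the genome) to a probability profile over
#'   \code{\link{ptm_types}}. Hydroxylation is forced to zero outside the
#'   collagen category regardless of the profile supplied.
#' @param category_split Named numeric vector of proportions over the six
#'   matrisome categories; defaults to the composition of the human matrisome
#'   (collagens ~4\%, ECM glycoproteins ~19\%, proteoglycans ~3\%,
#'   ECM-affiliated ~17\%, ECM regulators ~23\%, secreted factors ~34\%).
#' @param effect_profile Probabilities over non-silent effect classes.
#' @param dual_site_rate Probability that a lysine PTM site carries a second
#'   lysine-directed PTM type at the same residue (emulating e.g. a lysine
#'   that is both sumoylated and ubiquitylated).
#' @param region_annotation_fraction Fraction of proteins carrying
#'   functional-region annotation (the rest form the "no information"
#'   stratum).
#' @param n_domain_pool Size of the shared pool of domain identifiers.
#' @param interaction_density Expected interaction edges per gene.
#' @param homotypic_rate Fraction of interaction edges that are self
#'   (homotypic) interactions.
#' @param hotspot_specs \code{data.frame} with columns \code{gene},
#'   \code{position}, \code{ptm_type}, \code{cancers} (comma-separated cohort
#'   codes); each spec is injected verbatim into one sample of every listed
#'   cohort, after selection filtering.
#' @param seed Integer root seed; all generator stages derive child seeds from
#'   it, so the same configuration always regenerates byte-identical fixtures.
#'
#' @return A validated list of class \code{"ptm_sim_config"}.
#' @export
simulation_config <- function(n_genes = 200L,
                              matrisome_fraction = 0.048,
                              n_cancers = 5L,
                              samples_per_cancer = 50L,
                              mutation_rate = 40,
                              ptm_selection_s = 0,
                              selection_scope = c("all", "matrisome"),
                              silent_fraction = 0.30,
                              titv_ratio = 2.0,
                              ptm_site_density = 0.12,
                              ptm_type_profile = default_ptm_type_profile(),
                              category_split = default_category_split(),
                              effect_profile = default_effect_profile(),
                              dual_site_rate = 0.02,
                              region_annotation_fraction = 0.6,
                              n_domain_pool = 30L,
                              interaction_density = 1.5,
                              homotypic_rate = 0.02,
                              hotspot_specs = NULL,
                              seed = 1L) {
  selection_scope <- match.arg(selection_scope)
  props <- c(matrisome_fraction = matrisome_fraction,
             silent_fraction = silent_fraction,
             ptm_selection_s = ptm_selection_s,
             ptm_site_density = ptm_site_density,
             dual_site_rate = dual_site_rate,
             region_annotation_fraction = region_annotation_fraction,
             homotypic_rate = homotypic_rate)
  bad <- props[!is.finite(props) | props < 0 | props > 1]
  if (length(bad)) {
    stop_config("proportions outside [0, 1]: %s",
                paste(names(bad), collapse = ", "))
  }
  if (n_genes < 10) stop_config("n_genes must be >= 10")
  if (titv_ratio <= 0) stop_config("titv_ratio must be positive")
  if (mutation_rate <= 0) stop_config("mutation_rate must be positive")
  if (!setequal(names(category_split), names(matrisome_categories()))) {
    stop_config("category_split must name all six matrisome categories")
  }
  for (nm in names(ptm_type_profile)) {
    prof <- ptm_type_profile[[nm]]
    if (!all(names(prof) %in% ptm_types()) || any(prof < 0)) {
      stop_config("invalid PTM type profile for category '%s'", nm)
    }
  }
  cancer_codes <- sprintf("CA%02d", seq_len(n_cancers))
  if (!is.null(hotspot_specs)) {
    hotspot_specs <- as.data.frame(hotspot_specs, stringsAsFactors = FALSE)
    need <- c("gene", "position", "ptm_type", "cancers")
    if (!all(need %in% names(hotspot_specs))) {
      stop_config("hotspot_specs needs columns %s", paste(need, collapse = ", "))
    }
    listed <- unlist(strsplit(hotspot_specs$cancers, ","))
    if (!all(trimws(listed) %in% cancer_codes)) {
      stop_config("hotspot_specs reference cohorts outside the configured %d",
                  n_cancers)
    }
  }
  structure(list(
    n_genes = as.integer(n_genes),
    matrisome_fraction = matrisome_fraction,
    n_cancers = as.integer(n_cancers),
    cancer_codes = cancer_codes,
    samples_per_cancer = as.integer(samples_per_cancer),
    mutation_rate = mutation_rate,
    ptm_selection_s = ptm_selection_s,
    selection_scope = selection_scope,
    silent_fraction = silent_fraction,
    titv_ratio = titv_ratio,
    ptm_site_density = ptm_site_density,
    ptm_type_profile = ptm_type_profile,
    category_split = category_split,
    effect_profile = effect_profile,
    dual_site_rate = dual_site_rate,
    region_annotation_fraction = region_annotation_fraction,
    n_domain_pool = as.integer(n_domain_pool),
    interaction_density = interaction_density,
    homotypic_rate = homotypic_rate,
    hotspot_specs = hotspot_specs,
    seed = as.integer(seed)
  ), class = "ptm_sim_config")
}

#' @rdname simulation_config
#' @export
default_category_split <- function() {
  # composition of the ~1000-gene human matrisome
  c(collagens = 44, ecm_glycoproteins = 195, proteoglycans = 35,
    ecm_affiliated = 171, ecm_regulators = 238, secreted_factors = 344) / 1027
}

#' @rdname simulation_config
#' @export
default_ptm_type_profile <- function() {
  list(
    collagens = c(hydroxylation = 0.50, phosphorylation = 0.15,
                  n_glycosylation = 0.08, o_glycosylation = 0.12,
                  acetylation = 0.04, ubiquitylation = 0.04,
                  sumoylation = 0.03, methylation = 0.04),
    ecm_glycoproteins = c(phosphorylation = 0.34, n_glycosylation = 0.22,
                          o_glycosylation = 0.14, sumoylation = 0.10,
                          ubiquitylation = 0.08, acetylation = 0.07,
                          methylation = 0.05),
    proteoglycans = c(o_glycosylation = 0.30, n_glycosylation = 0.18,
                      phosphorylation = 0.28, acetylation = 0.08,
                      ubiquitylation = 0.08, sumoylation = 0.04,
                      methylation = 0.04),
    ecm_affiliated = c(phosphorylation = 0.42, ubiquitylation = 0.15,
                       acetylation = 0.14, n_glycosylation = 0.10,
                       o_glycosylation = 0.06, sumoylation = 0.07,
                       methylation = 0.06),
    ecm_regulators = c(phosphorylation = 0.45, ubiquitylation = 0.16,
                       acetylation = 0.13, n_glycosylation = 0.10,
                       o_glycosylation = 0.05, sumoylation = 0.06,
                       methylation = 0.05),
    secreted_factors = c(phosphorylation = 0.48, ubiquitylation = 0.14,
                         acetylation = 0.12, n_glycosylation = 0.09,
                         o_glycosylation = 0.05, sumoylation = 0.07,
                         methylation = 0.05),
    none = c(phosphorylation = 0.52, ubiquitylation = 0.16,
             acetylation = 0.12, sumoylation = 0.07, methylation = 0.06,
             n_glycosylation = 0.04, o_glycosylation = 0.03)
  )
}

#' @rdname simulation_config
#' @export
default_effect_profile <- function() {
  c(missense = 0.82, nonsense = 0.08, frameshift = 0.05,
    splice_site = 0.03, inframe_indel = 0.02)
}

#' Generate a synthetic gene/protein catalog
#'
#' Creates \code{round(n_genes * matrisome_fraction)} matrisome genes whose
#' categories follow the configured split (largest-remainder allocation, so
#' the per-category counts are deterministic), plus non-matrisome filler
#' genes. Protein lengths are log-normal; gene length is the coding length
#' \code{3 * (protein_length + 1)} (includes the stop codon).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return \code{data.frame} with columns \code{gene_symbol},
#'   \code{protein_id}, \code{gene_length}, \code{protein_length},
#'   \code{is_matrisome}, \code{division}, \code{category}.
#' @export
generate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "ptm_sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  n <- config$n_genes
  n_mat <- round(n * config$matrisome_fraction)

  # largest-remainder apportionment of matrisome genes over categories
  split <- config$category_split / sum(config$category_split)
  quota <- split * n_mat
  counts <- floor(quota)
  rem <- n_mat - sum(counts)
  if (rem > 0) {
    counts[order(quota - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(quota - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  categories <- c(rep(names(counts), counts), rep("none", n - n_mat))

  protein_length <- pmin(pmax(round(stats::rlnorm(n, log(400), 0.45)), 50L), 5000L)
  div_map <- matrisome_categories()
  data.frame(
    gene_symbol = sprintf("G%04d", seq_len(n)),
    protein_id = sprintf("P%04d", seq_len(n)),
    gene_length = as.integer(3L * (protein_length + 1L)),
    protein_length = as.integer(protein_length),
    is_matrisome = categories != "none",
    division = ifelse(categories == "none", "none",
                      unname(div_map[categories])),
    category = categories,
    stringsAsFactors = FALSE
  )
}

# Draw n PTM types for one protein from its category profile; hydroxylation is
# only admissible for collagen-category proteins.
.draw_ptm_types <- function(n, category, profile_list) {
  prof <- profile_list[[category]] %||% profile_list[["none"]]
  full <- stats::setNames(numeric(length(ptm_types())), ptm_types())
  full[names(prof)] <- prof
  if (category != "collagens") full["hydroxylation"] <- 0
  full <- full / sum(full)
  sample(names(full), n, replace = TRUE, prob = full)
}

#' Generate annotations for a synthetic catalog
#'
#' Produces random protein sequences, PTM sites on chemically valid residues
#' (sequence positions are overwritten with a residue valid for the site's
#' type), domain and functional-region intervals, and an interaction edge
#' list. Hydroxylation sites are restricted to collagen-category proteins.
#' Any configured hotspot positions are guaranteed a PTM site of the
#' requested type.
#'
#' @param catalog Output of \code{\link{generate_gene_catalog}}.
#' @param config The same \code{\link{simulation_config}}.
#' @return Named list with elements \code{sites}, \code{domains},
#'   \code{regions}, \code{sequences} (named character vector), and
#'   \code{interactions}.
#' @export
generate_annotations <- function(catalog, config) {
  stopifnot(inherits(config, "ptm_sim_config"), nrow(catalog) > 0)
  set.seed(stage_seed(config$seed, 2L))
  valid <- ptm_valid_residues()
  aas <- amino_acids()

  seqs <- vapply(catalog$protein_length, function(L) {
    paste(sample(aas, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- catalog$protein_id

  site_rows <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    L <- catalog$protein_length[i]
    n_sites <- stats::rbinom(1, L, config$ptm_site_density)
    if (n_sites == 0) next
    pos <- sort(sample.int(L, n_sites))
    typ <- .draw_ptm_types(n_sites, catalog$category[i], config$ptm_type_profile)
    res <- vapply(typ, function(tp) {
      v <- valid[[tp]]
      if (length(v) == 1) v else sample(v, 1)
    }, character(1))
    # force valid residues into the sequence
    sq <- strsplit(seqs[i], "")[[1]]
    sq[pos] <- res
    seqs[i] <- paste(sq, collapse = "")
    df <- data.frame(protein_id = catalog$protein_id[i], position = pos,
                     ptm_type = typ, residue = res, stringsAsFactors = FALSE)
    # occasionally stack a second lysine-directed PTM on the same lysine
    k_idx <- which(res == "K")
    if (length(k_idx)) {
      extra <- k_idx[stats::runif(length(k_idx)) < config$dual_site_rate]
      if (length(extra)) {
        k_types <- c("acetylation", "ubiquitylation", "sumoylation", "methylation")
        add <- df[extra, , drop = FALSE]
        add$ptm_type <- vapply(df$ptm_type[extra], function(tp) {
          sample(setdiff(k_types, tp), 1)
        }, character(1))
        df <- rbind(df, add)
      }
    }
    site_rows[[i]] <- df
  }
  sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null, logical(1))])
  if (is.null(sites)) {
    sites <- data.frame(protein_id = character(), position = integer(),
                        ptm_type = character(), residue = character(),
                        stringsAsFactors = FALSE)
  }

  # guarantee hotspot sites exist (and carry a valid residue)
  if (!is.null(config$hotspot_specs)) {
    hs <- config$hotspot_specs
    for (j in seq_len(nrow(hs))) {
      ci <- match(hs$gene[j], catalog$gene_symbol)
      if (is.na(ci)) stop_config("hotspot gene '%s' not in catalog", hs$gene[j])
      pid <- catalog$protein_id[ci]
      pos <- as.integer(hs$position[j])
      if (pos > catalog$protein_length[ci]) {
        stop_config("hotspot position %d beyond protein length", pos)
      }
      tp <- hs$ptm_type[j]
      hit <- sites$protein_id == pid & sites$position == pos &
        sites$ptm_type == tp
      if (!any(hit)) {
        v <- valid[[tp]]
        res <- if (length(v) == 1) v else v[1]
        sq <- strsplit(seqs[pid], "")[[1]]
        sq[pos] <- res
        seqs[pid] <- paste(sq, collapse = "")
        # keep any pre-existing co-located sites chemically consistent
        sites$residue[sites$protein_id == pid & sites$position == pos] <- res
        sites <- rbind(sites, data.frame(protein_id = pid, position = pos,
                                         ptm_type = tp, residue = res,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  sites <- unique(sites)
  sites <- sites[order(sites$protein_id, sites$position, sites$ptm_type), ]
  rownames(sites) <- NULL

  # domains: shared pool of identifiers, per-protein instances
  pool <- sprintf("DOM%03d", seq_len(config$n_domain_pool))
  dom_rows <- lapply(seq_len(nrow(catalog)), function(i) {
    L <- catalog$protein_length[i]
    n_dom <- 1L + stats::rpois(1, 1)
    w <- pmin(sample(40:120, n_dom, replace = TRUE), L)
    st <- vapply(w, function(wi) sample.int(L - wi + 1L, 1), integer(1))
    data.frame(protein_id = catalog$protein_id[i],
               domain_id = sample(pool, n_dom, replace = TRUE),
               start = st, end = st + w - 1L, stringsAsFactors = FALSE)
  })
  domains <- do.call(rbind, dom_rows)

  # functional regions for a subset of proteins
  labels <- c("triple-helical region", "GAG attachment", "heparin-binding",
              "collagen-binding", "EGF-like", "binding site")
  has_reg <- stats::runif(nrow(catalog)) < config$region_annotation_fraction
  reg_rows <- lapply(which(has_reg), function(i) {
    L <- catalog$protein_length[i]
    n_reg <- sample(1:3, 1)
    w <- pmin(sample(20:80, n_reg, replace = TRUE), L)
    st <- vapply(w, function(wi) sample.int(L - wi + 1L, 1), integer(1))
    data.frame(protein_id = catalog$protein_id[i], start = st,
               end = st + w - 1L,
               region_function = sample(labels, n_reg, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  regions <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    data.frame(protein_id = character(), start = integer(), end = integer(),
               region_function = character(), stringsAsFactors = FALSE)

  # interaction edge list (undirected, deduplicated; a few homotypic loops)
  n_edges <- round(config$interaction_density * nrow(catalog))
  a <- sample(catalog$gene_symbol, n_edges, replace = TRUE)
  b <- sample(catalog$gene_symbol, n_edges, replace = TRUE)
  loop <- stats::runif(n_edges) < config$homotypic_rate
  b[!loop & a == b] <- sample(catalog$gene_symbol, sum(!loop & a == b),
                              replace = TRUE)
  keep <- loop | a != b
  ga <- pmin(a[keep], b[keep])
  gb <- pmax(a[keep], b[keep])
  interactions <- unique(data.frame(gene_a = ga, gene_b = gb,
                                    stringsAsFactors = FALSE))
  interactions <- interactions[order(interactions$gene_a, interactions$gene_b), ]
  rownames(interactions) <- NULL

  list(sites = sites, domains = domains, regions = regions,
       sequences = seqs, interactions = interactions)
}

# transition partner for each base
.transition_of <- c(A = "G", G = "A", C = "T", T = "C")
.transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))

#' Simulate a pan-cancer somatic mutation cohort
#'
#' Per sample, the mutation count is Poisson(\code{mutation_rate}); each
#' mutation picks a gene with probability proportional to gene length, a
#' uniform residue position, a silent flag, an effect class, and SNV alleles
#' with the configured transition probability. A non-silent candidate whose
#' residue footprint touches an annotated PTM position is rejected and
#' redrawn with probability \code{ptm_selection_s} (restricted to matrisome
#' genes when \code{selection_scope = "matrisome"}). Configured hotspots are
#' injected verbatim afterwards, so they survive any selection strength.
#'
#' @param catalog,annotations Outputs of the generator stages above.
#' @param config The same \code{\link{simulation_config}}.
#' @return Mutation \code{data.frame} in the package's tabular schema
#'   (\code{sample}, \code{cancer}, \code{gene}, \code{protein_id},
#'   \code{aa_start}, \code{aa_end}, \code{effect}, \code{variant_kind},
#'   \code{ref}, \code{alt}, \code{ref_aa}, \code{sift}, \code{polyphen}).
#' @export
simulate_cohort <- function(catalog, annotations, config) {
  stopifnot(inherits(config, "ptm_sim_config"))
  if (nrow(catalog) == 0) stop_config("empty catalog")
  set.seed(stage_seed(config$seed, 3L))

  samples <- data.frame(
    sample = sprintf("%s_S%03d",
                     rep(config$cancer_codes, each = config$samples_per_cancer),
                     rep(seq_len(config$samples_per_cancer), config$n_cancers)),
    cancer = rep(config$cancer_codes, each = config$samples_per_cancer),
    stringsAsFactors = FALSE
  )
  n_per_sample <- stats::rpois(nrow(samples), config$mutation_rate)
  n_total <- sum(n_per_sample)
  sample_idx <- rep(seq_len(nrow(samples)), n_per_sample)

  # PTM-position lookup (keyed protein:position), optionally matrisome-only
  sel_sites <- annotations$sites
  if (config$selection_scope == "matrisome") {
    mat_prot <- catalog$protein_id[catalog$is_matrisome]
    sel_sites <- sel_sites[sel_sites$protein_id %in% mat_prot, , drop = FALSE]
  }
  sel_keys <- unique(paste(sel_sites$protein_id, sel_sites$position))

  gene_prob <- catalog$gene_length / sum(catalog$gene_length)
  eff_prof <- config$effect_profile / sum(config$effect_profile)
  p_ti <- config$titv_ratio / (config$titv_ratio + 1)

  draw <- function(n) {
    gi <- sample.int(nrow(catalog), n, replace = TRUE, prob = gene_prob)
    L <- catalog$protein_length[gi]
    aa_start <- as.integer(floor(stats::runif(n) * L) + 1L)
    silent <- stats::runif(n) < config$silent_fraction
    effect <- ifelse(silent, "silent",
                     sample(names(eff_prof), n, replace = TRUE, prob = eff_prof))
    variant_kind <- rep("SNP", n)
    indel <- effect %in% c("frameshift", "inframe_indel")
    variant_kind[indel] <- sample(c("INS", "DEL"), sum(indel), replace = TRUE)
    aa_end <- aa_start
    span <- effect == "inframe_indel" & variant_kind == "DEL"
    aa_end[span] <- pmin(aa_start[span] + sample(0:2, sum(span), replace = TRUE),
                         L[span])
    ref <- rep(NA_character_, n); alt <- rep(NA_character_, n)
    snp <- variant_kind == "SNP"
    ref[snp] <- sample(c("A", "C", "G", "T"), sum(snp), replace = TRUE)
    ti <- stats::runif(n) < p_ti
    alt[snp & ti] <- .transition_of[ref[snp & ti]]
    tv_idx <- which(snp & !ti)
    alt[tv_idx] <- vapply(ref[tv_idx], function(b) {
      sample(.transversions_of[[b]], 1)
    }, character(1))
    data.frame(gene_idx = gi, aa_start = aa_start, aa_end = aa_end,
               effect = effect, variant_kind = variant_kind,
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  }

  hits_ptm <- function(d) {
    # footprint overlap with selected PTM positions (footprints span <= 3 aa)
    hit <- rep(FALSE, nrow(d))
    pid <- catalog$protein_id[d$gene_idx]
    for (off in 0:2) {
      p <- d$aa_start + off
      ok <- p <= d$aa_end
      hit[ok] <- hit[ok] | (paste(pid[ok], p[ok]) %in% sel_keys)
    }
    hit
  }

  muts <- draw(n_total)
  if (config$ptm_selection_s > 0 && length(sel_keys)) {
    # each freshly drawn candidate gets exactly one rejection trial; rejected
    # candidates are redrawn and re-tried until everyone has survived one trial
    fresh <- seq_len(n_total)
    while (length(fresh)) {
      sub <- muts[fresh, , drop = FALSE]
      cand <- fresh[sub$effect != "silent" & hits_ptm(sub)]
      reject <- cand[stats::runif(length(cand)) < config$ptm_selection_s]
      if (!length(reject)) break
      muts[reject, ] <- draw(length(reject))
      fresh <- reject
    }
  }

  seqs <- annotations$sequences
  out <- data.frame(
    sample = samples$sample[sample_idx],
    cancer = samples$cancer[sample_idx],
    gene = catalog$gene_symbol[muts$gene_idx],
    protein_id = catalog$protein_id[muts$gene_idx],
    aa_start = muts$aa_start,
    aa_end = muts$aa_end,
    effect = muts$effect,
    variant_kind = muts$variant_kind,
    ref = muts$ref,
    alt = muts$alt,
    ref_aa = substr(seqs[catalog$protein_id[muts$gene_idx]],
                    muts$aa_start, muts$aa_start),
    sift = sample(c("deleterious", "tolerated", "unknown"), n_total,
                  replace = TRUE, prob = c(0.25, 0.45, 0.30)),
    polyphen = sample(c("probably_damaging", "benign", "unknown"), n_total,
                      replace = TRUE, prob = c(0.25, 0.40, 0.35)),
    stringsAsFactors = FALSE
  )

  # hotspot injection (post-selection, one sample per listed cohort)
  if (!is.null(config$hotspot_specs)) {
    hs <- config$hotspot_specs
    inj <- list()
    for (j in seq_len(nrow(hs))) {
      ci <- match(hs$gene[j], catalog$gene_symbol)
      pid <- catalog$protein_id[ci]
      pos <- as.integer(hs$position[j])
      for (cc in trimws(strsplit(hs$cancers[j], ",")[[1]])) {
        smp <- samples$sample[samples$cancer == cc][1]
        inj[[length(inj) + 1L]] <- data.frame(
          sample = smp, cancer = cc, gene = hs$gene[j], protein_id = pid,
          aa_start = pos, aa_end = pos, effect = "missense",
          variant_kind = "SNP", ref = "A", alt = "G",
          ref_aa = substr(seqs[pid], pos, pos),
          sift = "deleterious", polyphen = "probably_damaging",
          stringsAsFactors = FALSE)
      }
    }
    out <- rbind(out, do.call(rbind, inj))
  }
  out <- out[order(out$cancer, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Run the whole generator in one call
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{catalog}, \code{annotations}, \code{mutations}.
#' @export
simulate_study <- function(config) {
  catalog <- generate_gene_catalog(config)
  annotations <- generate_annotations(catalog, config)
  mutations <- simulate_cohort(catalog, annotations, config)
  list(catalog = catalog, annotations = annotations, mutations = mutations)
}

#' Write a simulated fixture bundle to disk
#'
#' Emits the TSV/FASTA files the readers in this package consume:
#' \code{mutations.tsv}, \code{ptm_sites.tsv}, \code{gene_catalog.tsv},
#' \code{domains.tsv}, \code{regions.tsv}, \code{interactions.tsv} and
#' \code{proteins.fasta}. Missing values are written as \code{"."}. Given the
#' same study object the files are byte-identical across runs.
#'
#' @param study Output of \code{\link{simulate_study}}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    df[] <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- "."
      x
    })
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.path(dir, file)
  }
  paths <- c(
    wt(study$mutations, "mutations.tsv"),
    wt(study$annotations$sites, "ptm_sites.tsv"),
    wt(study$catalog, "gene_catalog.tsv"),
    wt(study$annotations$domains, "domains.tsv"),
    wt(study$annotations$regions, "regions.tsv"),
    wt(study$annotations$interactions, "interactions.tsv")
  )
  fa <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(study$annotations$sequences), fa)
  invisible(c(paths, fa))
}
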