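# The PTM^mut burden measure and its comparisons.
#
# The local burden of a (protein, PTM type, cancer) cell is the percentage of
# that protein's known sites of that type hit by at least one PTM^mut in that
# cohort; local burdens are averaged over (protein, cancer) cells to give a
# per-type global burden for a gene set, and gene sets are compared by fold
# change, a 100-random-gene-set chi-square control, and per-family
# burden/count correlations.

#' Percentage share of a count
#'
#' @param numerator,denominator Non-negative counts; \code{denominator > 0}.
#' @return \code{100 * numerator / denominator}.
#' @export
share_ratio <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop_config("share_ratio: denominator must be > 0")
  100 * numerator / denominator
}

#' Local PTM^mut burdens
#'
#' For every (protein, PTM type) with at least one annotated site and every
#' cancer cohort present in the annotation, counts the number of distinct
#' site positions of that type hit by PTM^mut in that cohort (recurrent hits
#' on one site count once) and expresses it as a percentage of the known
#' sites. Proteins with no sites of a type are absent, not zero; cells with
#' sites but no hits are present with burden 0.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param sites The PTM site table used for the annotation.
#' @param cancers Optional cohort codes; defaults to those observed in the
#'   mutation table.
#' @return \code{data.frame} with columns \code{protein_id}, \code{ptm_type},
#'   \code{cancer}, \code{n_sites_known}, \code{n_sites_hit},
#'   \code{local_burden}.
#' @export
local_burdens <- function(ann, sites, cancers = NULL) {
  cancers <- cancers %||% sort(unique(ann$mutations$cancer))
  known <- stats::aggregate(position ~ protein_id + ptm_type, data = sites,
                            FUN = function(p) length(unique(p)))
  names(known)[3] <- "n_sites_known"

  grid <- merge(known, data.frame(cancer = cancers, stringsAsFactors = FALSE))
  h <- unique(ann$hits[c("protein_id", "ptm_type", "cancer", "position")])
  if (nrow(h)) {
    hit <- stats::aggregate(position ~ protein_id + ptm_type + cancer,
                            data = h, FUN = length)
    names(hit)[4] <- "n_sites_hit"
    grid <- merge(grid, hit, by = c("protein_id", "ptm_type", "cancer"),
                  all.x = TRUE)
  } else {
    grid$n_sites_hit <- 0L
  }
  grid$n_sites_hit[is.na(grid$n_sites_hit)] <- 0L
  grid$local_burden <- 100 * grid$n_sites_hit / grid$n_sites_known
  grid <- grid[order(grid$protein_id, grid$ptm_type, grid$cancer), ]
  rownames(grid) <- NULL
  grid
}

#' Global burdens and matrisome-vs-rest folds
#'
#' Averages local burdens over all (protein, cancer) cells of each gene set,
#' per PTM type (unweighted mean-of-means; \code{method = "pooled"} instead
#' divides summed distinct hits by summed known sites). The fold of a set
#' against the \code{"rest"} set is \code{global / global_rest - 1}; folds
#' against a zero rest burden are reported as \code{NA}.
#'
#' @param bt A \code{\link{local_burdens}} table.
#' @param gene_sets Named list of protein-id vectors; must contain
#'   \code{"rest"} for folds to be computed.
#' @param method \code{"mean"} (default) or \code{"pooled"}.
#' @return \code{data.frame} with \code{gene_set}, \code{ptm_type},
#'   \code{global_burden}, \code{fold_vs_rest}.
#' @export
global_burden <- function(bt, gene_sets, method = c("mean", "pooled")) {
  method <- match.arg(method)
  rows <- list()
  for (set_name in names(gene_sets)) {
    sub <- bt[bt$protein_id %in% gene_sets[[set_name]], , drop = FALSE]
    if (!nrow(sub)) next
    gb <- if (method == "mean") {
      stats::aggregate(local_burden ~ ptm_type, data = sub, FUN = mean)
    } else {
      agg <- stats::aggregate(cbind(n_sites_hit, n_sites_known) ~ ptm_type,
                              data = sub, FUN = sum)
      data.frame(ptm_type = agg$ptm_type,
                 local_burden = 100 * agg$n_sites_hit / agg$n_sites_known)
    }
    names(gb)[2] <- "global_burden"
    gb$gene_set <- set_name
    rows[[set_name]] <- gb
  }
  out <- do.call(rbind, rows)
  out <- out[c("gene_set", "ptm_type", "global_burden")]
  rest <- out[out$gene_set == "rest", c("ptm_type", "global_burden")]
  names(rest)[2] <- ".rest"
  out <- merge(out, rest, by = "ptm_type", all.x = TRUE)
  out$fold_vs_rest <- ifelse(!is.na(out$.rest) & out$.rest > 0,
                             out$global_burden / out$.rest - 1, NA_real_)
  out$fold_vs_rest[out$gene_set == "rest"] <- 0
  out$.rest <- NULL
  out <- out[order(out$gene_set, out$ptm_type), c("gene_set", "ptm_type",
                                                  "global_burden", "fold_vs_rest")]
  rownames(out) <- NULL
  out
}

# per-gene PTM^mut / non-PTM^mut (non-silent) counts
.gene_class_counts <- function(ann) {
  m <- ann$mutations
  ns <- m[m$effect != "silent", , drop = FALSE]
  data.frame(
    gene = sort(unique(ns$gene)),
    n_ptm = as.integer(table(factor(ns$gene[ns$is_ptm_mut],
                                    levels = sort(unique(ns$gene))))),
    n_non_ptm = as.integer(table(factor(ns$gene[!ns$is_ptm_mut],
                                        levels = sort(unique(ns$gene))))),
    stringsAsFactors = FALSE
  )
}

#' Random gene-set control for the matrisome PTM^mut excess/deficit
#'
#' Draws \code{n_draws} random gene sets of the matrisome's size from the
#' non-matrisome pool (without replacement, seeded) and compares the
#' matrisome's PTM^mut / non-PTM^mut (non-silent) count split against each
#' draw with a two-sided 2x2 chi-square test (no continuity correction by
#' default). Draws with any expected cell below 1 are flagged and excluded
#' from the min/max summary.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param catalog Gene catalog with \code{is_matrisome}.
#' @param n_draws Number of random sets (default 100).
#' @param set_size Genes per draw; defaults to the matrisome size.
#' @param seed Integer seed for the draws.
#' @param correct Apply Yates continuity correction (default \code{FALSE}).
#' @return List with \code{draws} (data.frame of p-values and flags),
#'   \code{p_min}, \code{p_max}, and the matrisome counts used.
#' @export
random_set_control <- function(ann, catalog, n_draws = 100, set_size = NULL,
                               seed = 1L, correct = FALSE) {
  counts <- .gene_class_counts(ann)
  mat_genes <- catalog$gene_symbol[catalog$is_matrisome]
  pool <- catalog$gene_symbol[!catalog$is_matrisome]
  set_size <- set_size %||% length(mat_genes)
  if (length(pool) < set_size) {
    stop_config("non-matrisome pool (%d) smaller than set size (%d)",
                length(pool), set_size)
  }
  mat <- colSums(counts[counts$gene %in% mat_genes, c("n_ptm", "n_non_ptm")])
  set.seed(as.integer(seed))
  p <- numeric(n_draws)
  flagged <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    drawn <- sample(pool, set_size)
    dr <- colSums(counts[counts$gene %in% drawn, c("n_ptm", "n_non_ptm")])
    tab <- rbind(matrisome = mat, random = dr)
    if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      p[d] <- NA_real_; flagged[d] <- TRUE; next
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    tst <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    p[d] <- tst$p.value
    flagged[d] <- any(expd < 1)
  }
  ok <- !flagged & !is.na(p)
  list(draws = data.frame(draw = seq_len(n_draws), p_value = p,
                          flagged = flagged),
       p_min = if (any(ok)) min(p[ok]) else NA_real_,
       p_max = if (any(ok)) max(p[ok]) else NA_real_,
       matrisome_counts = mat)
}

#' Per-family correlation between burden and PTM^mut count
#'
#' For each matrisome category, correlates (Pearson) the per-cancer mean
#' local burden of the category's proteins with the per-cancer count of
#' PTM^mut in the category. Families with fewer than 3 cohorts or a constant
#' vector are reported with \code{NA}.
#'
#' @param bt A \code{\link{local_burdens}} table.
#' @param ann The matching \code{\link{call_ptm_mut}} annotation.
#' @param catalog Gene catalog with \code{category}.
#' @return \code{data.frame} with \code{category}, \code{n_points}, \code{r},
#'   \code{p_value}.
#' @export
family_burden_correlation <- function(bt, ann, catalog) {
  cats <- setdiff(unique(catalog$category[catalog$is_matrisome]), "none")
  m <- ann$mutations
  rows <- lapply(sort(cats), function(cat) {
    prot <- catalog$protein_id[catalog$category == cat]
    genes <- catalog$gene_symbol[catalog$category == cat]
    sub <- bt[bt$protein_id %in% prot, , drop = FALSE]
    cancers <- sort(unique(sub$cancer))
    x <- vapply(cancers, function(cc) {
      mean(sub$local_burden[sub$cancer == cc])
    }, numeric(1))
    y <- vapply(cancers, function(cc) {
      sum(m$is_ptm_mut & m$cancer == cc & m$gene %in% genes)
    }, numeric(1))
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(category = cat, n_points = length(x),
                        r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(category = cat, n_points = length(x),
               r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean length-normalized mutation rate over a gene set
#'
#' Mean over genes of (mutation count of the requested class) / gene length.
#' Genes in the subset with zero mutations contribute 0.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param catalog Gene catalog with \code{gene_length}.
#' @param genes Gene symbols defining the subset.
#' @param mut_class One of \code{"ptm"} (PTM^mut), \code{"non_ptm"}
#'   (non-silent non-PTM^mut), \code{"nonsilent"}, \code{"silent"}.
#' @return Single numeric mean rate (mutations per coding base).
#' @export
length_normalized_rate <- function(ann, catalog, genes,
                                   mut_class = c("ptm", "non_ptm",
                                                 "nonsilent", "silent")) {
  mut_class <- match.arg(mut_class)
  m <- ann$mutations
  keep <- switch(mut_class,
                 ptm = m$is_ptm_mut,
                 non_ptm = m$effect != "silent" & !m$is_ptm_mut,
                 nonsilent = m$effect != "silent",
                 silent = m$effect == "silent")
  sub <- catalog[catalog$gene_symbol %in% genes, , drop = FALSE]
  if (any(sub$gene_length <= 0)) stop_config("non-positive gene length")
  cnt <- table(factor(m$gene[keep], levels = sub$gene_symbol))
  mean(as.integer(cnt) / sub$gene_length)
}
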