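# One-call orchestration of the full analysis: annotate -> burden ->
# selection -> context -> network, with every table written to disk and a
# summary.json carrying headline counts and a reproducibility block.

#' Validate a pipeline run configuration
#'
#' A run configuration is a list (or YAML file) with either a
#' \code{simulate} block (arguments to \code{\link{simulation_config}}) or
#' an \code{inputs} block of file paths (\code{mutations}, \code{sites},
#' \code{catalog}, \code{domains}, \code{regions}, \code{sequences},
#' \code{interactions}, optional \code{normals}), plus optional
#' \code{thresholds} overriding the analysis defaults
#' (\code{min_cohorts = 3}, \code{domain_fold = 2}, \code{motif_window = 3},
#' \code{context_flank = 10}, \code{alpha = 0.05},
#' \code{n_random_draws = 100}, \code{dnds_pseudocount = 0.5}) and a root
#' \code{seed}.
#'
#' @param config List or path to a YAML file.
#' @return The validated configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  if (is.null(config$simulate) && is.null(config$inputs$mutations)) {
    stop_config("config error: need a 'simulate' block or 'inputs$mutations'")
  }
  th <- list(min_cohorts = 3, domain_fold = 2, motif_window = 3,
             context_flank = 10, alpha = 0.05, n_random_draws = 100,
             dnds_pseudocount = 0.5)
  for (nm in names(config$thresholds)) th[[nm]] <- config$thresholds[[nm]]
  if (any(unlist(th[c("min_cohorts", "domain_fold", "motif_window",
                      "context_flank", "n_random_draws")]) <= 0)) {
    stop_config("config error: thresholds must be positive")
  }
  if (th$alpha <= 0 || th$alpha >= 1) stop_config("config error: alpha in (0,1)")
  config$thresholds <- th
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

.write_tsv_out <- function(df, path) {
  df[] <- lapply(df, function(x) {
    x <- as.character(x); x[is.na(x)] <- "."; x
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full PTM^mut analysis pipeline
#'
#' Executes annotation, burden, selection, sequence-context and network
#' stages on either simulated or file-based inputs, writes every module's
#' output tables under \code{outdir}, and emits \code{summary.json} with
#' headline counts (which satisfy the partition identities
#' silent + PTM^mut + other non-silent = total, and matrisome + rest PTM^mut
#' = total PTM^mut) plus a reproducibility block (seed, versions, config
#' hash). A failure in any stage aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config A \code{\link{run_config}} list or YAML path.
#' @param outdir Output directory.
#' @return Invisibly, a list with all in-memory results and the summary.
#' @export
run_pipeline <- function(config, outdir) {
  config <- run_config(config)
  th <- config$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)

  stage <- "load"
  res <- list()
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop_config("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  dat <- run_stage("load", {
    if (!is.null(config$simulate)) {
      sim_cfg <- do.call(simulation_config,
                         c(config$simulate,
                           if (is.null(config$simulate$seed))
                             list(seed = config$seed)))
      study <- simulate_study(sim_cfg)
      list(mutations = {
        m <- study$mutations; m$mut_id <- seq_len(nrow(m)); m
      },
      sites = study$annotations$sites,
      catalog = study$catalog,
      domains = study$annotations$domains,
      regions = study$annotations$regions,
      sequences = study$annotations$sequences,
      interactions = study$annotations$interactions,
      normals = NULL)
    } else {
      ip <- config$inputs
      list(mutations = read_mutations(ip$mutations),
           sites = read_ptm_sites(ip$sites),
           catalog = read_catalog(ip$catalog),
           domains = read_domains(ip$domains),
           regions = read_regions(ip$regions),
           sequences = if (!is.null(ip$sequences)) read_sequences(ip$sequences),
           interactions = read_interactions(ip$interactions),
           normals = if (!is.null(ip$normals))
             utils::read.delim(ip$normals, na.strings = "."))
    }
  })
  catalog <- dat$catalog
  mat_genes <- catalog$gene_symbol[catalog$is_matrisome]
  mat_prot <- catalog$protein_id[catalog$is_matrisome]
  rest_prot <- catalog$protein_id[!catalog$is_matrisome]

  ann <- run_stage("annotate", call_ptm_mut(dat$mutations, dat$sites))
  .write_tsv_out(ann$mutations, file.path(outdir, "annotated_mutations.tsv"))
  .write_tsv_out(ann$hits, file.path(outdir, "ptm_hits.tsv"))
  res$annotation <- ann

  res$burden <- run_stage("burden", {
    bt <- local_burdens(ann, dat$sites)
    gb <- global_burden(bt, list(matrisome = mat_prot, rest = rest_prot))
    rc <- random_set_control(ann, catalog, n_draws = th$n_random_draws,
                             seed = stage_seed(config$seed, 4L))
    fc <- family_burden_correlation(bt, ann, catalog)
    .write_tsv_out(bt, file.path(outdir, "burden_local.tsv"))
    .write_tsv_out(gb, file.path(outdir, "burden_global.tsv"))
    .write_tsv_out(rc$draws, file.path(outdir, "random_control.tsv"))
    .write_tsv_out(fc, file.path(outdir, "family_correlation.tsv"))
    list(local = bt, global = gb, random_control = rc, family = fc)
  })

  res$selection <- run_stage("selection", {
    rd <- compute_rdnds(dat$mutations, dat$sites, catalog,
                        pseudocount = th$dnds_pseudocount)
    cmp <- compare_rdnds(rd, mat_genes, setdiff(catalog$gene_symbol, mat_genes))
    hs <- find_hotspots(ann, min_cohorts = th$min_cohorts)
    rcmp <- residue_composition(ann)
    .write_tsv_out(rd, file.path(outdir, "rdnds.tsv"))
    .write_tsv_out(hs, file.path(outdir, "hotspots.tsv"))
    .write_tsv_out(rcmp, file.path(outdir, "residue_composition.tsv"))
    list(rdnds = rd, comparison = cmp, hotspots = hs,
         residue_composition = rcmp)
  })

  res$context <- run_stage("context", {
    dr <- domain_ratios(ann, dat$domains, catalog)
    dd <- differential_domains(dr, fold = th$domain_fold)
    ro <- region_overlap(ann, dat$regions)
    .write_tsv_out(dr, file.path(outdir, "domain_ratios.tsv"))
    writeLines(dd, file.path(outdir, "differential_domains.txt"))
    .write_tsv_out(ro$per_mutation, file.path(outdir, "region_overlap.tsv"))
    mh <- NULL; profile <- NULL
    if (!is.null(dat$sequences)) {
      pm <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
      hits <- lapply(seq_len(nrow(pm)), function(i) {
        sq <- dat$sequences[[pm$protein_id[i]]]
        if (is.null(sq)) return(NULL)
        h <- motif_scan(sq, pm$aa_start[i], window = th$motif_window)
        if (nrow(h)) cbind(mut_id = pm$mut_id[i], gene = pm$gene[i], h)
      })
      mh <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
      if (is.null(mh)) {
        mh <- data.frame(mut_id = integer(), gene = character(),
                         motif = character(), motif_start = integer(),
                         motif_end = integer(), distance = integer())
      }
      ctx <- lapply(seq_len(nrow(pm)), function(i) {
        sq <- dat$sequences[[pm$protein_id[i]]]
        if (is.null(sq)) return(NULL)
        extract_context(sq, pm$aa_start[i], flank = th$context_flank)
      })
      ctx <- ctx[!vapply(ctx, is.null, logical(1))]
      profile <- context_property_profile(
        vapply(ctx, `[[`, character(1), "context"),
        vapply(ctx, `[[`, integer(1), "offset"),
        flank = th$context_flank)
      .write_tsv_out(mh, file.path(outdir, "motif_hits.tsv"))
      .write_tsv_out(profile, file.path(outdir, "context_profile.tsv"))
    }
    list(domain_ratios = dr, differential = dd, region_overlap = ro,
         motif_hits = mh, context_profile = profile)
  })

  res$network <- run_stage("network", {
    m <- ann$mutations
    ptm_genes <- unique(m$gene[m$is_ptm_mut])
    ro <- res$context$region_overlap
    func_ids <- ro$per_mutation$mut_id[ro$per_mutation$stratum == "overlapping"]
    func_genes <- unique(m$gene[m$mut_id %in% func_ids])
    g <- build_network(ptm_genes, dat$interactions, func_genes)
    write_network(g, outdir)
    co <- patient_cooccurrence(ann, dat$interactions)
    .write_tsv_out(co, file.path(outdir, "patient_cooccurrence.tsv"))
    healthy <- if (!is.null(dat$normals)) healthy_filter(ann, dat$normals)
    list(graph = g, cooccurrence = co, healthy = healthy)
  })

  res$top_genes <- run_stage("report", {
    tg <- top_genes_table(ann, k = 10)
    .write_tsv_out(tg, file.path(outdir, "top_genes.tsv"))
    tg
  })

  m <- ann$mutations
  counts <- list(
    total_mutations = nrow(m),
    silent = sum(m$effect == "silent"),
    nonsilent = sum(m$effect != "silent"),
    ptm_mut_total = sum(m$is_ptm_mut),
    non_ptm_nonsilent = sum(m$effect != "silent" & !m$is_ptm_mut),
    matrisome_nonsilent = sum(m$effect != "silent" & m$gene %in% mat_genes),
    matrisome_ptm_mut = sum(m$is_ptm_mut & m$gene %in% mat_genes),
    rest_ptm_mut = sum(m$is_ptm_mut & !(m$gene %in% mat_genes))
  )
  gbm <- res$burden$global
  summary <- list(
    counts = counts,
    shares = list(
      matrisome_share_pct = share_ratio(counts$matrisome_nonsilent,
                                        counts$nonsilent),
      ptm_mut_share_pct = share_ratio(counts$ptm_mut_total, counts$nonsilent),
      matrisome_ptm_ratio_pct = if (counts$matrisome_nonsilent > 0)
        share_ratio(counts$matrisome_ptm_mut, counts$matrisome_nonsilent)
      else NA,
      rest_ptm_ratio_pct = share_ratio(
        counts$rest_ptm_mut, counts$nonsilent - counts$matrisome_nonsilent)
    ),
    burden_folds = stats::setNames(
      as.list(gbm$fold_vs_rest[gbm$gene_set == "matrisome"]),
      gbm$ptm_type[gbm$gene_set == "matrisome"]),
    random_control = list(p_min = res$burden$random_control$p_min,
                          p_max = res$burden$random_control$p_max),
    rdnds_comparison_p = res$selection$comparison$p_value,
    n_hotspots = nrow(res$selection$hotspots),
    n_differential_domains = length(res$context$differential),
    region_overlap_pct = res$context$region_overlap$fraction,
    reproducibility = list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("ptmburden")),
      r_version = as.character(getRversion()),
      config_hash = unname(tools::md5sum(cfg_path))
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  res$summary <- summary
  invisible(res)
}

#' Top PTM^mut target genes per tumor cohort
#'
#' Ranks genes within each cohort by their PTM^mut count (ties broken
#' alphabetically) and keeps the top \code{k}.
#'
#' @param ann A \code{\link{call_ptm_mut}} annotation.
#' @param k Rows per cohort (default 10).
#' @return \code{data.frame} with \code{cancer}, \code{rank}, \code{gene},
#'   \code{n_ptm_mut}.
#' @export
top_genes_table <- function(ann, k = 10) {
  m <- ann$mutations[ann$mutations$is_ptm_mut, , drop = FALSE]
  rows <- lapply(sort(unique(m$cancer)), function(cc) {
    t <- table(m$gene[m$cancer == cc])
    df <- data.frame(cancer = cc, gene = names(t), n_ptm_mut = as.integer(t),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_ptm_mut, df$gene), , drop = FALSE]
    df <- utils::head(df, k)
    df$rank <- seq_len(nrow(df))
    df
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(cancer = character(), rank = integer(),
                      gene = character(), n_ptm_mut = integer()))
  }
  rownames(out) <- NULL
  out[c("cancer", "rank", "gene", "n_ptm_mut")]
}
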