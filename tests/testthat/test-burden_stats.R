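test_that("share_ratio reproduces plain percentage arithmetic", {
  expect_equal(round(share_ratio(151088, 2277979), 1), 6.6)
  expect_equal(round(share_ratio(42733, 2277979), 2), 1.88)
  expect_equal(share_ratio(0, 10), 0)
  expect_error(share_ratio(1, 0), "denominator")
})

test_that("local burdens count distinct hit sites per protein, type, cancer", {
  # 10 N-glycosylation sites, 2 distinct sites hit (one of them twice)
  sites <- make_sites("P0001", seq(10, 100, by = 10), "n_glycosylation", "N")
  muts <- make_muts("P0001", c(10, 10, 20, 33),
                    sample = c("S1", "S2", "S1", "S1"))
  ann <- call_ptm_mut(muts, sites)
  bt <- local_burdens(ann, sites)
  expect_equal(nrow(bt), 1)
  expect_equal(bt$n_sites_known, 10)
  expect_equal(bt$n_sites_hit, 2)
  expect_equal(bt$local_burden, 20)

  # zero-hit (protein, type) cells are present with burden 0
  sites2 <- rbind(sites, make_sites("P0002", 5))
  ann2 <- call_ptm_mut(muts, sites2)
  bt2 <- local_burdens(ann2, sites2)
  zero <- bt2[bt2$protein_id == "P0002", ]
  expect_equal(nrow(zero), 1)
  expect_equal(zero$local_burden, 0)
})

test_that("burdens are invariant to duplicated mutation records", {
  st <- small_study(seed = 31)
  bt1 <- local_burdens(st$ann, st$annotations$sites)
  dup <- rbind(st$mutations, st$mutations)
  dup$mut_id <- seq_len(nrow(dup))
  bt2 <- local_burdens(call_ptm_mut(dup, st$annotations$sites),
                       st$annotations$sites)
  expect_equal(bt1, bt2)
})

test_that("local burdens match the brute-force per-protein recount", {
  st <- small_study(seed = 37, n_genes = 25, mutation_rate = 12)
  bt <- local_burdens(st$ann, st$annotations$sites)
  ora <- oracle_local_burdens(st$ann, st$annotations$sites,
                              sort(unique(st$mutations$cancer)))
  expect_equal(bt, ora)
})

test_that("global burden folds compare gene sets against the rest", {
  bt <- data.frame(
    protein_id = c("PA", "PA", "PB", "PB"),
    ptm_type = "phosphorylation",
    cancer = c("CA01", "CA02", "CA01", "CA02"),
    n_sites_known = 10L, n_sites_hit = c(1L, 2L, 0L, 1L),
    local_burden = c(10, 20, 0, 10))
  # identical sets: fold 0
  gb <- global_burden(bt, list(matrisome = c("PA", "PB"),
                               rest = c("PA", "PB")))
  expect_equal(gb$fold_vs_rest, c(0, 0))

  # means 0.85 vs 0.10 give fold 7.5
  bt2 <- bt
  bt2$local_burden <- c(0.85, 0.85, 0.10, 0.10)
  gb2 <- global_burden(bt2, list(matrisome = "PA", rest = "PB"))
  expect_equal(gb2$fold_vs_rest[gb2$gene_set == "matrisome"], 7.5)

  # zero rest burden: fold reported missing
  bt3 <- bt
  bt3$local_burden <- c(5, 5, 0, 0)
  gb3 <- global_burden(bt3, list(matrisome = "PA", rest = "PB"))
  expect_true(is.na(gb3$fold_vs_rest[gb3$gene_set == "matrisome"]))

  # singleton-set global equals the mean of that protein's local burdens
  gb4 <- global_burden(bt, list(only = "PA", rest = "PB"))
  expect_equal(gb4$global_burden[gb4$gene_set == "only"], 15)
})

test_that("the random-set chi-square control behaves at both extremes", {
  # no signal: matrisome and every draw have identical per-gene counts
  cat_df <- data.frame(gene_symbol = paste0("G", 1:20),
                       protein_id = paste0("P", 1:20),
                       gene_length = 300L, protein_length = 90L,
                       is_matrisome = rep(c(TRUE, FALSE), each = 10),
                       division = rep(c("core_matrisome", "none"), each = 10),
                       category = rep(c("collagens", "none"), each = 10))
  sites <- make_sites(paste0("P", 1:20), 10)
  muts <- make_muts(paste0("P", rep(1:20, each = 4)),
                    rep(c(10, 20, 21, 22), 20),
                    gene = paste0("G", rep(1:20, each = 4)),
                    sample = "S1")
  ann <- call_ptm_mut(muts, sites)
  rc <- random_set_control(ann, cat_df, n_draws = 20, set_size = 10, seed = 1)
  expect_true(all(rc$draws$p_value == 1))

  # hand-checkable 2x2 without continuity correction
  tab <- rbind(c(10, 90), c(20, 80))
  expect_equal(oracle_chisq_p(tab),
               suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value)
})

test_that("random-set control flags selection against matrisome PTM sites", {
  cfg <- simulation_config(n_genes = 100, matrisome_fraction = 0.1,
                           n_cancers = 2, samples_per_cancer = 40,
                           mutation_rate = 40, ptm_selection_s = 0.9,
                           selection_scope = "matrisome", seed = 41)
  st <- simulate_study(cfg)
  st$mutations$mut_id <- seq_len(nrow(st$mutations))
  ann <- call_ptm_mut(st$mutations, st$annotations$sites)
  rc <- random_set_control(ann, st$catalog, n_draws = 100, seed = 2)
  # interval must exclude 0.5: strong depression of matrisome PTM^mut
  expect_lt(rc$p_max, 0.5)
  # and agree with an independently computed chi-square on one draw
  counts <- rc$matrisome_counts
  expect_true(all(counts >= 0))
})

test_that("family burden correlation recovers exact linear relations", {
  # perfectly anti-correlated synthetic points across 4 cancers
  cat_df <- data.frame(gene_symbol = "G1", protein_id = "PA",
                       gene_length = 300L, protein_length = 90L,
                       is_matrisome = TRUE, division = "core_matrisome",
                       category = "collagens")
  bt <- data.frame(protein_id = "PA", ptm_type = "phosphorylation",
                   cancer = paste0("CA0", 1:4),
                   n_sites_known = 10L, n_sites_hit = 0L,
                   local_burden = c(40, 30, 20, 10))
  ann <- call_ptm_mut(
    make_muts("PA", rep(10, 10), gene = "G1",
              sample = paste0("S", 1:10),
              cancer = rep(paste0("CA0", 1:4), c(1, 2, 3, 4))),
    make_sites("PA", 10))
  fc <- family_burden_correlation(bt, ann, cat_df)
  expect_equal(fc$r, -1)

  # two cancers only: refused (NA), matching the >= 3 points precondition
  bt2 <- bt[1:2, ]
  ann2 <- call_ptm_mut(
    make_muts("PA", rep(10, 3), gene = "G1", sample = paste0("S", 1:3),
              cancer = c("CA01", "CA02", "CA02")),
    make_sites("PA", 10))
  fc2 <- family_burden_correlation(bt2, ann2, cat_df)
  expect_true(is.na(fc2$r))

  # textbook Pearson formula oracle on a simulated family table
  st <- small_study(seed = 43)
  bt3 <- local_burdens(st$ann, st$annotations$sites)
  fc3 <- family_burden_correlation(bt3, st$ann, st$catalog)
  for (k in seq_len(nrow(fc3))) {
    if (is.na(fc3$r[k])) next
    cat_k <- fc3$category[k]
    prot <- st$catalog$protein_id[st$catalog$category == cat_k]
    genes <- st$catalog$gene_symbol[st$catalog$category == cat_k]
    cancers <- sort(unique(bt3$cancer))
    x <- vapply(cancers, function(cc)
      mean(bt3$local_burden[bt3$cancer == cc & bt3$protein_id %in% prot]),
      numeric(1))
    m <- st$ann$mutations
    y <- vapply(cancers, function(cc)
      sum(m$is_ptm_mut & m$cancer == cc & m$gene %in% genes), numeric(1))
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fc3$r[k], r_hand)
  }
})

test_that("length-normalized rates average per-gene counts over length", {
  cat_df <- data.frame(gene_symbol = c("G1", "G2"),
                       protein_id = c("PA", "PB"),
                       gene_length = c(2000L, 1000L),
                       protein_length = c(600L, 300L),
                       is_matrisome = TRUE, division = "core_matrisome",
                       category = "collagens")
  sites <- make_sites("PA", c(10, 20))
  # one gene: 2 PTM^mut, length 2000 -> 1e-3
  ann <- call_ptm_mut(make_muts("PA", c(10, 20), gene = "G1"), sites)
  expect_equal(length_normalized_rate(ann, cat_df, "G1", "ptm"), 1e-3)
  # two genes (0/1000, 2/2000): mean 0.5e-3 (zero-count gene included)
  expect_equal(length_normalized_rate(ann, cat_df, c("G1", "G2"), "ptm"),
               mean(c(2 / 2000, 0)))
  # brute-force recount on a simulated study
  st <- small_study(seed = 47)
  genes <- st$catalog$gene_symbol[st$catalog$is_matrisome]
  got <- length_normalized_rate(st$ann, st$catalog, genes, "nonsilent")
  m <- st$ann$mutations
  hand <- mean(vapply(genes, function(g) {
    sum(m$gene == g & m$effect != "silent") /
      st$catalog$gene_length[st$catalog$gene_symbol == g]
  }, numeric(1)))
  expect_equal(got, hand)
})
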