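test_that("catalog honours the matrisome fraction and category rules", {
  cfg <- simulation_config(n_genes = 100, matrisome_fraction = 0.05, seed = 3)
  cat100 <- generate_gene_catalog(cfg)
  expect_equal(sum(cat100$is_matrisome), 5)

  cfg2 <- simulation_config(n_genes = 1000, matrisome_fraction = 0.048, seed = 3)
  cat1k <- generate_gene_catalog(cfg2)
  expect_equal(sum(cat1k$is_matrisome), 48)

  # division/category consistency and length invariants
  div_map <- matrisome_categories()
  expect_true(all((cat1k$division == "none") == !cat1k$is_matrisome))
  mat <- cat1k[cat1k$is_matrisome, ]
  expect_equal(unname(div_map[mat$category]), mat$division)
  expect_true(all(cat1k$gene_length >= 3 * cat1k$protein_length))
  expect_false(any(duplicated(cat1k$gene_symbol)))
})

test_that("the generator is deterministic and fixture files byte-identical", {
  cfg <- simulation_config(n_genes = 30, matrisome_fraction = 0.2, n_cancers = 2,
                           samples_per_cancer = 5, mutation_rate = 10, seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(s1, d1)
  write_fixture_bundle(s2, d2)
  f <- list.files(d1)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("PTM sites sit on chemically valid residues within the protein", {
  st <- small_study(seed = 5, n_genes = 50, matrisome_fraction = 0.3)
  sites <- st$annotations$sites
  valid <- ptm_valid_residues()
  for (tp in unique(sites$ptm_type)) {
    expect_true(all(sites$residue[sites$ptm_type == tp] %in% valid[[tp]]))
  }
  # the recorded residue matches the sequence
  seq_res <- substr(st$annotations$sequences[sites$protein_id],
                    sites$position, sites$position)
  expect_equal(unname(seq_res), sites$residue)
  # positions within protein bounds
  plen <- st$catalog$protein_length[match(sites$protein_id,
                                          st$catalog$protein_id)]
  expect_true(all(sites$position >= 1 & sites$position <= plen))
})

test_that("hydroxylation sites occur only on collagen-category proteins", {
  # force a catalog with collagens present
  split <- c(collagens = 0.5, ecm_glycoproteins = 0.1, proteoglycans = 0.1,
             ecm_affiliated = 0.1, ecm_regulators = 0.1, secreted_factors = 0.1)
  st <- small_study(seed = 6, n_genes = 40, matrisome_fraction = 0.4,
                    category_split = split)
  sites <- st$annotations$sites
  hydrox_prot <- unique(sites$protein_id[sites$ptm_type == "hydroxylation"])
  col_prot <- st$catalog$protein_id[st$catalog$category == "collagens"]
  expect_gt(length(hydrox_prot), 0)
  expect_true(all(hydrox_prot %in% col_prot))
  expect_true(all(sites$residue[sites$ptm_type == "hydroxylation"] %in%
                    c("P", "K")))
})

test_that("total selection removes every non-injected PTM-site mutation", {
  hs <- data.frame(gene = "G0002", position = 5, ptm_type = "phosphorylation",
                   cancers = "CA01,CA02")
  st <- small_study(seed = 9, ptm_selection_s = 1.0, hotspot_specs = hs)
  h <- st$ann$hits
  injected <- h$gene == "G0002" & h$position == 5
  expect_true(all(injected))
  expect_equal(sort(unique(h$cancer)), c("CA01", "CA02"))
})

test_that("neutral PTM-site hit fraction matches the enumerated expectation", {
  cfg <- simulation_config(n_genes = 80, matrisome_fraction = 0.1,
                           n_cancers = 2, samples_per_cancer = 60,
                           mutation_rate = 90, ptm_selection_s = 0, seed = 21)
  st <- simulate_study(cfg)
  st$mutations$mut_id <- seq_len(nrow(st$mutations))
  ann <- call_ptm_mut(st$mutations, st$annotations$sites)
  m <- ann$mutations
  snv <- m$effect != "silent" & m$variant_kind == "SNP"
  observed <- mean(m$is_ptm_mut[snv])

  # exact expectation by enumerating annotated positions, weighted by the
  # length-proportional gene assignment
  keys <- unique(paste(st$annotations$sites$protein_id,
                       st$annotations$sites$position))
  n_ptm_pos <- table(factor(sub(" .*", "", keys),
                            levels = st$catalog$protein_id))
  w <- st$catalog$gene_length / sum(st$catalog$gene_length)
  expected <- sum(w * as.integer(n_ptm_pos) / st$catalog$protein_length)
  se <- sqrt(expected * (1 - expected) / sum(snv))
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("empirical Ti/Tv and silent fractions match their configuration", {
  cfg <- simulation_config(n_genes = 50, n_cancers = 2, samples_per_cancer = 80,
                           mutation_rate = 80, titv_ratio = 2.5,
                           silent_fraction = 0.35, seed = 13)
  st <- simulate_study(cfg)
  m <- st$mutations
  titv <- classify_titv(m$ref, m$alt, m$variant_kind)
  snv <- titv != "not_applicable"
  expect_gt(sum(snv), 10000)
  p_ti <- 2.5 / 3.5
  se_ti <- sqrt(p_ti * (1 - p_ti) / sum(snv))
  expect_lt(abs(mean(titv[snv] == "transition") - p_ti), 3 * se_ti)

  se_sil <- sqrt(0.35 * 0.65 / nrow(m))
  expect_lt(abs(mean(m$effect == "silent") - 0.35), 3 * se_sil)
})

test_that("realized PTM^mut counts decrease with the selection coefficient", {
  count_ptm <- function(s, seed) {
    cfg <- simulation_config(n_genes = 30, matrisome_fraction = 0.2,
                             n_cancers = 2, samples_per_cancer = 10,
                             mutation_rate = 25, ptm_selection_s = s,
                             seed = seed)
    st <- simulate_study(cfg)
    st$mutations$mut_id <- seq_len(nrow(st$mutations))
    sum(call_ptm_mut(st$mutations, st$annotations$sites)$mutations$is_ptm_mut)
  }
  seeds <- 300 + seq_len(20)
  n0 <- mean(vapply(seeds, function(sd) count_ptm(0, sd), numeric(1)))
  n5 <- mean(vapply(seeds, function(sd) count_ptm(0.5, sd), numeric(1)))
  n9 <- mean(vapply(seeds, function(sd) count_ptm(0.9, sd), numeric(1)))
  expect_gt(n0, n5)
  expect_gt(n5, n9)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(matrisome_fraction = 1.2), "proportions")
  expect_error(simulation_config(n_genes = 5), "n_genes")
  expect_error(simulation_config(titv_ratio = 0), "titv_ratio")
  expect_error(
    simulation_config(hotspot_specs = data.frame(
      gene = "G0001", position = 1, ptm_type = "phosphorylation",
      cancers = "CA99")),
    "cohorts")
  expect_error(simulate_cohort(data.frame()[0, ], list(),
                               simulation_config()), "empty catalog")
})
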