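test_that("domain ratios and differential calling follow the fold rule", {
  rec <- data.frame(
    domain_id = rep(c("D1", "D2", "D3"), each = 2),
    gene_set = rep(c("matrisome", "rest"), 3),
    n_ptm_mut = c(4, 1, 3, 2, 0, 0),
    n_non_ptm_mut = c(10, 10, 20, 20, 0, 10),
    ratio = c(0.4, 0.1, 0.15, 0.1, NA, 0))
  # 4x difference is differential, 1.5x is not, undefined ratio excluded
  expect_equal(differential_domains(rec, fold = 2), "D1")
  # the fold = 2 set is a subset of the fold = 1 (any difference) set
  expect_true(all(differential_domains(rec, fold = 2) %in%
                    differential_domains(rec, fold = 1)))
  expect_equal(differential_domains(rec, fold = 1), c("D1", "D2"))
})

test_that("domain-level counts match the brute-force interval recount", {
  st <- small_study(seed = 67, n_genes = 20, mutation_rate = 10)
  got <- domain_ratios(st$ann, st$annotations$domains, st$catalog)
  ora <- oracle_domain_counts(st$ann, st$annotations$domains, st$catalog)
  merged <- merge(got, ora, by = c("domain_id", "gene_set"),
                  suffixes = c("", ".ora"))
  expect_equal(merged$n_ptm_mut, merged$n_ptm_mut.ora)
  expect_equal(merged$n_non_ptm_mut, merged$n_non_ptm_mut.ora)

  # conservation: per-protein domain PTM^mut sums never exceed the protein's
  # total PTM^mut times its number of distinct domains
  m <- st$ann$mutations
  for (pid in unique(m$protein_id[m$is_ptm_mut])) {
    n_prot <- sum(m$is_ptm_mut & m$protein_id == pid)
    doms <- st$annotations$domains[st$annotations$domains$protein_id == pid, ]
    per_dom <- vapply(unique(doms$domain_id), function(d) {
      dd <- doms[doms$domain_id == d, ]
      mm <- m[m$is_ptm_mut & m$protein_id == pid, ]
      sum(vapply(seq_len(nrow(mm)), function(i) {
        fe <- if (mm$effect[i] == "inframe_indel") mm$aa_end[i] else mm$aa_start[i]
        any(dd$start <= fe & dd$end >= mm$aa_start[i])
      }, logical(1)))
    }, numeric(1))
    expect_true(all(per_dom <= n_prot))
  }
})

test_that("region overlap flags footprints and strata correctly", {
  regions <- data.frame(protein_id = "PA", start = 90L, end = 120L,
                        region_function = "binding site")
  sites <- make_sites("PA", c(100, 10))
  sitesB <- make_sites("PB", 10)
  ann <- call_ptm_mut(make_muts(c("PA", "PA", "PB"), c(100, 10, 10)),
                      rbind(sites, sitesB))
  ro <- region_overlap(ann, regions)
  expect_equal(ro$n_annotated, 2)      # both PA PTM^mut have region info
  expect_equal(ro$n_overlapping, 1)    # only the one at 100
  expect_equal(ro$n_no_information, 1) # PB has no region rows
  expect_equal(ro$fraction, 50)

  # fraction equals a recount on a simulated study
  st <- small_study(seed = 71)
  ro2 <- region_overlap(st$ann, st$annotations$regions)
  expect_equal(ro2$fraction,
               100 * ro2$n_overlapping / ro2$n_annotated)
  expect_equal(ro2$n_annotated + ro2$n_no_information,
               sum(st$ann$mutations$is_ptm_mut))
})

test_that("motif scanning finds overlapping spans within the window", {
  # RGD at 4-6 overlaps the +/-3 window around position 5
  hits <- motif_scan("MKKRGDSAAA", 5, window = 3)
  expect_equal(hits$motif, "RGD")
  expect_equal(hits$motif_start, 4)
  expect_equal(hits$distance, 0)

  # no motif in a poly-A tract
  expect_equal(nrow(motif_scan("MKKAAAAAAA", 5, window = 3)), 0)

  # window 0 keeps only motifs containing the mutated residue
  h0 <- motif_scan("MKKRGDSAAA", 3, window = 0)
  expect_equal(nrow(h0), 0)
  h1 <- motif_scan("MKKRGDSAAA", 5, window = 0)
  expect_equal(h1$motif, "RGD")

  # case-insensitive, position validated
  expect_equal(motif_scan("mkkrgdsaaa", 5, window = 3)$motif, "RGD")
  expect_error(motif_scan("MKKRGDSAAA", 11), "outside")

  # distance is the residue gap to the motif span
  h2 <- motif_scan("RGDAAAAKAA", 6, window = 3)
  expect_equal(h2$distance, 3)
})

test_that("motif scanning matches the exhaustive substring oracle", {
  set.seed(73)
  for (rep in 1:12) {
    sq <- paste(sample(c("G", "P", "R", "D", "V", "L", "E", "F", "A", "K"),
                       200, replace = TRUE), collapse = "")
    pos <- sample(200, 1)
    w <- sample(0:5, 1)
    got <- motif_scan(sq, pos, window = w)
    ora <- oracle_motif_scan(sq, pos, default_motifs(), w)
    expect_equal(got[c("motif", "motif_start", "motif_end")], ora,
                 ignore_attr = TRUE)
  }
})

test_that("context extraction clips at protein ends and reports the offset", {
  sq <- paste(rep("A", 30), collapse = "")
  ctx <- extract_context(sq, 5, flank = 10)
  expect_equal(ctx$start, 1); expect_equal(ctx$end, 15)
  expect_equal(ctx$offset, 5)
  ctx2 <- extract_context(sq, 15, flank = 10)
  expect_equal(ctx2$start, 5); expect_equal(ctx2$end, 25)
  expect_equal(ctx2$offset, 11)
  for (p in c(1, 10, 30)) {
    expect_lte(nchar(extract_context(sq, p)$context), 21)
  }
  expect_error(extract_context(sq, 31), "outside")
})

test_that("residue properties use the fixed five-class partition", {
  expect_equal(residue_property("S"), "polar")
  expect_equal(residue_property("L"), "hydrophobic")
  expect_equal(residue_property(c("D", "K", "G", "X")),
               c("acidic", "basic", "special", "unknown"))
  # complete partition of the 20 standard residues
  expect_false(any(residue_property(amino_acids()) == "unknown"))
})

test_that("context property profiles equal a direct tally and sum to 100", {
  set.seed(79)
  n <- 100
  contexts <- vapply(seq_len(n), function(i) {
    paste(sample(amino_acids(), 21, replace = TRUE), collapse = "")
  }, character(1))
  offsets <- rep(11L, n)
  prof <- context_property_profile(contexts, offsets, flank = 10)
  # rows sum to 100 within each offset
  sums <- tapply(prof$pct, prof$offset, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # spot-check offset +2 against a direct tally
  aa2 <- substr(contexts, 13, 13)
  direct <- table(residue_property(aa2))
  sub <- prof[prof$offset == 2, ]
  for (p in names(direct)) {
    expect_equal(sub$n[sub$property == p], unname(as.integer(direct[p])))
  }
})
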