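test_that("the default bundle has the full 2 x 7 x 3 design and is reproducible", {
  b <- default_bundle()
  expect_equal(ncol(b$rna_counts$values), 42L)
  expect_length(enumerate_contrasts(b$design), 7L)
  expect_true(any(b$annotation$chromosome == "X"))
  b2 <- simulate_study(sim_config(seed = 1))
  expect_identical(b$rna_counts$values, b2$rna_counts$values)
  expect_identical(b$protein_intensities$values, b2$protein_intensities$values)
  expect_identical(b$allelic_counts, b2$allelic_counts)
  expect_identical(b$isoform_counts, b2$isoform_counts)
  b3 <- simulate_study(sim_config(seed = 2))
  expect_false(identical(b$rna_counts$values, b3$rna_counts$values))
})

test_that("config validation rejects inconsistent settings before sampling", {
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(seed = 1, mar_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, n_imprinted = 5000), "n_imprinted")
  expect_error(sim_config(seed = 1, diu_switch = 0.9), "diu_switch")
  expect_error(
    simulate_proteome(default_bundle(), sim_config(seed = 1, n_proteins = 5000)),
    "exceeds")
})

test_that("truth tables reference only existing features", {
  b <- default_bundle()
  feats <- b$annotation$feature_id
  expect_true(all(b$truth$de_genes$gene_id %in% feats))
  expect_true(all(b$truth$diu_genes$gene_id %in% feats))
  expect_true(all(b$truth$ase_shift_genes$gene_id %in% feats))
  expect_true(all(b$truth$pt_events$gene_id %in% feats))
  expect_true(all(unlist(b$genesets) %in% feats))
  expect_true(all(b$truth$enriched_sets$set_id %in% names(b$genesets)))
})

test_that("MNAR-truth proteins are absent in all replicates of some group", {
  b <- default_bundle()
  x <- b$protein_intensities$values
  groups <- split(b$design$sample_id,
                  paste(b$design$genotype, b$design$day, b$design$region))
  for (p in b$truth$mnar_proteins$protein_id) {
    all_missing <- vapply(groups, function(s) all(is.na(x[p, s])), logical(1))
    expect_true(any(all_missing))
  }
})

test_that("no missingness is generated when both mechanisms are off", {
  cfg <- sim_config(seed = 3, mar_rate = 0, mnar_censor_quantile = 0)
  b <- simulate_study(cfg)
  expect_false(anyNA(b$protein_intensities$values))
})

test_that("protein intensities track RNA at the configured correlation", {
  b <- default_bundle()
  f <- exclude_chromosome(filter_expressed(b$rna_counts), b$annotation)
  nm <- tmm_normalize(f)
  raw <- b$protein_intensities
  pairs <- match_pairs(nm$log2cpm, raw, b$protein_mapping)
  expect_lt(abs(attr(pairs, "median_correlation") - 0.5), 0.1)
})

test_that("isoform counts are conserved and one-isoform genes are DIU-inert", {
  b <- default_bundle()
  iso <- b$isoform_counts
  sums <- tapply(iso$count, paste(iso$gene_id, iso$sample_id, sep = "\r"), sum)
  gene_sample <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
  expected <- b$rna_counts$values[cbind(gene_sample[, 1], gene_sample[, 2])]
  expect_equal(as.numeric(sums), as.numeric(expected))
  # genes simulated with a single isoform have constant usage 1
  n_iso <- tapply(iso$isoform_id, iso$gene_id, function(x) length(unique(x)))
  singles <- names(n_iso)[n_iso == 1]
  if (length(singles)) {
    ra <- relative_abundance(iso[iso$gene_id %in% singles[1], ])
    expect_true(all(ra$usage[!is.na(ra$usage)] == 1))
  }
})

test_that("balanced SNPs at depth 50 score near the beta-binomial expectation", {
  cfg <- sim_config(seed = 5, depth_mean = 50)
  b <- simulate_study(cfg)
  tab <- score_allelic_table(b$allelic_counts)
  imp <- b$annotation$feature_id[b$annotation$is_imprinted]
  balanced <- tab[!tab$gene_id %in% imp, ]
  expect_gt(mean(balanced$ase), 0.5)
  expect_lt(mean(balanced$ase), 0.62)
})

test_that("unenriched promoters give a null Welch test across seeds", {
  ann_ok <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, tss_enrichment_factor = 1)
    fake <- list(annotation = default_bundle()$annotation)
    prof <- simulate_tss_profiles(fake, cfg)$tss_profiles
    tss_enrichment(prof, fake$annotation, n_random_sets = 20, seed = s)$p > 0.05
  }, logical(1))
  expect_gte(mean(ann_ok), 0.9)
})

test_that("a null generator configuration yields a calibrated DE caller", {
  any_call <- vapply(1:15, function(s) {
    cfg <- sim_config(seed = 1000 + s, fraction_de = 0, n_transient = 0,
                      rtt_delay_days = 0)
    b <- simulate_study(cfg)
    f <- exclude_chromosome(filter_expressed(b$rna_counts), b$annotation)
    nm <- tmm_normalize(f)
    res <- fit_contrast(nm$log2cpm, enumerate_contrasts(b$design)[["D40-dorsal"]])
    any(res$FDR < 0.05)
  }, logical(1))
  # under a complete null, BH limits the chance of any discovery to ~5%
  expect_lte(sum(any_call), 3L)
})

test_that("bundle export writes readable text tables", {
  b <- default_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  back <- read_matrix(file.path(dir, "rna_counts.tsv"), "raw_count")
  expect_equal(back$values, b$rna_counts$values, tolerance = 1e-12)
  des <- read_design(file.path(dir, "design.tsv"))
  expect_equal(des$sample_id, b$design$sample_id)
  expect_equal(des$day, b$design$day)
  expect_equal(des$genotype, b$design$genotype)
  sets <- read_gmt(file.path(dir, "genesets.gmt"))
  expect_setequal(names(sets), names(b$genesets))
  expect_setequal(sets$SET_DEV_forebrain, b$genesets$SET_DEV_forebrain)
})
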