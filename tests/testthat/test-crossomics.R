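make_paired_layers <- function(n_pairs = 5, n_samples = 12, seed = 1) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  g <- matrix(rnorm(n_pairs * n_samples, 8), n_pairs,
              dimnames = list(sprintf("G%d", seq_len(n_pairs)), samples))
  p <- g + matrix(rnorm(n_pairs * n_samples, 0, 0.1), n_pairs)
  rownames(p) <- sprintf("P%d", seq_len(n_pairs))
  list(rna = expr_matrix(g, "log2cpm"),
       protein = expr_matrix(p, "log2intensity"),
       mapping = data.frame(gene_id = rownames(g), protein_id = rownames(p),
                            stringsAsFactors = FALSE))
}

test_that("pair matching drops multi-mapped proteins and reports correlations", {
  ly <- make_paired_layers()
  p <- ly$protein$values
  p["P1", ] <- ly$rna$values["G1", ]            # exact copy -> rho 1
  p["P2", ] <- -ly$rna$values["G2", ]           # negation -> rho -1
  pairs <- expect_silent(match_pairs(ly$rna, expr_matrix(p, "log2intensity"),
                                     ly$mapping))
  expect_equal(pairs$spearman[pairs$gene_id == "G1"], 1)
  expect_equal(pairs$spearman[pairs$gene_id == "G2"], -1)
  expect_gte(attr(pairs, "negative_fraction"), 1 / 5)
  bad_map <- rbind(ly$mapping,
                   data.frame(gene_id = "G9", protein_id = "P1"))
  expect_warning(pairs2 <- match_pairs(ly$rna, ly$protein, bad_map),
                 "multiple genes")
  expect_false("P1" %in% pairs2$protein_id)
})

test_that("post-transcriptional events require both model conditions", {
  design <- make_full_design()
  samples <- design$sample_id
  grp <- as.integer(design$genotype == "RTT")
  set.seed(51)
  g <- matrix(rnorm(3 * length(samples), 8, 1), 3,
              dimnames = list(c("G1", "G2", "G3"), samples))
  p <- rbind(
    G1 = 2 + 1 * g["G1", ] + 2 * grp + rnorm(length(samples), 0, 0.3),
    G2 = 2 + 1 * g["G2", ] + 0 * grp + rnorm(length(samples), 0, 0.3),
    G3 = 2 + 0 * g["G3", ] + 2 * grp + rnorm(length(samples), 0, 0.3))
  rownames(p) <- c("P1", "P2", "P3")
  mapping <- data.frame(gene_id = rownames(g), protein_id = rownames(p),
                        stringsAsFactors = FALSE)
  rna <- expr_matrix(g, "log2cpm")
  prot <- expr_matrix(p, "log2intensity")
  pairs <- match_pairs(rna, prot, mapping)
  fit <- post_transcriptional_events(pairs, rna, prot, design)
  expect_true(fit$event[fit$gene_id == "G1"])      # both conditions hold
  expect_false(fit$event[fit$gene_id == "G2"])     # no group offset
  expect_false(fit$event[fit$gene_id == "G3"])     # protein untracked by gene
})

test_that("regulator edges follow the top-fraction rule exactly", {
  set.seed(52)
  samples <- sprintf("s%02d", 1:20)
  cand <- matrix(rnorm(100 * 20), 100,
                 dimnames = list(sprintf("C%03d", 1:100), samples))
  targets <- matrix(rnorm(10 * 20), 10,
                    dimnames = list(sprintf("T%02d", 1:10), samples))
  classes <- setNames(rep("TF-protein", 100), rownames(cand))
  net <- infer_regulators(targets, cand, classes, n_trees = 50, seed = 1)
  expect_equal(nrow(net), 50L)  # top 5% of 100 x 10 = 1000 interactions
  expect_true(all(net$class == "TF-protein"))
  # with the full pool kept, importances sum to 1 per target
  all_edges <- infer_regulators(targets, cand, classes,
                                top_fraction = c("TF-protein" = 1),
                                n_trees = 50, seed = 1)
  sums <- tapply(all_edges$weight, all_edges$target_set, sum)
  expect_equal(as.numeric(sums), rep(1, 10), tolerance = 1e-9)
  # candidate order does not change the selected edges
  net2 <- infer_regulators(targets, cand[sample(100), ], classes,
                           n_trees = 50, seed = 1)
  key <- function(n) sort(paste(n$regulator, n$target_set))
  expect_identical(key(net2), key(net))
})

test_that("a regulator driving a target ranks at the top of its importances", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    samples <- sprintf("s%02d", 1:30)
    cand <- matrix(rnorm(51 * 30), 51,
                   dimnames = list(sprintf("C%02d", 1:51), samples))
    target <- matrix(cand["C01", ] + rnorm(30, 0, 0.3), 1,
                     dimnames = list("T1", samples))
    classes <- setNames(rep("TF-protein", 51), rownames(cand))
    net <- infer_regulators(target, cand, classes,
                            top_fraction = c("TF-protein" = 1),
                            n_trees = 300, seed = s)
    "C01" %in% net$regulator[order(-net$weight)][1:3]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("a driven target concentrates importance on its driver", {
  set.seed(53)
  samples <- sprintf("s%02d", 1:30)
  cand <- matrix(rnorm(50 * 30), 50,
                 dimnames = list(sprintf("C%02d", 1:50), samples))
  target <- matrix(cand["C01", ] + rnorm(30, 0, 0.3), 1,
                   dimnames = list("T1", samples))
  classes <- setNames(rep("TF-protein", 50), rownames(cand))
  net <- infer_regulators(target, cand, classes,
                          top_fraction = c("TF-protein" = 1),
                          n_trees = 300, seed = 1)
  expect_gt(net$weight[net$regulator == "C01"], 0.15)
})

test_that("noise targets spread importance over many candidates", {
  diffuse <- vapply(1:10, function(s) {
    set.seed(100 + s)
    samples <- sprintf("s%02d", 1:30)
    cand <- matrix(rnorm(50 * 30), 50,
                   dimnames = list(sprintf("C%02d", 1:50), samples))
    target <- matrix(rnorm(30), 1, dimnames = list("T1", samples))
    classes <- setNames(rep("TF-protein", 50), rownames(cand))
    net <- infer_regulators(target, cand, classes,
                            top_fraction = c("TF-protein" = 1),
                            n_trees = 300, seed = s)
    # far below the share a genuine driver attains (cf. the test above)
    max(net$weight) < 0.15
  }, logical(1))
  expect_gte(mean(diffuse), 0.8)
})
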