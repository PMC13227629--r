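test_that("enrichment score equals the brute-force running sum", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:20)
  ranks <- setNames(seq(3, -3, length.out = 20) + rnorm(20, 0, 0.1), genes)
  top_set <- names(sort(ranks, decreasing = TRUE))[1:5]
  g <- preranked_gsea(ranks, list(S = top_set), n_perm = 50, min_size = 1,
                      max_size = 20, seed = 1)
  expect_equal(g$ES, brute_force_es(ranks, top_set), tolerance = 1e-12)
  expect_gt(g$ES, 0.8)  # a top-placed set is strongly enriched
  # random sets, random weights, several cases
  for (i in 1:10) {
    set.seed(100 + i)
    r <- setNames(rnorm(30), sprintf("x%02d", 1:30))
    s <- sample(names(r), sample(5:15, 1))
    g2 <- preranked_gsea(r, list(S = s), n_perm = 10, min_size = 1,
                         max_size = 30, seed = 1)
    expect_equal(g2$ES, brute_force_es(r, s), tolerance = 1e-12)
  }
})

test_that("degenerate sets give zero or skipped results", {
  ranks <- setNames(rnorm(15), sprintf("g%02d", 1:15))
  g <- preranked_gsea(ranks, list(ALL = names(ranks)), n_perm = 10,
                      min_size = 1, max_size = 15, seed = 1)
  expect_equal(g$ES, 0)
  expect_warning(
    g2 <- preranked_gsea(ranks, list(NONE = c("zz1", "zz2")), n_perm = 10,
                         min_size = 1, max_size = 15, seed = 1),
    "no ranked members")
  expect_equal(nrow(g2), 0L)
})

test_that("classic (weight 0) scores of a set and its complement are opposed", {
  set.seed(12)
  ranks <- setNames(rnorm(12), sprintf("g%02d", 1:12))
  s <- names(ranks)[c(1, 4, 5, 9)]
  comp <- setdiff(names(ranks), s)
  es_s <- brute_force_es(ranks, s, weight = 0)
  es_c <- brute_force_es(ranks, comp, weight = 0)
  expect_equal(es_s, -es_c, tolerance = 1e-12)
  g <- preranked_gsea(ranks, list(S = s, C = comp), weight = 0, n_perm = 10,
                      min_size = 1, max_size = 12, seed = 1)
  expect_equal(g$ES[g$set_id == "S"], -g$ES[g$set_id == "C"], tolerance = 1e-12)
})

test_that("term aggregation applies the >= 4-of-7 rule", {
  labs <- paste0("c", 1:7)
  mk <- function(fdrs) {
    lapply(setNames(labs, labs), function(l) {
      data.frame(set_id = c("A", "B"), size = 10, ES = 0.5, NES = 1.2,
                 P = c(0.001, 0.5),
                 FDR = c(fdrs[[l]][1], fdrs[[l]][2]),
                 leading_edge = "", stringsAsFactors = FALSE)
    })
  }
  fdrs <- setNames(rep(list(c(0.2, 0.2)), 7), labs)
  for (l in labs[1:4]) fdrs[[l]][1] <- 0.01  # A significant in 4
  for (l in labs[1:3]) fdrs[[l]][2] <- 0.01  # B significant in 3
  agg <- aggregate_terms(mk(fdrs), fdr_max = 0.05, min_contrasts = 4)
  expect_identical(agg$set_id, "A")
  agg1 <- aggregate_terms(mk(fdrs), fdr_max = 0.05, min_contrasts = 1)
  expect_setequal(agg1$set_id, c("A", "B"))
  # monotone non-increasing in fdr_max
  n_loose <- nrow(aggregate_terms(mk(fdrs), fdr_max = 0.3, min_contrasts = 4))
  expect_gte(n_loose, nrow(agg))
})

test_that("term clustering uses the Jaccard overlap and picks representatives", {
  expect_equal(jaccard_index(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_index(c("A", "B"), c("A", "B")), 1)
  sets <- list(T1 = c("A", "B", "C"), T2 = c("B", "C", "D"), T3 = c("X", "Y"))
  agg <- data.frame(set_id = c("T1", "T2", "T3"), n_significant = 4,
                    mean_neg_log10_p = c(3, 2, 1), stringsAsFactors = FALSE)
  tg <- cluster_terms(agg, sets, jaccard_threshold = 0.5)
  expect_equal(nrow(tg$edges), 1L)
  expect_equal(tg$edges$jaccard, 0.5)
  expect_equal(unname(tg$clusters[c("T1", "T2")]), c(1L, 1L))
  expect_false(tg$clusters["T3"] == tg$clusters["T1"])
  expect_identical(unname(tg$representatives[1]), "T1")
})

test_that("permutation-count null hits its analytic bounds", {
  genes <- sprintf("g%03d", 1:60)
  sets <- list(S1 = genes[1:12], S2 = genes[13:24])
  r0 <- permutation_count_null(genes, sets, observed_count = 0, n_perm = 100,
                               inner_n_perm = 50, min_size = 5, seed = 1)
  expect_equal(r0$p_value, 1)
  rbig <- permutation_count_null(genes, sets, observed_count = 99, n_perm = 100,
                                 inner_n_perm = 50, min_size = 5, seed = 1)
  expect_equal(rbig$p_value, 1 / 101)
})

test_that("eigengene and membership match the direct PCA and correlations", {
  samples <- paste0("s", 1:10)
  prof <- sin(seq(0, 3, length.out = 10))
  m <- rbind(a = prof, b = prof, c = prof)
  colnames(m) <- samples
  r <- eigengene_membership(m, c("a", "b", "c"))
  expect_equal(unname(r$membership), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(r$explained_variance, 1, tolerance = 1e-9)
  m2 <- rbind(a = prof, b = -prof)
  colnames(m2) <- samples
  r2 <- eigengene_membership(m2, c("a", "b"))
  expect_equal(unname(r2$membership), c(1, 1), tolerance = 1e-9)
  set.seed(13)
  m3 <- matrix(rnorm(100), 10, dimnames = list(paste0("g", 1:10), samples))
  r3 <- eigengene_membership(m3, rownames(m3))
  brute <- apply(m3, 1, function(row) abs(cor(row, r3$eigengene)))
  expect_equal(r3$membership, brute, tolerance = 1e-9)
  # orientation convention: positive correlation with the mean profile
  z <- sweep(sweep(m3, 1, rowMeans(m3)), 1, apply(m3, 1, sd), "/")
  expect_gte(cor(r3$eigengene, colMeans(z)), 0)
})

test_that("over-representation P equals the hypergeometric tail", {
  universe <- sprintf("u%03d", 1:100)
  hits <- universe[1:20]
  ann <- universe[c(1:10, 51:60)]  # overlap 10
  r <- overrep_test(hits, ann, universe)
  brute <- sum(dhyper(10:20, 20, 80, 20))
  expect_equal(r$p, brute, tolerance = 1e-12)
  expect_equal(r$table[1, 1], 10)
  expect_equal(overrep_test(universe, universe, universe)$p, 1)
  expect_equal(overrep_test(character(), ann, universe)$p, 1)
})
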