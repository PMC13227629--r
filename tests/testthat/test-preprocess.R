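test_that("CPM expression filter keeps and drops genes by the 10-in-3 rule", {
  # libraries of 1e6 so counts are CPM directly
  n <- 42
  base <- matrix(rep(1e6 / 10, 10 * n), 10, n,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:n)))
  base["g01", ] <- 0; base["g01", 1:3] <- 15 * 1e6 / 1e6  # ~15 CPM in 3 samples
  base["g02", ] <- 0; base["g02", 1:2] <- 15
  base["g03", ] <- 0
  em <- expr_matrix(round(base), "raw_count")
  kept <- rownames(filter_expressed(em, min_cpm = 10, min_samples = 3)$values)
  cp <- cpm(em)
  expect_true(sum(cp["g01", ] > 10) >= 3)
  expect_true("g01" %in% kept)
  expect_false("g02" %in% kept)
  expect_false("g03" %in% kept)
})

test_that("CPM columns sum to one million", {
  set.seed(7)
  m <- matrix(rpois(300, 50), 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:10)))
  cp <- cpm(expr_matrix(m, "raw_count"))
  expect_equal(unname(colSums(cp)), rep(1e6, 10), tolerance = 1e-9)
})

test_that("chromosome exclusion removes listed chromosomes and checks coverage", {
  set.seed(1)
  m <- matrix(rpois(100 * 4, 40), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  ann <- data.frame(feature_id = rownames(m),
                    chromosome = c(rep("X", 7), rep("1", 93)))
  em <- expr_matrix(m, "raw_count")
  expect_equal(nrow(exclude_chromosome(em, ann)$values), 93L)
  expect_identical(exclude_chromosome(em, ann, character())$values, em$values)
  expect_error(exclude_chromosome(em, ann[-1, ]), "without annotation")
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  set.seed(2)
  col <- rpois(200, 100) + 1
  m <- cbind(s1 = col, s2 = col, s3 = col)
  rownames(m) <- sprintf("g%03d", 1:200)
  nm <- tmm_normalize(expr_matrix(m, "raw_count"))
  expect_equal(unname(nm$factors), rep(1, 3), tolerance = 1e-12)
  m2 <- cbind(s1 = col, s2 = 2L * col, s3 = col)
  rownames(m2) <- rownames(m)
  nm2 <- tmm_normalize(expr_matrix(m2, "raw_count"))
  expect_equal(unname(nm2$factors), rep(1, 3), tolerance = 1e-12)
  # same composition at double depth: log2-CPM agrees across samples
  expect_equal(nm2$log2cpm$values[, "s2"], nm2$log2cpm$values[, "s1"],
               tolerance = 0.01)
})

test_that("TMM matches the established reference implementation on a toy", {
  set.seed(3)
  m <- matrix(rpois(30, lambda = rep(c(20, 100, 500), 10)) + 1, 10, 3,
              byrow = TRUE, dimnames = list(sprintf("g%02d", 1:10),
                                            c("a", "b", "c")))
  m[, 2] <- m[, 2] * 3L
  ours <- tmm_normalize(expr_matrix(m, "raw_count"))$factors
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("tmm_normalize is invariant to feature order", {
  set.seed(4)
  m <- matrix(rpois(150 * 3, 60) + 1, 150, 3,
              dimnames = list(sprintf("g%03d", 1:150), c("a", "b", "c")))
  f1 <- tmm_normalize(expr_matrix(m, "raw_count"))$factors
  f2 <- tmm_normalize(expr_matrix(m[sample(150), ], "raw_count"))$factors
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("protein presence filter follows the 2-of-a-group rule", {
  design <- make_full_design()
  em <- make_log_matrix(3, design$sample_id, seed = 5)
  x <- em$values
  grp <- design$sample_id[design$genotype == "RTT" & design$day == 13 &
                          design$region == "dorsal"]
  # protein 1: seen only in 2 replicates of one stratum
  x["F001", ] <- NA; x["F001", grp[1:2]] <- 8
  # protein 2: one observation per stratum everywhere
  x["F002", ] <- NA
  strata <- split(design$sample_id,
                  paste(design$genotype, design$day, design$region))
  for (s in strata) x["F002", s[1]] <- 8
  em2 <- expr_matrix(x, "log2intensity", missing_allowed = TRUE)
  kept <- rownames(filter_proteins(em2, design)$values)
  expect_true("F001" %in% kept)
  expect_false("F002" %in% kept)
  expect_true("F003" %in% kept)
})

test_that("missingness classification separates MNAR, MAR and complete", {
  design <- make_full_design()
  em <- make_log_matrix(3, design$sample_id, seed = 6)
  x <- em$values
  grp <- design$sample_id[design$genotype == "IC" & design$day == 40 &
                          design$region == "ventral"]
  x["F001", grp] <- NA                      # whole stratum missing -> MNAR
  x["F002", design$sample_id[5]] <- NA      # one scattered cell -> MAR
  cls <- classify_missingness(
    expr_matrix(x, "log2intensity", missing_allowed = TRUE), design)
  expect_identical(unname(cls[c("F001", "F002", "F003")]),
                   c("MNAR", "MAR", "complete"))
})

test_that("mixed imputation preserves observed cells and respects the classes", {
  design <- make_full_design()
  em <- make_log_matrix(30, design$sample_id, seed = 7)
  x <- em$values
  # MAR cell whose neighbours are identical rows
  x[1:6, ] <- rep(x[2, ], each = 6)
  x[1, 3] <- NA
  # MNAR protein: absent in one whole stratum
  grp <- design$sample_id[design$genotype == "RTT" & design$day == 75 &
                          design$region == "dorsal"]
  x["F010", grp] <- NA
  em2 <- expr_matrix(x, "log2intensity", missing_allowed = TRUE)
  cls <- classify_missingness(em2, design)
  imp <- impute_mixed(em2, cls, k = 5, seed = 1)
  expect_false(anyNA(imp$values))
  expect_equal(imp$values[1, 3], x[2, 3], tolerance = 1e-12)
  obs <- !is.na(x)
  expect_identical(imp$values[obs], x[obs])
  # MNAR draws sit below the host sample's observed median
  for (s in grp)
    expect_lt(imp$values["F010", s], median(x[, s], na.rm = TRUE))
  # no missing values -> identity
  full <- make_log_matrix(5, design$sample_id, seed = 8)
  expect_identical(impute_mixed(full, classify_missingness(full, design))$values,
                   full$values)
})

test_that("vsn stand-in calibrates offsets and stabilizes variance", {
  set.seed(9)
  base <- matrix(rnorm(200 * 2, 20, 2), 200,
                 dimnames = list(sprintf("p%03d", 1:200), c("a", "b")))
  base[, "b"] <- base[, "a"] + 3  # global offset
  vs <- vsn_normalize(expr_matrix(base, "log2intensity", missing_allowed = TRUE))
  expect_equal(median(vs$values[, "a"]), median(vs$values[, "b"]),
               tolerance = 1e-6)
  cons <- matrix(5, 10, 3, dimnames = list(sprintf("p%d", 1:10), c("a", "b", "c")))
  vc <- vsn_normalize(expr_matrix(cons, "log2intensity", missing_allowed = TRUE))
  expect_equal(max(vc$values) - min(vc$values), 0, tolerance = 1e-9)
})

test_that("the glog reduces heteroscedasticity of additive-noise intensities", {
  set.seed(10)
  mu <- 2^runif(500, 4, 14)                      # wide dynamic range
  lin <- sapply(1:6, function(j) pmax(mu + rnorm(500, 0, 40), 1))
  rownames(lin) <- sprintf("p%03d", 1:500); colnames(lin) <- paste0("s", 1:6)
  em <- expr_matrix(log2(lin), "log2intensity", missing_allowed = TRUE)
  vs <- vsn_normalize(em)
  decile_spread <- function(m) {
    sds <- apply(m, 1, sd); means <- rowMeans(m)
    var(tapply(sds, cut(rank(means), 10), mean))
  }
  expect_lt(decile_spread(vs$values), decile_spread(log2(lin)))
})

test_that("z-scoring gives the closed-form values and flags constant rows", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(z <- zscore_panel(m), "zero-variance")
  expect_equal(unname(z["g1", ]), c(-1.225, 0, 1.225), tolerance = 1e-3)
  expect_equal(mean(z["g1", ]^2), 1, tolerance = 1e-12)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
})
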