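# Shared fixture builders: everything is generated in code at test time.

# minimal full design: 2 genotypes x (D0 + 3 days x 2 regions) x n replicates
make_full_design <- function(n_replicates = 3) {
  strata <- rbind(data.frame(day = 0L, region = "iPSC"),
                  expand.grid(day = c(13L, 40L, 75L),
                              region = c("dorsal", "ventral"),
                              stringsAsFactors = FALSE))
  rows <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i)
    expand.grid(genotype = c("RTT", "IC"), replicate = seq_len(n_replicates),
                day = strata$day[i], region = strata$region[i],
                stringsAsFactors = FALSE)))
  rows$sample_id <- sprintf("%s_D%d_%s_r%d", rows$genotype, rows$day,
                            rows$region, rows$replicate)
  study_design(rows[, c("sample_id", "genotype", "region", "day", "replicate")])
}

# random named log-scale matrix
make_log_matrix <- function(n_feat, samples, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * length(samples), 8, sd), n_feat,
              dimnames = list(sprintf("F%03d", seq_len(n_feat)), samples))
  expr_matrix(m, "log2intensity", missing_allowed = TRUE)
}

# a fabricated per-contrast result table (for marker-rule tests)
make_result <- function(features, lfc, p, label) {
  res <- data.frame(feature_id = features, log2FC = lfc, t = 0, P = p,
                    FDR = p, stringsAsFactors = FALSE)
  res$ranking <- ranking_score(pmax(res$P, 1e-300), res$log2FC)
  attr(res, "contrast") <- label
  res
}

# brute-force weighted KS running-sum enrichment score (independent oracle)
brute_force_es <- function(ranks, set, weight = 1) {
  ord <- order(-ranks, names(ranks))
  r <- ranks[ord]
  hit <- names(r) %in% set
  nr <- sum(abs(r[hit])^weight)
  n_miss <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(r)) {
    run <- if (hit[i]) run + abs(r[i])^weight / nr else run - 1 / n_miss
    if (abs(run) > abs(best)) best <- run
    else if (abs(run) == abs(best) && run > best) best <- run
  }
  unname(best)
}

# one cached default bundle shared by tests that only read from it
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 1))
    cache
  }
})
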