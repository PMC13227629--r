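# Preranked GSEA with a gene-label permutation null, cross-contrast
# aggregation of GO-BP style terms, Jaccard term clustering, the
# permutation-count null for significant-term counts, and eigengene /
# module-membership interpretation.

# Order ranking scores decreasing, breaking ties by feature id so the
# ranked list is reproducible.
.prep_ranks <- function(ranks) {
  if (is.null(names(ranks))) stop("ranks must be named by feature id")
  if (anyDuplicated(names(ranks))) stop("duplicate feature ids in ranks")
  ranks[order(-ranks, names(ranks))]
}

# Weighted Kolmogorov-Smirnov enrichment score for hit positions `pos`
# (sorted, 1-based) in a ranked list of length N. `w` are the |score|^weight
# increments at the hits.
.gsea_es <- function(w, pos, N) {
  m <- length(pos)
  if (m == 0L || m == N) return(0)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, m); nr <- m }
  cum_hit <- cumsum(w) / nr
  miss <- (pos - seq_len(m)) / (N - m)
  top <- cum_hit - miss
  bottom <- c(0, cum_hit[-m]) - miss
  hi <- max(top)
  lo <- min(bottom)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment scores on a ranked
#' list (typically signed -log10 P ranking scores), with a gene-label
#' permutation null: for each set, hit positions are redrawn uniformly
#' \code{n_perm} times.  NES = ES divided by the mean |null ES| of the same
#' sign; nominal P is the one-sided permutation tail among same-sign nulls;
#' FDR is Benjamini-Hochberg across sets.
#'
#' @param ranks named numeric vector, feature id -> ranking score; ties are
#'   broken by feature id.
#' @param sets named list of character vectors.
#' @param n_perm permutations per set (default 1000).
#' @param weight exponent on |score| in the running sum (default 1).
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked universe (defaults 10 and 500).
#' @param seed RNG seed for the permutation null.
#' @return data frame: set_id, size, ES, NES, P, FDR, leading_edge
#'   (comma-separated member ids).
#' @export
preranked_gsea <- function(ranks, sets, n_perm = 1000, weight = 1,
                           min_size = 10, max_size = 500, seed = 1) {
  r <- .prep_ranks(ranks)
  N <- length(r)
  ids <- names(r)
  absw <- abs(r)^weight
  set_pos <- lapply(sets, function(s) sort(match(unique(s), ids)))
  set_pos <- lapply(set_pos, function(p) p[!is.na(p)])
  sizes <- lengths(set_pos)
  absent <- sizes == 0L
  if (any(absent))
    warning("set(s) with no ranked members skipped: ",
            paste(utils::head(names(sets)[absent], 5), collapse = ", "))
  keep <- !absent & sizes >= min_size & sizes <= max_size
  set_pos <- set_pos[keep]
  if (!length(set_pos))
    return(data.frame(set_id = character(), size = integer(), ES = numeric(),
                      NES = numeric(), P = numeric(), FDR = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  res <- lapply(names(set_pos), function(sid) {
    pos <- set_pos[[sid]]
    m <- length(pos)
    es <- .gsea_es(absw[pos], pos, N)
    null_es <- vapply(seq_len(n_perm), function(b) {
      p <- sort(sample.int(N, m))
      .gsea_es(absw[p], p, N)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    if (length(same)) {
      p_val <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (mean(abs(same)) > 0) es / mean(abs(same)) else 0
    } else {
      p_val <- 1 / (n_perm + 1)
      nes <- if (mean(abs(null_es)) > 0) es / mean(abs(null_es)) else 0
    }
    # leading edge: hits at or before (after, for negative ES) the extremum
    le <- .leading_edge(absw[pos], pos, N, es)
    data.frame(set_id = sid, size = m, ES = es, NES = nes, P = p_val,
               leading_edge = paste(ids[pos[le]], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$FDR <- stats::p.adjust(out$P, "BH")
  out[, c("set_id", "size", "ES", "NES", "P", "FDR", "leading_edge")]
}

# indices (into pos) of leading-edge hits
.leading_edge <- function(w, pos, N, es) {
  m <- length(pos)
  if (m == 0L || m == N) return(integer())
  nr <- sum(w); if (nr == 0) { w <- rep(1, m); nr <- m }
  cum_hit <- cumsum(w) / nr
  miss <- (pos - seq_len(m)) / (N - m)
  top <- cum_hit - miss
  bottom <- c(0, cum_hit[-m]) - miss
  if (es >= 0) seq_len(which.max(top)) else which.min(bottom):m
}

#' Aggregate GSEA results across contrasts
#'
#' Retains terms significant (FDR < \code{fdr_max}) in at least
#' \code{min_contrasts} of the supplied contrasts (at most the canonical
#' seven), attaching the per-contrast signed -log10 P matrix and its
#' cross-contrast mean -log10 P.
#'
#' @param results named list (per contrast) of \code{\link{preranked_gsea}}
#'   tables.
#' @param fdr_max significance threshold within a contrast (default 0.05).
#' @param min_contrasts minimum significant contrasts (default 4).
#' @return data frame: set_id, n_significant, mean_neg_log10_p, then one
#'   signed -log10 P column per contrast.
#' @export
aggregate_terms <- function(results, fdr_max = 0.05, min_contrasts = 4) {
  if (length(results) > 7L) stop("at most the seven canonical contrasts expected")
  all_sets <- sort(unique(unlist(lapply(results, `[[`, "set_id"))))
  sig <- matrix(FALSE, length(all_sets), length(results),
                dimnames = list(all_sets, names(results)))
  signedp <- matrix(NA_real_, length(all_sets), length(results),
                    dimnames = list(all_sets, names(results)))
  neglogp <- signedp
  for (lab in names(results)) {
    r <- results[[lab]]
    i <- match(r$set_id, all_sets)
    sig[i, lab] <- r$FDR < fdr_max
    signedp[i, lab] <- -log10(r$P) * sign(r$ES)
    neglogp[i, lab] <- -log10(r$P)
  }
  n_sig <- rowSums(sig, na.rm = TRUE)
  keep <- n_sig >= min_contrasts
  out <- data.frame(set_id = all_sets[keep],
                    n_significant = n_sig[keep],
                    mean_neg_log10_p = rowMeans(neglogp, na.rm = TRUE)[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(signedp[keep, , drop = FALSE], row.names = NULL))
}

#' Jaccard index between two sets
#' @param a,b character vectors.
#' @return |intersection| / |union|.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Cluster aggregated terms by gene overlap
#'
#' Builds a term graph with edges where the Jaccard index of member genes
#' reaches \code{jaccard_threshold}, clusters by connected components, and
#' names as representative the member with the highest mean -log10 P across
#' contrasts.
#'
#' @param aggregated \code{\link{aggregate_terms}} output.
#' @param sets the gene-set collection the terms come from.
#' @param jaccard_threshold minimum overlap for an edge (default 0.5).
#' @return List: \code{edges} (set_a, set_b, jaccard), \code{clusters}
#'   (named integer vector), \code{representatives} (one set id per
#'   cluster).
#' @export
cluster_terms <- function(aggregated, sets, jaccard_threshold = 0.5) {
  ids <- aggregated$set_id
  if (!length(ids)) stop("no aggregated terms to cluster")
  n <- length(ids)
  edges <- list()
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    jc <- jaccard_index(sets[[ids[i]]], sets[[ids[j]]])
    if (jc >= jaccard_threshold) {
      edges[[length(edges) + 1L]] <-
        data.frame(set_a = ids[i], set_b = ids[j], jaccard = jc,
                   stringsAsFactors = FALSE)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- match(roots, sort(unique(roots)))
  names(clusters) <- ids
  reps <- vapply(sort(unique(clusters)), function(cl) {
    members <- ids[clusters == cl]
    mp <- aggregated$mean_neg_log10_p[match(members, aggregated$set_id)]
    members[which.max(mp)]
  }, character(1))
  list(edges = if (length(edges)) do.call(rbind, edges)
       else data.frame(set_a = character(), set_b = character(),
                       jaccard = numeric(), stringsAsFactors = FALSE),
       clusters = clusters, representatives = reps)
}

#' Permutation-count null for the number of significant terms
#'
#' Repeatedly assigns uniform random ranking scores to the feature universe,
#' reruns preranked GSEA, and counts significant sets, yielding an empirical
#' probability of observing at least \code{observed_count} significant terms
#' by chance: \code{(1 + #[null >= observed]) / (n_perm + 1)}.
#'
#' @param universe feature ids to rank.
#' @param sets gene-set collection.
#' @param observed_count the observed number of significant terms.
#' @param n_perm outer permutations (default 1000; < 100 warns).
#' @param alpha per-set significance threshold (default 0.05).
#' @param significance "nominal" (default) or "fdr" P values.
#' @param inner_n_perm permutations inside each GSEA run (default 250).
#' @param min_size,max_size set-size bounds passed through.
#' @param seed RNG seed.
#' @return List: \code{p_value}, \code{null_counts} (length n_perm).
#' @export
permutation_count_null <- function(universe, sets, observed_count,
                                   n_perm = 1000, alpha = 0.05,
                                   significance = c("nominal", "fdr"),
                                   inner_n_perm = 250,
                                   min_size = 10, max_size = 500, seed = 1) {
  significance <- match.arg(significance)
  if (observed_count < 0) stop("observed_count must be >= 0")
  if (n_perm < 100) warning("fewer than 100 permutations gives a coarse null")
  counts <- vapply(seq_len(n_perm), function(b) {
    local_seed <- seed + b
    set.seed(local_seed)
    scores <- stats::runif(length(universe), -1, 1)
    names(scores) <- universe
    g <- preranked_gsea(scores, sets, n_perm = inner_n_perm,
                        min_size = min_size, max_size = max_size,
                        seed = local_seed)
    p <- if (significance == "nominal") g$P else g$FDR
    sum(p < alpha)
  }, numeric(1))
  list(p_value = (1 + sum(counts >= observed_count)) / (n_perm + 1),
       null_counts = counts)
}

#' Eigengene and module membership of a gene set
#'
#' The eigengene is the first principal component of the set members'
#' expression submatrix (each member centered and unit-variance scaled
#' across samples), oriented to correlate positively with the mean member
#' profile.  Module membership is the absolute Pearson correlation of each
#' member with the eigengene.
#'
#' @param expr log-scale \code{expr_matrix} or numeric matrix.
#' @param set character vector of member feature ids.
#' @return List: \code{eigengene} (named per sample), \code{membership}
#'   (named per member, in [0,1]), \code{explained_variance}.
#' @export
eigengene_membership <- function(expr, set) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  members <- intersect(set, rownames(x))
  if (!length(members)) stop("no set members present in the matrix")
  sub <- x[members, , drop = FALSE]
  if (length(members) == 1L) {
    warning("singleton set: eigengene is the standardized member profile")
    z <- as.numeric(scale(sub[1L, ]))
    names(z) <- colnames(x)
    return(list(eigengene = z,
                membership = stats::setNames(1, members),
                explained_variance = 1))
  }
  s <- apply(sub, 1L, stats::sd)
  s[s == 0] <- 1
  z <- sweep(sweep(sub, 1L, rowMeans(sub), "-"), 1L, s, "/")
  sv <- svd(z)
  eig <- sv$v[, 1L]
  mean_prof <- colMeans(z)
  # orientation is arbitrary when the mean member profile is flat
  if (stats::sd(mean_prof) > 0 && stats::cor(eig, mean_prof) < 0) eig <- -eig
  names(eig) <- colnames(x)
  membership <- apply(sub, 1L, function(row)
    if (stats::sd(row) == 0) 1 else abs(stats::cor(row, eig)))
  list(eigengene = eig, membership = membership,
       explained_variance = sv$d[1L]^2 / sum(sv$d^2))
}

#' Over-representation (hypergeometric) test
#'
#' One-sided hypergeometric tail P for enrichment of an annotation set in a
#' hit set within a universe, plus the 2x2 sample odds ratio.
#'
#' @param hits character vector (e.g. DIU genes).
#' @param annotation_set character vector (e.g. a GO term's genes).
#' @param universe background feature ids; both sets are intersected with it.
#' @return List: \code{p}, \code{odds_ratio}, \code{table} (2x2 counts).
#' @export
overrep_test <- function(hits, annotation_set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  hits <- intersect(unique(hits), universe)
  ann <- intersect(unique(annotation_set), universe)
  k <- length(intersect(hits, ann))
  K <- length(ann); n <- length(hits); N <- length(universe)
  p <- if (n == 0 || K == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2L, 2L,
                dimnames = list(c("hit", "not_hit"), c("in_set", "not_in_set")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(p, 1), odds_ratio = or, table = tab)
}
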