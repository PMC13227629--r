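# Gene-protein integration: pair matching and correlation summaries,
# detection of differentially regulated post-transcriptional events, and
# tree-ensemble regulator inference with eigengene targets.

#' Match proteins to genes and summarize pair correlations
#'
#' One pair per mapped protein; proteins mapping to more than one gene are
#' dropped with a warning (duplicating them would pseudo-replicate the
#' correlation summaries).  Spearman correlation is computed over the
#' samples shared by the two matrices.
#'
#' @param rna log2-CPM \code{expr_matrix}.
#' @param protein log2-intensity \code{expr_matrix} (complete).
#' @param mapping data frame with columns \code{gene_id}, \code{protein_id}.
#' @return data frame: gene_id, protein_id, spearman; attributes
#'   \code{"median_correlation"} and \code{"negative_fraction"}.
#' @export
match_pairs <- function(rna, protein, mapping) {
  stopifnot(all(c("gene_id", "protein_id") %in% names(mapping)))
  shared <- intersect(colnames(rna$values), colnames(protein$values))
  if (!length(shared)) stop("RNA and protein matrices share no samples")
  n_genes <- tapply(mapping$gene_id, mapping$protein_id,
                    function(g) length(unique(g)))
  multi <- names(n_genes)[n_genes > 1L]
  if (length(multi)) {
    warning(length(multi), " protein(s) mapping to multiple genes dropped")
    mapping <- mapping[!mapping$protein_id %in% multi, , drop = FALSE]
  }
  keep <- mapping$gene_id %in% rownames(rna$values) &
          mapping$protein_id %in% rownames(protein$values)
  mapping <- unique(mapping[keep, c("gene_id", "protein_id")])
  rho <- vapply(seq_len(nrow(mapping)), function(i)
    stats::cor(rna$values[mapping$gene_id[i], shared],
               protein$values[mapping$protein_id[i], shared],
               method = "spearman", use = "pairwise.complete.obs"),
    numeric(1))
  out <- data.frame(mapping, spearman = rho,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "median_correlation") <- stats::median(rho, na.rm = TRUE)
  attr(out, "negative_fraction") <- mean(rho < 0, na.rm = TRUE)
  out
}

#' Detect differentially regulated post-transcriptional events
#'
#' Per gene-protein pair, fits the ordinary least-squares model
#' \code{protein ~ gene + group} (protein log2 intensity on gene log2 CPM
#' plus a 0/1 genotype indicator, IC = 0, RTT = 1).  A pair is flagged when
#' the gene coefficient is significantly greater than 0 (one-sided) and the
#' group coefficient significantly different from 0 (two-sided), both at
#' FDR < \code{fdr_max} after Benjamini-Hochberg within each coefficient
#' family.
#'
#' @param pairs \code{\link{match_pairs}} output.
#' @param rna,protein the matrices the pairs refer to.
#' @param design \code{study_design} covering the shared samples.
#' @param fdr_max flagging threshold (default 0.05).
#' @return data frame: gene_id, protein_id, beta_gene, beta_group, p_gene
#'   (one-sided), p_group, fdr_gene, fdr_group, event.
#' @export
post_transcriptional_events <- function(pairs, rna, protein, design,
                                        fdr_max = 0.05) {
  shared <- intersect(colnames(rna$values), colnames(protein$values))
  shared <- intersect(shared, design$sample_id)
  if (length(shared) < 6L) stop("need >= 6 shared samples")
  grp <- as.integer(design$genotype[match(shared, design$sample_id)] == "RTT")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- rna$values[pairs$gene_id[i], shared]
    p <- protein$values[pairs$protein_id[i], shared]
    X <- cbind(1, g, grp)
    if (qr(X)$rank < 3L) {
      warning("collinear design for pair ", pairs$gene_id[i], "; skipped")
      return(NULL)
    }
    fit <- stats::lm.fit(X, p)
    df <- length(shared) - 3L
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(s2 * diag(xtx_inv))
    t_gene <- fit$coefficients[2L] / se[2L]
    t_grp <- fit$coefficients[3L] / se[3L]
    data.frame(gene_id = pairs$gene_id[i], protein_id = pairs$protein_id[i],
               beta_gene = unname(fit$coefficients[2L]),
               beta_group = unname(fit$coefficients[3L]),
               se_gene = se[2L], se_group = se[3L], df = df,
               p_gene = stats::pt(t_gene, df, lower.tail = FALSE),
               p_group = 2 * stats::pt(-abs(t_grp), df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_gene <- stats::p.adjust(out$p_gene, "BH")
  out$fdr_group <- stats::p.adjust(out$p_group, "BH")
  out$event <- out$fdr_gene < fdr_max & out$fdr_group < fdr_max
  out
}

#' Infer protein and lncRNA regulators of eigengene targets
#'
#' Fits, per target eigengene, a random-forest regression on the candidate
#' regulators' expression (GENIE3-style: impurity importance, sqrt(K)
#' candidates per split), normalizes importances to sum to 1 per target,
#' and keeps the top \code{top_fraction} of the candidate-by-target
#' importance pool per candidate class (default 5\% for TF proteins, 5
#' per mille for regulatory lncRNAs).
#'
#' @param eigengenes numeric matrix, targets (rows, named by set id) x
#'   samples — e.g. stacked \code{\link{eigengene_membership}} eigengenes.
#' @param candidates \code{expr_matrix} or matrix of candidate expression
#'   over the same samples.
#' @param classes named character vector over candidate ids with values
#'   \code{"TF-protein"} or \code{"regulatory-lncRNA"}.
#' @param top_fraction named numeric vector of retained fractions per class.
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed (forests are deterministic given it).
#' @return data frame of edges: regulator, target_set, weight, class,
#'   ordered by decreasing weight.
#' @export
infer_regulators <- function(eigengenes, candidates, classes,
                             top_fraction = c("TF-protein" = 0.05,
                                              "regulatory-lncRNA" = 0.005),
                             n_trees = 1000, seed = 1) {
  x <- if (inherits(candidates, "expr_matrix")) candidates$values
       else as.matrix(candidates)
  samples <- intersect(colnames(eigengenes), colnames(x))
  if (length(samples) < 4L) stop("too few shared samples")
  classes <- classes[intersect(names(classes), rownames(x))]
  edges <- list()
  for (cl in unique(classes)) {
    cand <- sort(names(classes)[classes == cl])
    if (length(cand) < 2L) {
      warning("class ", cl, " has < 2 candidates; skipped")
      next
    }
    feat <- t(x[cand, samples, drop = FALSE])
    imp <- matrix(0, length(cand), nrow(eigengenes),
                  dimnames = list(cand, rownames(eigengenes)))
    for (tg in rownames(eigengenes)) {
      y <- eigengenes[tg, samples]
      fit <- ranger::ranger(
        x = feat, y = y, num.trees = n_trees,
        mtry = max(1L, floor(sqrt(length(cand)))),
        importance = "impurity", num.threads = 1L, seed = seed)
      w <- fit$variable.importance[cand]
      w[w < 0 | is.na(w)] <- 0
      imp[, tg] <- if (sum(w) > 0) w / sum(w) else 0
    }
    pool <- data.frame(regulator = rep(cand, times = ncol(imp)),
                       target_set = rep(colnames(imp), each = nrow(imp)),
                       weight = as.vector(imp), class = cl,
                       stringsAsFactors = FALSE)
    frac <- top_fraction[[cl]]
    if (is.null(frac)) stop("no top_fraction for class ", cl)
    n_keep <- max(1L, floor(frac * nrow(pool)))
    ord <- order(-pool$weight, pool$regulator, pool$target_set)
    edges[[cl]] <- pool[ord[seq_len(n_keep)], , drop = FALSE]
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
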