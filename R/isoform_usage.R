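# Differential isoform usage: expression filters, effective-length-weighted
# relative abundance, and the cross-contrast exact Mann-Whitney rule.
#
# Isoform quantifications arrive in long format (RSEM-style): one row per
# gene_id / isoform_id / sample_id with a raw count and an effective length.

.check_quant <- function(quant) {
  req <- c("gene_id", "isoform_id", "sample_id", "count", "effective_length")
  miss <- setdiff(req, names(quant))
  if (length(miss)) stop("isoform table missing columns: ", paste(miss, collapse = ", "))
  if (any(quant$count < 0)) stop("negative isoform counts")
  if (any(quant$effective_length <= 0)) stop("effective lengths must be positive")
  quant
}

#' Filter isoforms by gene- and isoform-level expression
#'
#' Keeps an isoform iff its gene's total raw count exceeds
#' \code{min_gene_count} in every sample and the isoform's raw count
#' exceeds \code{min_isoform_count} in every RTT sample or in every IC
#' sample.
#'
#' @param quant long-format isoform table (gene_id, isoform_id, sample_id,
#'   count, effective_length).
#' @param design \code{study_design}.
#' @param min_gene_count gene-total threshold (default 50, strict >).
#' @param min_isoform_count isoform threshold (default 10, strict >).
#' @return Filtered isoform table.
#' @export
filter_isoforms <- function(quant, design, min_gene_count = 50,
                            min_isoform_count = 10) {
  quant <- .check_quant(quant)
  quant <- quant[quant$sample_id %in% design$sample_id, , drop = FALSE]
  gene_tot <- stats::aggregate(count ~ gene_id + sample_id, quant, sum)
  ok_gene <- tapply(gene_tot$count > min_gene_count, gene_tot$gene_id, all)
  n_samples <- length(unique(design$sample_id))
  n_per_gene <- table(gene_tot$gene_id)
  ok_gene <- ok_gene & (as.vector(n_per_gene[names(ok_gene)]) == n_samples)
  rtt <- design$sample_id[design$genotype == "RTT"]
  ic <- design$sample_id[design$genotype == "IC"]
  iso_ok <- vapply(split(quant, quant$isoform_id), function(d) {
    above <- d$sample_id[d$count > min_isoform_count]
    all(rtt %in% above) || all(ic %in% above)
  }, logical(1))
  keep <- ok_gene[quant$gene_id] & iso_ok[quant$isoform_id]
  quant[!is.na(keep) & keep, , drop = FALSE]
}

#' Effective-length-weighted relative isoform abundance
#'
#' Per gene and sample, the usage of isoform i is
#' \code{(count_i / efflen_i) / sum_j (count_j / efflen_j)} — the share of
#' the gene's transcript molecules attributed to that isoform.  Gene-sample
#' cells with no signal get \code{NA}.
#'
#' @param quant (filtered) isoform table.
#' @return The table with a \code{usage} column added.
#' @export
relative_abundance <- function(quant) {
  quant <- .check_quant(quant)
  rate <- quant$count / quant$effective_length
  key <- paste(quant$gene_id, quant$sample_id, sep = "\r")
  tot <- as.numeric(tapply(rate, key, sum)[key])
  quant$usage <- ifelse(tot > 0, rate / tot, NA_real_)
  quant
}

#' Call differential isoform usage across contrasts
#'
#' Per isoform and contrast, the RTT and IC usage fractions are compared
#' with the exact two-sided Mann-Whitney test; a gene is flagged DIU when
#' any of its isoforms attains P <= \code{alpha} in at least
#' \code{min_contrasts} of the canonical contrasts.
#'
#' @param quant isoform table with a \code{usage} column
#'   (\code{\link{relative_abundance}}).
#' @param design \code{study_design}.
#' @param alpha per-contrast P threshold (default 0.1, inclusive).
#' @param min_contrasts minimum passing contrasts (default 4).
#' @return List: \code{isoforms} (gene_id, isoform_id, n_passing, one P
#'   column per contrast), \code{diu_genes} (character vector).
#' @export
diu_call <- function(quant, design, alpha = 0.1, min_contrasts = 4) {
  if (!"usage" %in% names(quant)) stop("run relative_abundance first")
  contrasts <- enumerate_contrasts(design)
  iso_keys <- unique(quant[, c("gene_id", "isoform_id")])
  pmat <- matrix(NA_real_, nrow(iso_keys), length(contrasts),
                 dimnames = list(iso_keys$isoform_id, names(contrasts)))
  usage_by_iso <- split(quant[, c("sample_id", "usage")], quant$isoform_id)
  for (ct in contrasts) {
    if (length(ct$rtt_samples) < 2L || length(ct$ic_samples) < 2L) {
      warning("contrast ", ct$label, " has a group smaller than 2; skipped")
      next
    }
    for (i in seq_len(nrow(iso_keys))) {
      u <- usage_by_iso[[iso_keys$isoform_id[i]]]
      x <- u$usage[match(ct$rtt_samples, u$sample_id)]
      y <- u$usage[match(ct$ic_samples, u$sample_id)]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) next
      pmat[i, ct$label] <- mann_whitney_exact(x, y)$p
    }
  }
  n_pass <- rowSums(pmat <= alpha, na.rm = TRUE)
  iso <- data.frame(iso_keys, n_passing = n_pass,
                    stringsAsFactors = FALSE, row.names = NULL)
  iso <- cbind(iso, as.data.frame(pmat, row.names = NULL))
  flagged <- iso$n_passing >= min_contrasts
  list(isoforms = iso,
       diu_genes = sort(unique(iso$gene_id[flagged])))
}
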