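# Allele-specific expression: the ASE score, gene-level bi-allelic
# classification, and differential-ASE calling between genotypes.
#
# Allelic counts arrive in long format: one row per snp_id / gene_id /
# sample_id with reference and alternative read counts.  An ASE score of
# 0.5 means balanced bi-allelic expression; 1 means purely mono-allelic.

#' Allele-specific expression score
#'
#' The read fraction of the more highly expressed allele:
#' \code{max(ref, alt) / (ref + alt)}, in [0.5, 1].  Zero-coverage SNPs are
#' undefined (\code{NA}).
#'
#' @param ref_count,alt_count non-negative read counts (vectorized).
#' @return Numeric scores.
#' @export
ase_score <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("allelic counts must be non-negative")
  tot <- ref_count + alt_count
  ifelse(tot > 0, pmax(ref_count, alt_count) / tot, NA_real_)
}

.check_allelic <- function(table) {
  req <- c("snp_id", "gene_id", "sample_id", "ref_count", "alt_count")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("allelic table missing columns: ", paste(miss, collapse = ", "))
  gene_per_snp <- tapply(table$gene_id, table$snp_id, function(g) length(unique(g)))
  if (any(gene_per_snp > 1L))
    stop("snp mapped to multiple genes: ",
         names(gene_per_snp)[gene_per_snp > 1L][1L])
  table
}

#' Score an allelic count table
#'
#' @param table long-format allelic counts.
#' @return The table with an \code{ase} column added.
#' @export
score_allelic_table <- function(table) {
  table <- .check_allelic(table)
  table$ase <- ase_score(table$ref_count, table$alt_count)
  table
}

# Qualification of a SNP within one genotype arm of one stratum: in every
# sample, score < score_max with both allele counts > min_allele_count.
.qualifying_strata <- function(snp_rows, samples_by_stratum,
                               score_max, min_allele_count) {
  vapply(samples_by_stratum, function(smp) {
    rows <- snp_rows[match(smp, snp_rows$sample_id), , drop = FALSE]
    if (anyNA(rows$sample_id) || nrow(rows) < length(smp)) return(FALSE)
    all(!is.na(rows$ase) & rows$ase < score_max &
        rows$ref_count > min_allele_count &
        rows$alt_count > min_allele_count)
  }, logical(1))
}

#' Classify genes as bi-allelically expressed per genotype
#'
#' A gene counts as bi-allelic in a genotype when some SNP shows an ASE
#' score below \code{score_max} with both allele counts above
#' \code{min_allele_count} in every sample of at least \code{min_contrasts}
#' strata (time point / region combinations).  With
#' \code{min_contrasts = 1} and a single-stratum design this reduces to the
#' whole-group validation variant.
#'
#' @param table scored allelic table (\code{\link{score_allelic_table}}).
#' @param design \code{study_design}.
#' @param score_max ASE ceiling (default 0.85, strict <).
#' @param min_allele_count per-allele read floor (default 5, strict >).
#' @param min_contrasts minimum qualifying strata (default 4).
#' @return data frame: gene_id, genotype, biallelic (logical; \code{NA}
#'   when no SNP of the gene has qualifying coverage anywhere).
#' @export
call_biallelic <- function(table, design, score_max = 0.85,
                           min_allele_count = 5, min_contrasts = 4) {
  if (!"ase" %in% names(table)) table <- score_allelic_table(table)
  out <- list()
  for (gt in c("RTT", "IC")) {
    d <- design[design$genotype == gt, , drop = FALSE]
    strata <- split(d$sample_id, stratum_label(d$day, d$region))
    tab <- table[table$sample_id %in% d$sample_id, , drop = FALSE]
    for (g in unique(table$gene_id)) {
      rows <- tab[tab$gene_id == g, , drop = FALSE]
      if (!nrow(rows)) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, genotype = gt, biallelic = NA,
          stringsAsFactors = FALSE)
        next
      }
      qual_per_snp <- vapply(split(rows, rows$snp_id), function(sr)
        sum(.qualifying_strata(sr, strata, score_max, min_allele_count)),
        numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, genotype = gt,
        biallelic = any(qual_per_snp >= min_contrasts),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Per-sample gene-level ASE summary: the maximum score over the gene's
# covered SNPs in that sample.
.gene_sample_score <- function(rows, samples) {
  vapply(samples, function(s) {
    sc <- rows$ase[rows$sample_id == s]
    sc <- sc[!is.na(sc)]
    if (length(sc)) max(sc) else NA_real_
  }, numeric(1))
}

#' Differential allele-specific expression between genotypes
#'
#' For genes bi-allelic in at least one genotype, per-sample gene-level ASE
#' scores (maximum over covered SNPs) are compared between RTT and IC with
#' the exact two-sided Mann-Whitney test in each stratum; a gene is flagged
#' when P <= \code{alpha} in at least \code{min_contrasts} strata.
#'
#' @param table scored allelic table.
#' @param flags \code{\link{call_biallelic}} output.
#' @param design \code{study_design}.
#' @param alpha per-stratum P threshold (default 0.1, inclusive).
#' @param min_contrasts minimum passing strata (default 4; use 1 for the
#'   single-comparison validation variant).
#' @return data frame: gene_id, n_passing, differential_ase.
#' @export
differential_ase <- function(table, flags, design, alpha = 0.1,
                             min_contrasts = 4) {
  if (!"ase" %in% names(table)) table <- score_allelic_table(table)
  bi_any <- tapply(flags$biallelic, flags$gene_id,
                   function(b) any(b %in% TRUE))
  genes <- names(bi_any)[bi_any]
  contrasts <- enumerate_contrasts(design)
  out <- lapply(genes, function(g) {
    rows <- table[table$gene_id == g, , drop = FALSE]
    n_pass <- 0L
    for (ct in contrasts) {
      x <- .gene_sample_score(rows, ct$rtt_samples)
      y <- .gene_sample_score(rows, ct$ic_samples)
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) next
      if (mann_whitney_exact(x, y)$p <= alpha) n_pass <- n_pass + 1L
    }
    data.frame(gene_id = g, n_passing = n_pass,
               differential_ase = n_pass >= min_contrasts,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(gene_id = character(), n_passing = integer(),
                      differential_ase = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
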