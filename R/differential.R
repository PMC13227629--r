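# Per-contrast differential statistics, the signed -log10 P ranking score,
# and the declarative marker-selection rules.
#
# One moderated linear-model engine serves both omics layers: log2-CPM for
# RNA and imputed log2 intensities for protein.  Per feature, a two-group
# fit with empirical-Bayes variance moderation (prior variance and prior
# degrees of freedom pooled across all features) yields a moderated t and a
# two-sided P value; FDR is Benjamini-Hochberg within the contrast.

#' Fit a two-group moderated model for one contrast
#'
#' @param expr log-scale \code{expr_matrix} (log2cpm or log2intensity,
#'   no missing values).
#' @param contrast one element of \code{\link{enumerate_contrasts}}.
#' @param prior_df empirical-Bayes prior degrees of freedom. \code{NULL}
#'   (default) estimates prior df and prior variance from all features
#'   (via \code{limma::squeezeVar}); \code{0} disables moderation, giving
#'   the ordinary two-sample t-test on equal variances.
#' @return data frame (one row per feature): \code{feature_id},
#'   \code{log2FC} (RTT minus IC), \code{t}, \code{P}, \code{FDR},
#'   \code{ranking}; attribute \code{"contrast"} holds the label.
#' @export
fit_contrast <- function(expr, contrast, prior_df = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  x <- expr$values
  if (anyNA(x)) stop("fit_contrast needs a complete matrix (impute first)")
  g1 <- contrast$rtt_samples; g2 <- contrast$ic_samples
  missing <- setdiff(c(g1, g2), colnames(x))
  if (length(missing)) stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m1 - m2
  df <- n1 + n2 - 2L
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / df
  if (is.null(prior_df)) {
    sq <- limma::squeezeVar(s2, df)
    s2_post <- sq$var.post
    df_total <- df + sq$df.prior
  } else if (prior_df == 0) {
    s2_post <- s2
    df_total <- rep(df, length(s2))
  } else {
    s2_prior <- stats::median(s2)
    s2_post <- (prior_df * s2_prior + df * s2) / (prior_df + df)
    df_total <- rep(df + prior_df, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tt), df = pmin(df_total, 1e6)), 1)
  p[lfc == 0 & s2 == 0] <- 1
  res <- data.frame(feature_id = rownames(x), log2FC = lfc, t = tt, P = p,
                    FDR = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$ranking <- ranking_score(res$P, res$log2FC)
  attr(res, "contrast") <- contrast$label
  res
}

#' Fit all canonical contrasts
#'
#' @param expr log-scale \code{expr_matrix}.
#' @param design \code{study_design}.
#' @param ... passed to \code{\link{fit_contrast}}.
#' @return Named list of per-contrast result tables.
#' @export
fit_all_contrasts <- function(expr, design, ...) {
  contrasts <- enumerate_contrasts(design)
  lapply(contrasts, function(ct) fit_contrast(expr, ct, ...))
}

#' Signed -log10 P ranking score
#'
#' The gene-ordering statistic fed to preranked GSEA:
#' \code{-log10(P) * sgn(log2FC)}.  P values below the double-precision
#' floor are capped with a warning; a zero fold change gives score 0.
#'
#' @param P nominal P values in (0, 1].
#' @param log2FC log2 fold changes.
#' @return Numeric scores.
#' @export
ranking_score <- function(P, log2FC) {
  if (any(P <= 0)) stop("P values must be > 0")
  if (any(P < .Machine$double.xmin)) {
    warning("P value(s) below machine floor capped")
    P <- pmax(P, .Machine$double.xmin)
  }
  -log10(P) * sign(log2FC)
}

#' Call differentially expressed features
#'
#' FDR-adjusted P < \code{fdr_max} and |log2FC| > \code{min_abs_lfc}, both
#' strict, as in the study's definition of a differential call.
#'
#' @param result a \code{\link{fit_contrast}} table.
#' @param fdr_max FDR threshold (default 0.05, strict \code{<}).
#' @param min_abs_lfc absolute log2FC threshold (default 1, strict \code{>}).
#' @return Character vector of feature ids.
#' @export
call_deg <- function(result, fdr_max = 0.05, min_abs_lfc = 1) {
  result$feature_id[result$FDR < fdr_max & abs(result$log2FC) > min_abs_lfc]
}

#' Define a marker-selection rule
#'
#' A rule names the contrasts where a feature must be differentially
#' expressed (at \code{fdr_max}/\code{min_abs_lfc}), the contrasts where it
#' must look null (nominal P above \code{null_p_min}), whether the direction
#' of effect must agree across significant contrasts, and how many
#' significant contrasts are required.
#'
#' @param id rule identifier.
#' @param sig_contrasts contrast labels eligible to count as significant
#'   (\code{"any"} = all seven).
#' @param min_significant minimum number of significant contrasts.
#' @param fdr_max,min_abs_lfc differential thresholds within the rule.
#' @param null_contrasts contrast labels that must look unchanged.
#' @param null_p_min nominal-P floor for the null contrasts.
#' @param require_all_sig if TRUE, every contrast in \code{sig_contrasts}
#'   must individually be significant.
#' @param consistent_direction require one sign across significant contrasts.
#' @return A \code{marker_rule} list.
#' @export
marker_rule <- function(id, sig_contrasts = "any", min_significant = 1,
                        fdr_max = 0.05, min_abs_lfc = 1,
                        null_contrasts = character(), null_p_min = 0.1,
                        require_all_sig = FALSE,
                        consistent_direction = TRUE) {
  stopifnot(fdr_max > 0, min_abs_lfc >= 0, null_p_min >= 0)
  structure(list(id = id, sig_contrasts = sig_contrasts,
                 min_significant = min_significant, fdr_max = fdr_max,
                 min_abs_lfc = min_abs_lfc, null_contrasts = null_contrasts,
                 null_p_min = null_p_min, require_all_sig = require_all_sig,
                 consistent_direction = consistent_direction),
            class = "marker_rule")
}

#' Built-in marker rules
#'
#' \code{overall}: differentially expressed with a consistent direction of
#' effect in at least six of the seven contrasts.  \code{transient_d13}:
#' differentially expressed at both day-13 contrasts while unchanged
#' (nominal P > 0.1) at every day-40 and day-75 contrast.
#'
#' @return Named list of \code{marker_rule} objects.
#' @export
builtin_marker_rules <- function() {
  list(
    overall = marker_rule("overall", sig_contrasts = "any",
                          min_significant = 6, consistent_direction = TRUE),
    transient_d13 = marker_rule(
      "transient_d13",
      sig_contrasts = c("D13-dorsal", "D13-ventral"), min_significant = 2,
      require_all_sig = TRUE,
      null_contrasts = c("D40-dorsal", "D40-ventral",
                         "D75-dorsal", "D75-ventral"),
      null_p_min = 0.1, consistent_direction = TRUE)
  )
}

#' Select marker features by rule
#'
#' @param results named list of \code{\link{fit_contrast}} tables covering
#'   every contrast the rule references.
#' @param rule a \code{\link{marker_rule}}.
#' @return data frame: \code{feature_id}, \code{rule},
#'   \code{n_significant}, \code{direction}.
#' @export
select_markers <- function(results, rule) {
  stopifnot(inherits(rule, "marker_rule"))
  labels <- names(results)
  sig_labels <- if (identical(rule$sig_contrasts, "any")) labels
                else rule$sig_contrasts
  missing <- setdiff(c(sig_labels, rule$null_contrasts), labels)
  if (length(missing))
    stop("rule references missing contrast(s): ", paste(missing, collapse = ", "))
  feats <- results[[1L]]$feature_id
  for (r in results) stopifnot(identical(r$feature_id, feats))
  sig <- sapply(sig_labels, function(lab) {
    r <- results[[lab]]
    r$FDR < rule$fdr_max & abs(r$log2FC) > rule$min_abs_lfc
  })
  sig <- matrix(sig, nrow = length(feats),
                dimnames = list(feats, sig_labels))
  signs <- sapply(sig_labels, function(lab) sign(results[[lab]]$log2FC))
  signs <- matrix(signs, nrow = length(feats))
  n_sig <- rowSums(sig)
  ok <- n_sig >= rule$min_significant
  if (rule$require_all_sig) ok <- ok & rowSums(sig) == length(sig_labels)
  if (rule$consistent_direction) {
    sgn_sig <- signs * sig
    consistent <- abs(rowSums(sgn_sig)) == n_sig
    ok <- ok & consistent
  }
  for (lab in rule$null_contrasts) {
    r <- results[[lab]]
    ok <- ok & r$P > rule$null_p_min
  }
  dir <- ifelse(rowSums(signs * sig) > 0, "up",
                ifelse(rowSums(signs * sig) < 0, "down", "none"))
  data.frame(feature_id = feats[ok], rule = rule$id,
             n_significant = n_sig[ok], direction = dir[ok],
             stringsAsFactors = FALSE, row.names = NULL)
}
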