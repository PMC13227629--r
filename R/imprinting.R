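# Imprinted-gene statistics: Fisher odds of differential expression,
# cross-study random-effects pooling of log odds ratios, and promoter
# (TSS-window) tag-count enrichment with a random-gene-set envelope.

#' Odds of differential expression for imprinted genes
#'
#' Two-sided Fisher exact test on the 2x2 table of imprinted status against
#' differential-expression status over the QC-passing universe, with the
#' conditional-MLE odds ratio and its exact confidence interval.
#'
#' @param de_genes character vector of differentially expressed feature ids
#'   for one contrast (already filtered by direction if desired).
#' @param universe all QC-passing feature ids.
#' @param annotation feature annotation with \code{is_imprinted}.
#' @param direction \code{"either"} (default), \code{"up"} or \code{"down"};
#'   recorded in the result (the caller supplies direction-filtered
#'   \code{de_genes}).
#' @return List: table (2x2), odds_ratio, conf_int, p, direction.
#' @export
imprinted_de_odds <- function(de_genes, universe, annotation,
                              direction = "either") {
  universe <- unique(universe)
  imprinted <- annotation$feature_id[annotation$is_imprinted %in% TRUE]
  imprinted <- intersect(imprinted, universe)
  if (!length(imprinted)) stop("no imprinted genes in the universe")
  de <- intersect(unique(de_genes), universe)
  a <- length(intersect(de, imprinted))
  b <- length(imprinted) - a
  cc <- length(de) - a
  d <- length(universe) - length(imprinted) - cc
  tab <- matrix(c(a, b, cc, d), 2L, 2L,
                dimnames = list(c("DE", "notDE"),
                                c("imprinted", "not_imprinted")))
  if (!length(de))
    return(list(table = tab, odds_ratio = NA_real_,
                conf_int = c(NA_real_, NA_real_), p = 1,
                direction = direction))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate),
       conf_int = ft$conf.int, p = ft$p.value, direction = direction)
}

#' Random-effects pooling of study log odds ratios
#'
#' Inverse-variance random-effects meta-analysis with the between-study
#' variance estimated by restricted maximum likelihood (iterative, tolerance
#' 1e-8, at most 100 iterations) and the Hartung-Knapp adjustment: the
#' pooled standard error is the weighted residual variance and the
#' confidence interval and test use the t distribution on k - 1 degrees of
#' freedom.
#'
#' @param log_or per-study log odds ratios.
#' @param se per-study standard errors (positive).
#' @param conf_level confidence level (default 0.95).
#' @return List: estimate (pooled log OR), se, tau2, conf_int, p, k.
#' @export
pool_meta <- function(log_or, se, conf_level = 0.95) {
  k <- length(log_or)
  if (k < 2L) stop("need >= 2 studies")
  if (length(se) != k) stop("log_or and se lengths differ")
  if (any(se <= 0)) stop("standard errors must be positive")
  v <- se^2
  tau2 <- max(0, stats::var(log_or) - mean(v))  # starting value
  for (iter in seq_len(100L)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * log_or) / sum(w)
    # REML fixed-point update under the current weights
    tau2_new <- max(0, sum(w^2 * ((log_or - mu)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (abs(tau2_new - tau2) < 1e-8) { tau2 <- tau2_new; break }
    tau2 <- tau2_new
  }
  w <- 1 / (v + tau2)
  mu <- sum(w * log_or) / sum(w)
  # Hartung-Knapp variance
  q <- sum(w * (log_or - mu)^2) / (k - 1)
  se_hk <- sqrt(q / sum(w))
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = k - 1)
  if (se_hk == 0) {
    p <- if (mu == 0) 1 else 0
    ci <- c(mu, mu)
  } else {
    p <- 2 * stats::pt(-abs(mu / se_hk), df = k - 1)
    ci <- mu + c(-1, 1) * tcrit * se_hk
  }
  list(estimate = mu, se = se_hk, tau2 = tau2, conf_int = ci, p = p, k = k)
}

#' Promoter tag-count enrichment for imprinted genes
#'
#' Computes per-gene mean tag counts over the TSS +/- \code{window}
#' interval, compares imprinted against non-imprinted genes with the Welch
#' two-sample t-test, and builds a permutation envelope from the mean
#' profiles of random gene sets of the imprinted-set size.
#'
#' @param profiles numeric matrix, genes x bins, of tag counts covering the
#'   window; column names are bin offsets (bp, window start relative to
#'   TSS).
#' @param annotation feature annotation with \code{is_imprinted}; genes
#'   missing profiles are excluded (count logged via message).
#' @param n_random_sets envelope draws (default 100).
#' @param seed RNG seed for the envelope.
#' @return List: gene_means (named), mean_imprinted, mean_other, t, p,
#'   envelope (n_random_sets x bins matrix of random-set mean profiles).
#' @export
tss_enrichment <- function(profiles, annotation, n_random_sets = 100,
                           seed = 1) {
  imprinted <- annotation$feature_id[annotation$is_imprinted %in% TRUE]
  missing <- setdiff(imprinted, rownames(profiles))
  covered <- intersect(annotation$feature_id, rownames(profiles))
  n_excluded <- length(setdiff(annotation$feature_id, covered))
  if (n_excluded) message(n_excluded, " gene(s) without profiles excluded")
  imprinted <- intersect(imprinted, covered)
  others <- setdiff(covered, imprinted)
  if (!length(imprinted) || !length(others))
    stop("need both imprinted and non-imprinted genes with profiles")
  gene_means <- rowMeans(profiles[covered, , drop = FALSE])
  xi <- gene_means[imprinted]; xo <- gene_means[others]
  if (stats::sd(c(xi, xo)) == 0) {
    t_stat <- 0; p <- 1
  } else {
    tst <- stats::t.test(xi, xo)
    t_stat <- unname(tst$statistic); p <- tst$p.value
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  env <- t(vapply(seq_len(n_random_sets), function(b) {
    draw <- sample(covered, length(imprinted))
    colMeans(profiles[draw, , drop = FALSE])
  }, numeric(ncol(profiles))))
  colnames(env) <- colnames(profiles)
  list(gene_means = gene_means, mean_imprinted = mean(xi),
       mean_other = mean(xo), t = t_stat, p = p, envelope = env)
}
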