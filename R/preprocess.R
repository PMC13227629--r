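# Normalization, filtering and imputation for the RNA and protein layers.

#' Counts per million
#'
#' Plain CPM on (optionally scale-factor-corrected) library sizes; each
#' column sums to 1e6.
#'
#' @param counts \code{expr_matrix} of raw counts or a count matrix.
#' @param factors optional named scale factors (e.g. TMM) applied to the
#'   library sizes.
#' @return Numeric CPM matrix.
#' @export
cpm <- function(counts, factors = NULL) {
  x <- if (inherits(counts, "expr_matrix")) counts$values else as.matrix(counts)
  lib <- colSums(x)
  if (!is.null(factors)) lib <- lib * factors[colnames(x)]
  if (any(lib == 0)) stop("sample with zero library size")
  sweep(x, 2L, lib, "/") * 1e6
}

#' Filter lowly expressed genes by unnormalized CPM
#'
#' Keeps genes whose counts-per-million (computed on raw library sizes,
#' before any scale-factor correction) exceed \code{min_cpm} in at least
#' \code{min_samples} samples.
#'
#' @param counts \code{expr_matrix} with \code{raw_count} semantics.
#' @param min_cpm CPM threshold (default 10).
#' @param min_samples minimum number of samples above threshold (default 3).
#' @return Filtered \code{expr_matrix}.
#' @export
filter_expressed <- function(counts, min_cpm = 10, min_samples = 3) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$semantics != "raw_count") stop("filter_expressed expects raw counts")
  keep <- rowSums(cpm(counts) > min_cpm) >= min_samples
  if (!any(keep))
    stop("no genes pass the expression filter; review min_cpm/min_samples")
  expr_matrix(counts$values[keep, , drop = FALSE], "raw_count")
}

#' Remove features on given chromosomes
#'
#' The active X chromosome differs between the RTT and IC lines, making
#' X-linked differential calls unreliable; X genes are therefore excluded
#' before normalization factors are estimated.
#'
#' @param mat an \code{expr_matrix}.
#' @param annotation feature annotation with \code{feature_id} and
#'   \code{chromosome}; must cover every feature of \code{mat}.
#' @param chromosomes chromosomes to drop (default \code{"X"}).
#' @return \code{expr_matrix} without the listed chromosomes.
#' @export
exclude_chromosome <- function(mat, annotation, chromosomes = "X") {
  stopifnot(inherits(mat, "expr_matrix"))
  ids <- rownames(mat$values)
  missing <- setdiff(ids, annotation$feature_id)
  if (length(missing))
    stop("features without annotation: ", paste(utils::head(missing, 5), collapse = ", "))
  if (!length(chromosomes)) return(mat)
  chr <- annotation$chromosome[match(ids, annotation$feature_id)]
  keep <- !(chr %in% chromosomes)
  expr_matrix(mat$values[keep, , drop = FALSE], mat$semantics,
              missing_allowed = mat$missing_allowed)
}

# Per-sample 75th-percentile CPM; used to pick the TMM reference column.
.quantile_factor <- function(x, lib, p = 0.75) {
  apply(x, 2L, function(col) stats::quantile(col, p = p)) / lib
}

# Scale factor of one sample against the reference column, by the trimmed
# mean of M-values: log-ratios trimmed by `logratio_trim`, log-abundances by
# `sum_trim`, remaining M values combined with inverse asymptotic-variance
# weights.
.tmm_pair <- function(obs, ref, n_obs, n_ref,
                      logratio_trim = 0.30, sum_trim = 0.05) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' TMM normalization factors and log2-CPM
#'
#' Computes trimmed-mean-of-M-values scale factors (log-ratio trim 0.30,
#' abundance trim 0.05; reference = sample whose 75th-percentile CPM is
#' closest to the mean) and the log2 counts-per-million on effective
#' library sizes with a library-size-scaled prior count.
#'
#' @param counts filtered \code{expr_matrix} of raw counts.
#' @param logratio_trim,sum_trim trim fractions of the M and A values.
#' @param prior_count pseudo-count added before the log (default 2),
#'   scaled per sample by effective library size.
#' @return List with \code{factors} (named, rescaled to geometric mean 1),
#'   \code{reference_sample}, and \code{log2cpm} (\code{expr_matrix}).
#' @export
tmm_normalize <- function(counts, logratio_trim = 0.30, sum_trim = 0.05,
                          prior_count = 2) {
  stopifnot(inherits(counts, "expr_matrix"))
  x <- counts$values
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample with zero library size")
  f75 <- .quantile_factor(x, lib)
  ref_col <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j)
    .tmm_pair(x[, j], x[, ref_col], lib[j], lib[ref_col],
              logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  eff_lib <- lib * f
  pc <- prior_count * eff_lib / mean(eff_lib)
  lcpm <- log2(sweep(sweep(x, 2L, pc, "+"), 2L, eff_lib + 2 * pc, "/") * 1e6)
  list(factors = f,
       reference_sample = colnames(x)[ref_col],
       log2cpm = expr_matrix(lcpm, "log2cpm"))
}

# Group key for proteomics rules: genotype x region x day stratum.
.protein_groups <- function(design) {
  paste(design$genotype, stratum_label(design$day, design$region), sep = ".")
}

#' Filter proteins by group-wise presence
#'
#' Retains proteins quantified in at least \code{min_reps} replicates of at
#' least one experimental group (genotype x region x day).  Sex-chromosome
#' proteins are removed first when annotation is supplied.
#'
#' @param intensities \code{expr_matrix} of log-intensities with missing
#'   values allowed.
#' @param design matching \code{study_design}.
#' @param min_reps replicate threshold (default 2).
#' @param annotation optional annotation for sex-chromosome removal.
#' @param sex_chromosomes chromosomes stripped before the presence filter.
#' @return Filtered \code{expr_matrix}.
#' @export
filter_proteins <- function(intensities, design, min_reps = 2,
                            annotation = NULL,
                            sex_chromosomes = c("X", "Y")) {
  stopifnot(inherits(intensities, "expr_matrix"))
  if (!is.null(annotation))
    intensities <- exclude_chromosome(intensities, annotation, sex_chromosomes)
  x <- intensities$values[, design$sample_id, drop = FALSE]
  grp <- .protein_groups(design)
  obs_per_group <- sapply(split(seq_along(grp), grp), function(idx)
    rowSums(!is.na(x[, idx, drop = FALSE])))
  keep <- apply(obs_per_group, 1L, max) >= min_reps
  expr_matrix(intensities$values[keep, , drop = FALSE], intensities$semantics,
              missing_allowed = TRUE)
}

#' Variance-stabilizing normalization (robust affine + glog)
#'
#' Per-sample affine calibration on the log scale — median/MAD alignment to
#' a pseudo-reference built from feature medians — followed by a
#' generalized-log transform on the calibrated linear intensities,
#' \code{glog2(y) = log2((y + sqrt(y^2 + a^2)) / 2)} with the offset
#' \code{a} set to a low quantile of the calibrated intensities.  The glog
#' is linear near zero and logarithmic for large intensities, so additive
#' low-intensity noise no longer inflates the log-scale variance.  This is
#' a deterministic, dependency-light variance stabilizer sharing the
#' calibrate-then-glog structure of classical VSN.
#'
#' @param intensities filtered \code{expr_matrix} of log2 intensities,
#'   missing allowed.
#' @param offset_quantile quantile of the calibrated linear intensities used
#'   as the glog offset (default 0.05).
#' @return \code{expr_matrix} of stabilized log2-scale intensities.
#' @export
vsn_normalize <- function(intensities, offset_quantile = 0.05) {
  stopifnot(inherits(intensities, "expr_matrix"))
  x <- intensities$values
  if (any(colSums(!is.na(x)) == 0)) stop("sample with no observed intensities")
  ref <- apply(x, 1L, stats::median, na.rm = TRUE)
  cal <- x
  for (j in seq_len(ncol(x))) {
    obs <- which(!is.na(x[, j]) & !is.na(ref))
    s_med <- stats::median(x[obs, j])
    s_mad <- stats::mad(x[obs, j])
    r_med <- stats::median(ref[obs])
    r_mad <- stats::mad(ref[obs])
    scale_j <- if (s_mad > 0 && r_mad > 0) r_mad / s_mad else 1
    cal[, j] <- (x[, j] - s_med) * scale_j + r_med
  }
  lin <- 2^cal
  a <- stats::quantile(lin, offset_quantile, na.rm = TRUE, names = FALSE)
  out <- log2((lin + sqrt(lin^2 + a^2)) / 2)
  expr_matrix(out, "log2intensity", missing_allowed = TRUE)
}

#' Classify missingness as MAR, MNAR or complete
#'
#' A protein missing in all replicates of at least one experimental group is
#' treated as missing-not-at-random (left-censored by the detection limit);
#' any other missing pattern is missing-at-random; otherwise complete.
#'
#' @param intensities filtered \code{expr_matrix}.
#' @param design matching \code{study_design}.
#' @return Named character vector over proteins with values
#'   \code{"MNAR"}, \code{"MAR"}, \code{"complete"}.
#' @export
classify_missingness <- function(intensities, design) {
  x <- intensities$values[, design$sample_id, drop = FALSE]
  grp <- .protein_groups(design)
  all_missing_somewhere <- Reduce(`|`, lapply(split(seq_along(grp), grp),
    function(idx) rowSums(!is.na(x[, idx, drop = FALSE])) == 0))
  cls <- ifelse(all_missing_somewhere, "MNAR",
                ifelse(rowSums(is.na(x)) > 0, "MAR", "complete"))
  names(cls) <- rownames(x)
  cls
}

# kNN over protein profiles: neighbors ranked by Euclidean distance on
# shared observed samples.
.knn_impute_row <- function(i, x, k) {
  target <- x[i, ]
  need <- which(is.na(target))
  obs <- which(!is.na(target))
  d <- vapply(seq_len(nrow(x)), function(j) {
    if (j == i) return(Inf)
    shared <- obs[!is.na(x[j, obs])]
    if (length(shared) < 2L) return(Inf)
    sqrt(mean((target[shared] - x[j, shared])^2))
  }, numeric(1))
  for (s in need) {
    cand <- which(is.finite(d) & !is.na(x[, s]))
    if (!length(cand)) next
    nb <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
    target[s] <- mean(x[nb, s])
  }
  target
}

#' Mixed imputation of missing protein intensities
#'
#' Missing-at-random cells are imputed by k-nearest-neighbor averaging over
#' protein profiles; missing-not-at-random cells are drawn from a
#' left-truncated normal fitted to the host sample's low-intensity tail
#' (location = the sample's \code{censor_quantile} quantile, scale = the
#' sample's MAD), i.e. values plausible below the detection limit.
#'
#' @param intensities normalized \code{expr_matrix} with missing cells.
#' @param classification output of \code{\link{classify_missingness}}.
#' @param k neighbors for MAR imputation (default 10).
#' @param censor_quantile quantile bounding MNAR draws (default 0.01).
#' @param seed seed for the stochastic MNAR draws (default 0).
#' @return Complete \code{expr_matrix}; observed cells are never altered.
#' @export
impute_mixed <- function(intensities, classification, k = 10,
                         censor_quantile = 0.01, seed = 0) {
  stopifnot(inherits(intensities, "expr_matrix"))
  x <- intensities$values
  if (!all(rownames(x) %in% names(classification)))
    stop("classification must cover every protein")
  cls <- classification[rownames(x)]
  if (!anyNA(x))
    return(expr_matrix(x, intensities$semantics, missing_allowed = FALSE))
  out <- x
  mar_rows <- which(cls == "MAR" & rowSums(is.na(x)) > 0)
  if (length(mar_rows)) {
    complete_rows <- sum(rowSums(is.na(x)) == 0)
    if (complete_rows < k)
      warning("fewer than k complete neighbor profiles; kNN falls back to row medians where needed")
    for (i in mar_rows) out[i, ] <- .knn_impute_row(i, x, k)
    # rows kNN could not serve fall back to the row median
    still <- which(is.na(out) & row(out) %in% mar_rows)
    if (length(still)) {
      rmed <- apply(x, 1L, stats::median, na.rm = TRUE)
      out[still] <- rmed[row(out)[still]]
    }
  }
  mnar_rows <- which(cls == "MNAR")
  if (length(mnar_rows)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    for (j in seq_len(ncol(x))) {
      rows <- mnar_rows[is.na(x[mnar_rows, j])]
      if (!length(rows)) next
      obs <- x[!is.na(x[, j]), j]
      mu <- stats::quantile(obs, censor_quantile, names = FALSE)
      sd_j <- max(stats::mad(obs), 1e-8)
      # left tail of N(mu, sd) truncated above at mu
      u <- stats::runif(length(rows), 0, 0.5)
      out[rows, j] <- mu + sd_j * stats::qnorm(u)
    }
  }
  stopifnot(all(out[!is.na(x)] == x[!is.na(x)]))
  expr_matrix(out, intensities$semantics, missing_allowed = anyNA(out))
}

#' Z-score a marker panel
#'
#' Unit-variance scaling of each gene row across samples (population
#' variance, so a scaled row has mean 0 and mean square 1); constant rows
#' become zeros with a warning.
#'
#' @param mat \code{expr_matrix} or numeric matrix on a log scale.
#' @param genes rows to scale (default all).
#' @return Numeric matrix of z-scores.
#' @export
zscore_panel <- function(mat, genes = NULL) {
  x <- if (inherits(mat, "expr_matrix")) mat$values else as.matrix(mat)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss)) stop("genes not in matrix: ", paste(miss, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  mu <- rowMeans(x)
  s <- sqrt(rowMeans(sweep(x, 1L, mu, "-")^2))
  zero <- s == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) set to zeros")
    s[zero] <- 1
  }
  z <- sweep(sweep(x, 1L, mu, "-"), 1L, s, "/")
  z[zero, ] <- 0
  z
}
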