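# Core containers and text-format I/O for the organoid multi-omics pipeline.
#
# The study design is a 2-genotype (RTT vs isogenic control, "IC") x
# region/time layout: iPSC at day 0 plus dorsal/ventral forebrain organoids
# at days 13, 40 and 75, with replicate cultures per stratum.  Day-0 samples
# are shared between the two regional arms, so a full design yields exactly
# seven RTT-vs-IC contrasts.

VALID_GENOTYPES <- c("RTT", "IC")
VALID_REGIONS <- c("dorsal", "ventral", "iPSC")
VALID_DAYS <- c(0L, 13L, 40L, 75L)
VALID_SEMANTICS <- c("raw_count", "cpm", "log2cpm", "log2intensity")

#' Construct and validate a study design
#'
#' A study design records, per sample, the genotype (\code{"RTT"} mutant or
#' \code{"IC"} isogenic control), the organoid region (\code{"dorsal"},
#' \code{"ventral"}, or \code{"iPSC"} for undifferentiated day-0 cultures),
#' the differentiation day (0, 13, 40 or 75) and a replicate index.
#'
#' @param samples data frame with columns \code{sample_id}, \code{genotype},
#'   \code{region}, \code{day}, \code{replicate}.
#' @return A validated \code{study_design} data frame.
#' @export
study_design <- function(samples) {
  req <- c("sample_id", "genotype", "region", "day", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  d <- as.data.frame(samples)[req]
  d$sample_id <- as.character(d$sample_id)
  d$genotype <- as.character(d$genotype)
  d$region <- as.character(d$region)
  d$day <- as.integer(d$day)
  d$replicate <- as.integer(d$replicate)
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id: ", d$sample_id[duplicated(d$sample_id)][1L])
  if (!all(d$genotype %in% VALID_GENOTYPES))
    stop("genotype must be one of: ", paste(VALID_GENOTYPES, collapse = ", "))
  if (!all(d$region %in% VALID_REGIONS))
    stop("region must be one of: ", paste(VALID_REGIONS, collapse = ", "))
  if (!all(d$day %in% VALID_DAYS))
    stop("day must be one of: ", paste(VALID_DAYS, collapse = ", "))
  # day 0 and the iPSC label imply each other
  if (any((d$day == 0L) != (d$region == "iPSC")))
    stop("day 0 samples must (and only they may) carry region 'iPSC'")
  if (any(d$replicate < 1L)) stop("replicate indices must be positive")
  class(d) <- c("study_design", "data.frame")
  d
}

#' Read a study design table
#'
#' @param path TSV with columns sample_id, genotype, region, day, replicate.
#' @return A \code{study_design}.
#' @export
read_design <- function(path) {
  study_design(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Construct an expression matrix with declared value semantics
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param semantics one of \code{"raw_count"}, \code{"cpm"}, \code{"log2cpm"},
#'   \code{"log2intensity"}.
#' @param missing_allowed logical; whether \code{NA} entries are permitted
#'   (label-free proteomics intensities typically need this).
#' @return An \code{expr_matrix} object.
#' @export
expr_matrix <- function(values, semantics, missing_allowed = FALSE) {
  semantics <- match.arg(semantics, VALID_SEMANTICS)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must carry feature ids as rownames")
  if (is.null(colnames(values))) stop("values must carry sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (!is.numeric(values)) stop("values must be numeric")
  if (!missing_allowed && anyNA(values))
    stop("missing values present but missing_allowed = FALSE")
  if (semantics == "raw_count") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != floor(v)))
      stop("raw_count values must be non-negative integers")
  }
  structure(list(values = values, semantics = semantics,
                 missing_allowed = missing_allowed),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$semantics,
              if (anyNA(x$values)) sprintf(", %d missing cells", sum(is.na(x$values))) else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a delimited expression matrix
#'
#' First column holds feature ids, header row holds sample ids.
#'
#' @param path path to a tab-delimited text table.
#' @param semantics declared value semantics (see \code{\link{expr_matrix}}).
#' @param missing_allowed whether NA cells are tolerated.
#' @return An \code{expr_matrix}.
#' @export
read_matrix <- function(path, semantics, missing_allowed = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1L])
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1L], names(vals)[j], col[bad[1L]]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!missing_allowed && anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s' but missing_allowed = FALSE",
                 ids[idx[1L]], colnames(m)[idx[2L]]))
  }
  expr_matrix(m, semantics, missing_allowed = missing_allowed)
}

#' Write an expression matrix as TSV
#'
#' Inverse of \code{\link{read_matrix}} on values and labels.
#'
#' @param x an \code{expr_matrix}.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' @param path GMT path: per line, set id, description, then member ids.
#' @return Named list of character vectors (a gene-set collection); the
#'   description line is kept in \code{attr(, "set_names")}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  set_names <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required", i, length(f)))
    id <- f[1L]
    sets[[id]] <- unique(f[-(1:2)])
    set_names[id] <- f[2L]
  }
  if (anyDuplicated(names(sets))) stop("duplicate set id in GMT")
  attr(sets, "set_names") <- set_names
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "set_names")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(nm) && !is.na(nm[id])) nm[[id]] else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Columns: feature_id, symbol, chromosome, biotype, is_imprinted,
#' is_transcription_factor, is_regulatory_lncRNA, and optionally protein_id,
#' tss_position.
#'
#' @param path annotation TSV.
#' @return data frame keyed by unique \code{feature_id}.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(ann)) stop("annotation needs a feature_id column")
  if (anyDuplicated(ann$feature_id))
    stop("duplicate feature_id in annotation: ",
         ann$feature_id[duplicated(ann$feature_id)][1L])
  for (fl in c("is_imprinted", "is_transcription_factor", "is_regulatory_lncRNA"))
    if (fl %in% names(ann)) ann[[fl]] <- as.logical(ann[[fl]])
  ann
}

# Stratum key shared by every ">= k of 7" rule: day 0 collapses to "D0"
# because the iPSC comparison is common to both regional arms.
stratum_label <- function(day, region) {
  ifelse(day == 0L, "D0", paste0("D", day, "-", region))
}

CANONICAL_CONTRASTS <- c("D0", "D13-dorsal", "D13-ventral",
                         "D40-dorsal", "D40-ventral",
                         "D75-dorsal", "D75-ventral")

#' Enumerate the canonical RTT-vs-IC contrasts of a design
#'
#' One contrast per (day, region) stratum present in the design, with the
#' day-0 iPSC comparison collapsed to a single shared contrast.  A full
#' design therefore yields exactly seven contrasts, ordered by day with
#' dorsal before ventral.  Strata missing a genotype are dropped with a
#' warning.
#'
#' @param design a \code{study_design}.
#' @return List of contrasts; each has \code{label}, \code{day},
#'   \code{region}, \code{rtt_samples}, \code{ic_samples}.
#' @export
enumerate_contrasts <- function(design) {
  if (!all(VALID_GENOTYPES %in% design$genotype))
    stop("design must contain both RTT and IC samples")
  key <- stratum_label(design$day, design$region)
  out <- list()
  for (lab in CANONICAL_CONTRASTS) {
    sel <- key == lab
    if (!any(sel)) next
    rtt <- design$sample_id[sel & design$genotype == "RTT"]
    ic <- design$sample_id[sel & design$genotype == "IC"]
    if (!length(rtt) || !length(ic)) {
      warning("stratum ", lab, " lacks one genotype; contrast omitted")
      next
    }
    out[[lab]] <- list(label = lab,
                       day = design$day[sel][1L],
                       region = design$region[sel][1L],
                       rtt_samples = rtt, ic_samples = ic)
  }
  out
}
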