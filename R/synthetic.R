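# Synthetic study generator: a complete multi-omics bundle with known
# ground truth, emulating the statistical structure of the organoid study
# design — negative-binomial RNA counts over a 2-genotype x (iPSC day 0 +
# days 13/40/75 x dorsal/ventral) x 3-replicate layout with a latent
# developmental axis, a correlated proteome with MAR + left-censored MNAR
# missingness, isoform mixtures with planted usage switches, beta-binomial
# allelic counts with mono-allelic imprinted genes, and Poisson promoter
# tag profiles with planted enrichment at imprinted promoters.

#' Simulation configuration
#'
#' All rates are probabilities in [0, 1]; the seed is mandatory.  Defaults
#' give a desk-scale study (2,000 genes, 300 proteins, 400 isoform-bearing
#' genes, 500 SNPs) whose full bundle generates in seconds.
#'
#' @param seed RNG seed (required).
#' @param n_genes number of genes.
#' @param frac_x fraction of genes placed on chromosome X.
#' @param n_imprinted number of imprinted genes (autosomal).
#' @param n_replicates replicates per genotype x stratum.
#' @param fraction_de fraction of genes with a planted genotype effect.
#' @param lfc_de planted |log2FC| of persistent differential genes.
#' @param n_transient genes differential at day 13 only.
#' @param dispersion_shape,dispersion_scale inverse-gamma dispersion:
#'   phi = 1 / rgamma(shape, rate = 1) * scale... (phi ~ scale / Gamma(shape)).
#' @param libsize_range library-size range (uniform draw).
#' @param axis_frac fraction of genes loading on the developmental axis.
#' @param axis_sd SD of the axis loadings (log2 units per axis unit).
#' @param rtt_delay_days planted developmental delay of RTT samples (days).
#' @param n_sets,n_enriched gene-set collection size and planted enriched sets.
#' @param n_proteins proteome size (mapped autosomal genes).
#' @param rna_protein_cor target per-pair RNA-protein correlation.
#' @param mar_rate missing-at-random cell deletion rate.
#' @param mnar_censor_quantile per-sample left-censoring quantile.
#' @param n_mnar proteins planted below the detection limit in one group.
#' @param n_pt_events gene-protein pairs with a planted group offset.
#' @param pt_group_offset planted post-transcriptional offset (log2 units).
#' @param n_isoform_genes isoform-bearing genes.
#' @param max_isoforms isoforms per gene upper bound.
#' @param n_diu genes with a planted usage switch.
#' @param diu_switch planted usage-share switch magnitude.
#' @param efflen_range isoform effective-length range (bases).
#' @param n_snps total SNPs.
#' @param depth_mean mean allelic read depth per SNP and sample.
#' @param allelic_rho beta-binomial overdispersion (intra-class correlation).
#' @param mono_fraction floor of the major-allele fraction of imprinted genes.
#' @param n_ase_shift imprinted genes planted to gain bi-allelic expression
#'   in RTT.
#' @param tss_window TSS window half-width (bp).
#' @param tss_bin_width profile bin width (bp).
#' @param tss_background,tss_peak_height Poisson rate: background per bin
#'   and Gaussian bump height at the TSS.
#' @param tss_enrichment_factor multiplicative rate factor at imprinted
#'   promoters (1 = no enrichment).
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed,
                       n_genes = 2000, frac_x = 0.05, n_imprinted = 79,
                       n_replicates = 3,
                       fraction_de = 0.1, lfc_de = 2, n_transient = 25,
                       dispersion_shape = 10, dispersion_scale = 0.45,
                       libsize_range = c(1e6, 3e6),
                       axis_frac = 0.3, axis_sd = 1, rtt_delay_days = 15,
                       n_sets = 40, n_enriched = 8,
                       n_proteins = 300, rna_protein_cor = 0.5,
                       mar_rate = 0.05, mnar_censor_quantile = 0.05,
                       n_mnar = 30,
                       n_pt_events = 20, pt_group_offset = 2,
                       n_isoform_genes = 400, max_isoforms = 4,
                       n_diu = 40, diu_switch = 0.4,
                       efflen_range = c(500, 3000),
                       n_snps = 500, depth_mean = 80,
                       allelic_rho = 0.005, mono_fraction = 0.97,
                       n_ase_shift = 8,
                       tss_window = 3000, tss_bin_width = 100,
                       tss_background = 1, tss_peak_height = 3,
                       tss_enrichment_factor = 2) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  rates <- c("frac_x", "fraction_de", "axis_frac", "mar_rate",
             "mnar_censor_quantile", "allelic_rho", "mono_fraction")
  for (r in rates)
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must be in [0, 1]")
  if (n_imprinted > n_genes) stop("n_imprinted exceeds n_genes")
  if (n_ase_shift > n_imprinted) stop("n_ase_shift exceeds n_imprinted")
  if (diu_switch < 0 || diu_switch > 0.5) stop("diu_switch must be in [0, 0.5]")
  if (any(libsize_range <= 0) || any(efflen_range <= 0))
    stop("ranges must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# developmental axis position for a sample, in axis units
.axis_value <- function(day, genotype, delay_days) {
  eff_day <- ifelse(genotype == "RTT", pmax(day - delay_days, 0), day)
  eff_day / 25
}

.make_design <- function(n_replicates) {
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

#' Generate the full synthetic study bundle
#'
#' Deterministic given the config (which carries the seed).  Returns RNA
#' counts, design, annotation, gene sets, and the protein / isoform /
#' allelic / TSS layers with their planted-truth tables.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{synthetic_bundle} list: \code{design},
#'   \code{rna_counts}, \code{annotation}, \code{genesets},
#'   \code{protein_intensities}, \code{protein_mapping},
#'   \code{isoform_counts}, \code{allelic_counts}, \code{tss_profiles},
#'   and \code{truth} (a list of tables of planted effects).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  design <- .make_design(config$n_replicates)
  ng <- config$n_genes
  genes <- sprintf("G%04d", seq_len(ng))

  # chromosomes: autosomes 1..22 plus an X fraction to exercise exclusion
  chrom <- sample(as.character(1:22), ng, replace = TRUE)
  n_x <- round(config$frac_x * ng)
  if (n_x > 0) chrom[sample.int(ng, n_x)] <- "X"
  autosomal <- which(chrom != "X")

  # latent developmental axis
  axis_genes <- sort(sample(autosomal, round(config$axis_frac * ng)))
  lambda <- numeric(ng)
  lambda[axis_genes] <- stats::rnorm(length(axis_genes), 0, config$axis_sd)

  # region effect for a subset of genes
  region_genes <- sort(sample(autosomal, round(0.2 * ng)))
  rho_region <- numeric(ng)
  rho_region[region_genes] <- stats::rnorm(length(region_genes), 0, 0.5)

  # planted genotype effects: persistent (all strata) and transient (D13)
  n_de <- round(config$fraction_de * ng)
  de_pool <- setdiff(autosomal, integer(0))
  de_idx <- sort(sample(de_pool, n_de))
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  trans_pool <- setdiff(de_pool, de_idx)
  trans_idx <- sort(sample(trans_pool, min(config$n_transient, length(trans_pool))))
  trans_sign <- sample(c(-1, 1), length(trans_idx), replace = TRUE)

  base <- stats::rnorm(ng, 4, 1.5)
  phi <- config$dispersion_scale / stats::rgamma(ng, config$dispersion_shape, rate = 1)
  phi <- pmin(pmax(phi, 1e-4), 2)
  libsize <- stats::runif(nrow(design), config$libsize_range[1L],
                          config$libsize_range[2L])

  counts <- matrix(0L, ng, nrow(design),
                   dimnames = list(genes, design$sample_id))
  log2mu_mat <- matrix(0, ng, nrow(design))
  for (j in seq_len(nrow(design))) {
    z <- .axis_value(design$day[j], design$genotype[j], config$rtt_delay_days)
    log2mu <- base + lambda * z +
      rho_region * (design$region[j] == "ventral")
    if (design$genotype[j] == "RTT") {
      log2mu[de_idx] <- log2mu[de_idx] + de_sign * config$lfc_de
      if (design$day[j] == 13L)
        log2mu[trans_idx] <- log2mu[trans_idx] + trans_sign * config$lfc_de
    }
    log2mu_mat[, j] <- log2mu
    rel <- 2^log2mu
    mu <- rel / sum(rel) * libsize[j]
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = 1 / phi)
  }

  # annotation
  biotype <- rep("protein_coding", ng)
  lnc_idx <- sort(sample(setdiff(autosomal, c(de_idx, trans_idx)), round(0.08 * ng)))
  biotype[lnc_idx] <- "lncRNA"
  imp_pool <- setdiff(autosomal, lnc_idx)
  imp_idx <- sort(sample(imp_pool, config$n_imprinted))
  reg_lnc_idx <- sort(sample(lnc_idx, min(30L, length(lnc_idx))))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  annotation <- data.frame(
    feature_id = genes, symbol = genes, chromosome = chrom,
    biotype = biotype,
    is_imprinted = seq_len(ng) %in% imp_idx,
    is_transcription_factor = FALSE,
    is_regulatory_lncRNA = seq_len(ng) %in% reg_lnc_idx,
    protein_id = NA_character_,
    tss_chromosome = chrom,
    tss_position = sample.int(2e8, ng),
    tss_strand = strand, stringsAsFactors = FALSE)

  # gene sets: planted enriched sets from same-sign differential genes,
  # the rest random; plus a developmental set for trajectory work
  sets <- list()
  up <- genes[de_idx[de_sign > 0]]; down <- genes[de_idx[de_sign < 0]]
  enriched <- character(config$n_enriched)
  enriched_dir <- character(config$n_enriched)
  for (i in seq_len(config$n_enriched)) {
    dir_up <- i %% 2L == 1L
    pool <- if (dir_up) up else down
    sid <- sprintf("SET_ENR_%02d", i)
    sets[[sid]] <- unique(c(sample(pool, min(25L, length(pool))),
                            sample(genes, 5L)))
    enriched[i] <- sid
    enriched_dir[i] <- if (dir_up) "up" else "down"
  }
  for (i in seq_len(config$n_sets - config$n_enriched)) {
    sid <- sprintf("SET_RND_%02d", i)
    sets[[sid]] <- sample(genes, sample(15:60, 1L))
  }
  dev_set <- genes[axis_genes[order(-abs(lambda[axis_genes]))][1:40]]
  sets[["SET_DEV_forebrain"]] <- dev_set

  bundle <- list(design = design,
                 rna_counts = expr_matrix(counts, "raw_count"),
                 annotation = annotation, genesets = sets,
                 libsize = stats::setNames(libsize, design$sample_id),
                 truth = list(
                   de_genes = data.frame(
                     gene_id = genes[de_idx], sign = de_sign,
                     log2FC = de_sign * config$lfc_de,
                     type = rep("persistent", length(de_idx)),
                     stringsAsFactors = FALSE),
                   transient_genes = data.frame(
                     gene_id = genes[trans_idx], sign = trans_sign,
                     log2FC = trans_sign * config$lfc_de,
                     type = rep("transient_d13", length(trans_idx)),
                     stringsAsFactors = FALSE),
                   enriched_sets = data.frame(
                     set_id = enriched, direction = enriched_dir,
                     stringsAsFactors = FALSE),
                   axis_loadings = stats::setNames(lambda, genes)))
  class(bundle) <- "synthetic_bundle"

  bundle <- simulate_proteome(bundle, config)
  bundle <- simulate_isoforms(bundle, config)
  bundle <- simulate_allelic(bundle, config)
  bundle <- simulate_tss_profiles(bundle, config)
  bundle
}

# Composition-corrected log2 expression used internally by the generator
# (median-of-ratios size factors, independent of the preprocess module).
# Protein abundance should track relative transcript abundance after
# correcting for composition drift along the developmental axis, as any
# between-sample normalization (TMM, median-of-ratios) would see it.
.sim_log2cpm <- function(counts) {
  geo <- exp(rowMeans(log(counts + 0.5)))
  sf <- apply(sweep(counts, 1L, geo, "/"), 2L, stats::median)
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' Simulate the protein layer of a bundle
#'
#' Log-intensities follow the gene's log2-CPM plus protein-specific noise
#' calibrated to the target RNA-protein correlation, a planted RTT group
#' offset for post-transcriptional-truth proteins, uniform MAR deletion,
#' and left-censoring below a per-sample quantile with a chosen group of
#' each MNAR-truth protein pushed below the detection limit.
#'
#' @param bundle a \code{synthetic_bundle} with RNA counts.
#' @param config the \code{\link{sim_config}}.
#' @return The bundle with \code{protein_intensities},
#'   \code{protein_mapping} and extended truth tables.
#' @export
simulate_proteome <- function(bundle, config) {
  set.seed(config$seed + 101L)
  ann <- bundle$annotation
  counts <- bundle$rna_counts$values
  eligible <- ann$feature_id[ann$chromosome != "X" &
                             ann$biotype == "protein_coding"]
  if (config$n_proteins > length(eligible))
    stop("proteome size exceeds mappable genes")
  mapped <- sort(sample(eligible, config$n_proteins))
  prot <- paste0("P_", mapped)
  lcpm <- .sim_log2cpm(counts)[mapped, , drop = FALSE]
  sig_sd <- apply(lcpm, 1L, stats::sd)
  rho <- config$rna_protein_cor
  noise_sd <- sig_sd * sqrt(max(1 / rho^2 - 1, 0))
  shift <- stats::rnorm(length(mapped), 20, 2)
  x <- lcpm + shift +
    matrix(stats::rnorm(length(lcpm), 0, noise_sd), nrow(lcpm), ncol(lcpm))
  rownames(x) <- prot

  # planted post-transcriptional group offsets
  pt_genes <- sample(mapped, min(config$n_pt_events, length(mapped)))
  pt_sign <- sample(c(-1, 1), length(pt_genes), replace = TRUE)
  rtt_cols <- bundle$design$genotype == "RTT"
  x[paste0("P_", pt_genes), rtt_cols] <-
    x[paste0("P_", pt_genes), rtt_cols] + pt_sign * config$pt_group_offset

  # MNAR planting: push a whole group of each chosen protein below the floor
  groups <- split(seq_len(nrow(bundle$design)),
                  paste(bundle$design$genotype,
                        stratum_label(bundle$design$day, bundle$design$region)))
  mnar_prot <- sample(prot, min(config$n_mnar, length(prot)))
  mnar_group <- sample(names(groups), length(mnar_prot), replace = TRUE)
  for (i in seq_along(mnar_prot))
    x[mnar_prot[i], groups[[mnar_group[i]]]] <- min(x) - 5

  # left-censoring below the per-sample quantile, then uniform MAR deletion
  if (config$mnar_censor_quantile > 0) {
    for (j in seq_len(ncol(x))) {
      thr <- stats::quantile(x[, j], config$mnar_censor_quantile, names = FALSE)
      x[x[, j] < thr, j] <- NA
    }
  }
  if (config$mar_rate > 0) {
    obs <- which(!is.na(x))
    drop <- sample(obs, round(config$mar_rate * length(obs)))
    x[drop] <- NA
  }

  ann$protein_id[match(mapped, ann$feature_id)] <- prot
  bundle$annotation <- ann
  bundle$protein_intensities <- expr_matrix(x, "log2intensity",
                                            missing_allowed = TRUE)
  bundle$protein_mapping <- data.frame(gene_id = mapped, protein_id = prot,
                                       stringsAsFactors = FALSE)
  bundle$truth$pt_events <- data.frame(
    gene_id = pt_genes, protein_id = paste0("P_", pt_genes),
    group_offset = pt_sign * config$pt_group_offset, stringsAsFactors = FALSE)
  bundle$truth$mnar_proteins <- data.frame(
    protein_id = mnar_prot, missing_group = mnar_group,
    stringsAsFactors = FALSE)
  bundle
}

#' Simulate the isoform layer of a bundle
#'
#' Splits each chosen gene's counts over isoforms by a usage vector
#' (multinomially per sample, so isoform counts sum to the gene count);
#' usage-switch truth genes carry two isoforms whose shares swap by
#' \code{diu_switch} in RTT.
#'
#' @param bundle,config as in \code{\link{simulate_proteome}}.
#' @return The bundle with long-format \code{isoform_counts} and DIU truth.
#' @export
simulate_isoforms <- function(bundle, config) {
  set.seed(config$seed + 202L)
  counts <- bundle$rna_counts$values
  min_count <- apply(counts, 1L, min)
  eligible <- rownames(counts)[min_count > 100]
  iso_genes <- sort(sample(eligible, min(config$n_isoform_genes,
                                         length(eligible))))
  diu_genes <- sort(sample(iso_genes, min(config$n_diu, length(iso_genes))))
  rtt <- bundle$design$genotype[match(colnames(counts),
                                      bundle$design$sample_id)] == "RTT"
  rows <- list()
  for (g in iso_genes) {
    is_diu <- g %in% diu_genes
    k <- if (is_diu) 2L else sample(seq_len(config$max_isoforms), 1L)
    iso_ids <- sprintf("%s.%d", g, seq_len(k))
    efflen <- stats::runif(k, config$efflen_range[1L], config$efflen_range[2L])
    if (is_diu) {
      u_ic <- c(0.5 + config$diu_switch / 2, 0.5 - config$diu_switch / 2)
      u_rtt <- rev(u_ic)
    } else {
      a <- stats::rgamma(k, 2)
      u_ic <- u_rtt <- a / sum(a)
    }
    cnt <- sapply(seq_len(ncol(counts)), function(j) {
      u <- if (rtt[j]) u_rtt else u_ic
      as.vector(stats::rmultinom(1L, counts[g, j], u))
    })
    cnt <- matrix(cnt, nrow = k)
    rows[[g]] <- data.frame(
      gene_id = g, isoform_id = rep(iso_ids, times = ncol(counts)),
      sample_id = rep(colnames(counts), each = k),
      count = as.vector(cnt),
      effective_length = rep(efflen, times = ncol(counts)),
      stringsAsFactors = FALSE)
  }
  bundle$isoform_counts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bundle$truth$diu_genes <- data.frame(gene_id = diu_genes,
                                       switch = config$diu_switch,
                                       stringsAsFactors = FALSE)
  bundle
}

# beta-binomial draw: n trials, mean p, intra-class correlation rho
.rbetabinom <- function(k, n, p, rho) {
  if (rho <= 0) return(stats::rbinom(k, n, p))
  ab <- (1 - rho) / rho
  pr <- stats::rbeta(k, p * ab, (1 - p) * ab)
  stats::rbinom(k, n, pr)
}

#' Simulate the allelic layer of a bundle
#'
#' Imprinted genes express one allele at a major fraction drawn above the
#' configured mono-allelic floor; planted ASE-shift genes switch to
#' balanced expression in RTT; all other genes are balanced.  Depths are
#' Poisson; zero-depth SNP-sample rows are never emitted.
#'
#' @param bundle,config as in \code{\link{simulate_proteome}}.
#' @return The bundle with long-format \code{allelic_counts} and ASE truth.
#' @export
simulate_allelic <- function(bundle, config) {
  set.seed(config$seed + 303L)
  ann <- bundle$annotation
  imp <- ann$feature_id[ann$is_imprinted]
  shift_genes <- sort(sample(imp, min(config$n_ase_shift, length(imp))))
  n_imp_snps <- 2L * length(imp)
  n_other <- max(config$n_snps - n_imp_snps, 0L)
  other_pool <- ann$feature_id[!ann$is_imprinted & ann$chromosome != "X"]
  other_genes <- sample(other_pool, n_other, replace = TRUE)
  snp_gene <- c(rep(imp, each = 2L), other_genes)
  snp_id <- sprintf("snp%04d", seq_along(snp_gene))
  samples <- bundle$design$sample_id
  rtt <- bundle$design$genotype == "RTT"
  major_is_ref <- stats::setNames(sample(c(TRUE, FALSE),
                                         length(unique(snp_gene)),
                                         replace = TRUE), unique(snp_gene))
  p_major <- stats::setNames(stats::runif(length(imp), config$mono_fraction,
                                          0.995), imp)
  rows <- vector("list", length(snp_id))
  for (i in seq_along(snp_id)) {
    g <- snp_gene[i]
    depth <- stats::rpois(length(samples), config$depth_mean)
    p <- if (g %in% imp) {
      ifelse(rtt & g %in% shift_genes, 0.65, p_major[[g]])
    } else rep(0.5, length(samples))
    maj <- .rbetabinom(length(samples), depth, p, config$allelic_rho)
    ref <- if (major_is_ref[[g]]) maj else depth - maj
    keep <- depth > 0
    rows[[i]] <- data.frame(snp_id = snp_id[i], gene_id = g,
                            sample_id = samples[keep],
                            ref_count = ref[keep],
                            alt_count = (depth - ref)[keep],
                            stringsAsFactors = FALSE)
  }
  bundle$allelic_counts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  bundle$truth$ase_shift_genes <- data.frame(
    gene_id = shift_genes, rtt_major_fraction = 0.65,
    stringsAsFactors = FALSE)
  bundle
}

#' Simulate TSS tag-count profiles of a bundle
#'
#' Poisson bin counts over TSS +/- \code{tss_window} with a Gaussian rate
#' bump at the TSS; imprinted genes' rates are multiplied by
#' \code{tss_enrichment_factor}.
#'
#' @param bundle,config as in \code{\link{simulate_proteome}}.
#' @return The bundle with \code{tss_profiles} (genes x bins matrix; column
#'   names are bin-start offsets in bp).
#' @export
simulate_tss_profiles <- function(bundle, config) {
  set.seed(config$seed + 404L)
  ann <- bundle$annotation
  n_bins <- 2L * config$tss_window / config$tss_bin_width
  starts <- seq(-config$tss_window, config$tss_window - config$tss_bin_width,
                by = config$tss_bin_width)
  mids <- starts + config$tss_bin_width / 2
  rate <- config$tss_background +
    config$tss_peak_height * exp(-(mids / 800)^2)
  prof <- t(vapply(seq_len(nrow(ann)), function(i) {
    f <- if (ann$is_imprinted[i]) config$tss_enrichment_factor else 1
    stats::rpois(n_bins, f * rate)
  }, numeric(n_bins)))
  dimnames(prof) <- list(ann$feature_id, starts)
  bundle$tss_profiles <- prof
  bundle
}

#' Write a synthetic bundle to a directory of text files
#'
#' Emits the design, annotation, matrices, long-format tables and GMT gene
#' sets in the package's interchange formats, plus the truth tables under
#' \code{truth/}.
#'
#' @param bundle a \code{synthetic_bundle}.
#' @param dir output directory (created if absent).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(as.data.frame(bundle$design), "design.tsv")
  w(bundle$annotation, "annotation.tsv")
  write_matrix(bundle$rna_counts, file.path(dir, "rna_counts.tsv"))
  write_matrix(bundle$protein_intensities, file.path(dir, "protein_intensities.tsv"))
  w(bundle$protein_mapping, "protein_mapping.tsv")
  w(bundle$isoform_counts, "isoform_counts.tsv")
  w(bundle$allelic_counts, "allelic_counts.tsv")
  w(data.frame(gene_id = rownames(bundle$tss_profiles),
               bundle$tss_profiles, check.names = FALSE), "tss_profiles.tsv")
  write_gmt(bundle$genesets, file.path(dir, "genesets.gmt"))
  for (nm in names(bundle$truth)) {
    tr <- bundle$truth[[nm]]
    if (is.data.frame(tr)) w(tr, file.path("truth", paste0(nm, ".tsv")))
  }
  invisible(dir)
}
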