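# Reference-trajectory pseudotime: PCA on control (IC) samples restricted
# to a developmental gene set, a smoothing spline through the IC samples in
# PCA space, and arc-length projection of all samples onto that spline.
# Dorsal and ventral organoids are fitted independently; day-0 iPSC samples
# belong to both arms.

#' Fit a reference developmental trajectory through IC samples
#'
#' PCA is computed on the IC samples only (restricted to \code{gene_set},
#' e.g. forebrain-development genes), one cubic smoothing spline per
#' retained component is fitted against the day-ordered sample rank, and
#' the spline is evaluated on a dense grid to form a polyline whose
#' cumulative arc length defines pseudotime.  Orientation is flipped if
#' pseudotime decreases with day.
#'
#' @param expr log-scale \code{expr_matrix}.
#' @param design \code{study_design}.
#' @param gene_set feature ids defining the developmental space.
#' @param region \code{"dorsal"} or \code{"ventral"}; the arm's IC samples
#'   plus the shared day-0 iPSC IC samples are used.
#' @param n_components retained principal components (default 2).
#' @param spar optional smoothing parameter for \code{stats::smooth.spline};
#'   \code{NULL} (default) selects smoothing by generalized cross-validation.
#' @param grid_points dense evaluation grid size (default 400, minimum 200).
#' @return A \code{trajectory_model}: gene set, centering vector, rotation,
#'   spline polyline (grid x components), cumulative arc length, region.
#' @export
fit_reference_trajectory <- function(expr, design, gene_set, region,
                                     n_components = 2, spar = NULL,
                                     grid_points = 400) {
  stopifnot(inherits(expr, "expr_matrix"))
  region <- match.arg(region, c("dorsal", "ventral"))
  grid_points <- max(grid_points, 200L)
  genes <- intersect(gene_set, rownames(expr$values))
  if (length(genes) < n_components + 1L)
    stop("too few gene-set members present in the matrix")
  sel <- design$genotype == "IC" & design$region %in% c(region, "iPSC")
  ic <- design[sel, , drop = FALSE]
  if (length(unique(ic$day)) < 3L)
    stop("need IC samples at >= 3 days to fit a spline")
  x <- t(expr$values[genes, ic$sample_id, drop = FALSE])
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$rotation))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  # day-ordered rank (ties within a day broken by sample id for determinism)
  ord <- order(ic$day, ic$sample_id)
  rank_x <- seq_along(ord)
  grid_x <- seq(1, length(ord), length.out = grid_points)
  polyline <- sapply(seq_len(k), function(comp) {
    y <- scores[ord, comp]
    fit <- if (is.null(spar)) stats::smooth.spline(rank_x, y)
           else stats::smooth.spline(rank_x, y, spar = spar)
    stats::predict(fit, grid_x)$y
  })
  polyline <- matrix(polyline, nrow = grid_points)
  seg <- sqrt(rowSums((polyline[-1L, , drop = FALSE] -
                       polyline[-grid_points, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  model <- structure(list(genes = genes, center = pca$center,
                          rotation = pca$rotation[, seq_len(k), drop = FALSE],
                          polyline = polyline, arc_length = arc,
                          region = region), class = "trajectory_model")
  # orient pseudotime to increase with day
  pt_ic <- assign_pseudotime(model, expr, ic$sample_id)
  if (stats::cor(pt_ic$pseudotime, ic$day[match(pt_ic$sample_id, ic$sample_id)],
                 method = "spearman") < 0) {
    model$polyline <- model$polyline[grid_points:1, , drop = FALSE]
    model$arc_length <- max(arc) - rev(arc)
  }
  model
}

#' Project samples onto a reference trajectory
#'
#' Each sample is projected with the model's PCA loadings and assigned the
#' cumulative arc length of the nearest point on the dense spline polyline
#' (Euclidean distance; ties resolve to the smaller arc length).
#'
#' @param model a \code{trajectory_model}.
#' @param expr \code{expr_matrix} sharing the model's gene space.
#' @param samples sample ids to project.
#' @return data frame: sample_id, pseudotime, distance.
#' @export
assign_pseudotime <- function(model, expr, samples) {
  x <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  missing <- setdiff(model$genes, rownames(x))
  if (length(missing))
    stop("matrix lacks trajectory genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sub <- t(x[model$genes, samples, drop = FALSE])
  proj <- sweep(sub, 2L, model$center, "-") %*% model$rotation
  res <- t(vapply(seq_len(nrow(proj)), function(i) {
    d2 <- rowSums(sweep(model$polyline, 2L, proj[i, ], "-")^2)
    j <- which.min(d2)  # first minimum = smaller arc length on ties
    c(model$arc_length[j], sqrt(d2[j]))
  }, numeric(2)))
  data.frame(sample_id = samples, pseudotime = res[, 1L],
             distance = res[, 2L], stringsAsFactors = FALSE)
}

#' Welch test of pseudotime between genotypes at one day
#'
#' @param assignments \code{\link{assign_pseudotime}} output merged with the
#'   design (must carry \code{genotype} and \code{day} columns, e.g. via
#'   \code{merge} with the design).
#' @param day the time point to test.
#' @return List: day, t, p, mean_rtt, mean_ic, n_rtt, n_ic.
#' @export
compare_pseudotime <- function(assignments, day) {
  a <- assignments[assignments$day == day, , drop = FALSE]
  rtt <- a$pseudotime[a$genotype == "RTT"]
  ic <- a$pseudotime[a$genotype == "IC"]
  if (length(rtt) < 2L || length(ic) < 2L)
    stop("need >= 2 samples per genotype at day ", day)
  if (stats::sd(rtt) == 0 && stats::sd(ic) == 0 && mean(rtt) == mean(ic))
    return(list(day = day, t = 0, p = 1, mean_rtt = mean(rtt),
                mean_ic = mean(ic), n_rtt = length(rtt), n_ic = length(ic)))
  tst <- stats::t.test(rtt, ic)
  list(day = day, t = unname(tst$statistic), p = tst$p.value,
       mean_rtt = mean(rtt), mean_ic = mean(ic),
       n_rtt = length(rtt), n_ic = length(ic))
}
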