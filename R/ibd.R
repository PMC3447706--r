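## Geographic distances, Mantel tests of isolation by distance, and
## gene-flow/drift regime classification from the shape of the
## F_ST-vs-distance scatter.

EARTH_RADIUS_KM <- 6371.0

.haversine <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param pops an [population_table()] with decimal-degree coordinates.
#' @return A [distance_matrix()] in km.
#' @export
great_circle_matrix <- function(pops) {
  stopifnot(inherits(pops, "hg_pops"))
  lat <- pops$meta$lat; lon <- pops$meta$lon
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("coordinates out of range")
  }
  P <- length(lat)
  D <- outer(seq_len(P), seq_len(P), function(i, j) {
    .haversine(lat[i], lon[i], lat[j], lon[j])
  })
  diag(D) <- 0
  dimnames(D) <- list(pops$meta$pop, pops$meta$pop)
  distance_matrix(D, units = "km")
}

#' Simple Mantel test
#'
#' Pearson correlation between the off-diagonal entries of two labelled
#' distance matrices, with significance from random permutations of the
#' labels of one matrix. One-tailed against positive association by
#' default (the isolation-by-distance hypothesis), with the add-one
#' p-value correction.
#'
#' @param d_gen,d_geo square matrices with matching labels (order may
#'   differ).
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @param scope label recorded on the result.
#' @return An object of class `hg_mantel`: `r`, `p_value`, `n_perm`,
#'   `n_populations`. `r` is `NA` (with warning) for a zero-variance
#'   matrix.
#' @export
mantel_test <- function(d_gen, d_geo, n_perm = 999, seed = NULL,
                        scope = "all") {
  if (is.null(rownames(d_gen)) || is.null(rownames(d_geo))) {
    stop("matrices must be labelled")
  }
  common <- intersect(rownames(d_gen), rownames(d_geo))
  n <- length(common)
  if (n < 4) stop("need at least 4 shared labels")
  A <- unclass(d_gen)[common, common]
  B <- unclass(d_geo)[common, common]
  lt <- lower.tri(A)
  if (stats::sd(A[lt]) == 0 || stats::sd(B[lt]) == 0) {
    warning("zero-variance distance matrix: r undefined")
    return(structure(list(r = NA_real_, p_value = NA_real_, n_perm = n_perm,
                          n_populations = n, scope = scope),
                     class = "hg_mantel"))
  }
  r_obs <- stats::cor(A[lt], B[lt])
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_b <- stats::cor(A[lt], B[idx, idx][lt])
    if (r_b >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(r = r_obs, p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, n_populations = n, scope = scope),
            class = "hg_mantel")
}

#' @export
print.hg_mantel <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.3f, one-tailed p = %.4g (%d populations, %d permutations)\n",
              x$scope, x$r, x$p_value, x$n_populations, x$n_perm))
  invisible(x)
}

#' Classify the gene-flow/drift regime of a region
#'
#' Operationalizes the four qualitative scatterplot cases of regional
#' equilibrium analysis on the genetic-vs-geographic distance cloud:
#'
#' * Case I - significant positive association (positive slope, Mantel
#'   p < alpha): regional equilibrium between gene flow and drift
#'   (isolation by distance).
#' * Case II - no association and uniformly low scatter: gene flow
#'   dominates throughout.
#' * Case III - no association with substantial scatter at all distances:
#'   drift dominates.
#' * Case IV - significant association with negative slope: intermediate
#'   non-equilibrium.
#'
#' The residual-scatter trend (Spearman correlation between distance and
#' absolute residuals of the linear regression of genetic on geographic
#' distance) is reported descriptively; it is not used to separate Case I,
#' because with differentiation bounded in `[0, 1]` the residual spread
#' necessarily shrinks near the ceiling even under textbook isolation by
#' distance. "Low scatter" means a mean absolute residual below
#' `low_scatter`.
#'
#' @param d_gen,d_geo distance matrices as in [mantel_test()].
#' @param mantel an `hg_mantel` result for the same matrices.
#' @param low_scatter threshold on the mean absolute residual separating
#'   Case II from Case III.
#' @param alpha significance threshold.
#' @return An object of class `hg_ibd_class`: `case` (`"I"`..`"IV"`),
#'   `slope`, `slope_p`, `scatter_rho`, `scatter_p`, `mean_abs_residual`.
#' @export
classify_ibd_regime <- function(d_gen, d_geo, mantel, low_scatter = 0.05,
                                alpha = 0.05) {
  common <- intersect(rownames(d_gen), rownames(d_geo))
  if (length(common) < 5) {
    warning("fewer than 5 populations: classification declined")
    return(structure(list(case = NA_character_), class = "hg_ibd_class"))
  }
  A <- unclass(d_gen)[common, common]
  B <- unclass(d_geo)[common, common]
  lt <- lower.tri(A)
  y <- A[lt]; x <- B[lt]
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[["x"]]
  slope_p <- summary(fit)$coefficients["x", "Pr(>|t|)"]
  res <- abs(stats::residuals(fit))
  ct <- suppressWarnings(stats::cor.test(x, res, method = "spearman",
                                         exact = FALSE))
  scatter_rho <- unname(ct$estimate)
  scatter_p <- ct$p.value
  mar <- mean(res)
  sig <- mantel$p_value < alpha
  case <- if (sig && slope > 0) {
    "I"
  } else if (!sig) {
    if (mar <= low_scatter) "II" else "III"
  } else "IV"
  structure(list(case = case, slope = slope, slope_p = slope_p,
                 scatter_rho = scatter_rho, scatter_p = scatter_p,
                 mean_abs_residual = mar, mantel_r = mantel$r,
                 mantel_p = mantel$p_value),
            class = "hg_ibd_class")
}

#' @export
print.hg_ibd_class <- function(x, ...) {
  cat("Gene flow/drift regime: Case", x$case, "\n")
  if (!is.na(x$case)) {
    cat(sprintf("  slope = %.3g (p = %.3g), scatter trend rho = %.3f, mantel r = %.3f (p = %.3g)\n",
                x$slope, x$slope_p, x$scatter_rho, x$mantel_r, x$mantel_p))
  }
  invisible(x)
}

#' Nei's standard genetic distance between populations
#'
#' `D = -ln( J_xy / sqrt(J_x J_y) )` on haplotype frequencies. Pairs
#' sharing no haplotype have infinite distance; these are capped at the
#' maximum finite value plus one (with a warning), and the cap is recorded
#' in attribute `cap`.
#'
#' @param pops an [population_table()].
#' @return A [distance_matrix()], units `"nei"`.
#' @export
nei_distance_matrix <- function(pops) {
  stopifnot(inherits(pops, "hg_pops"))
  P <- pops$counts / rowSums(pops$counts)
  K <- nrow(P)
  J <- P %*% t(P)                      # J[x,y] = sum_i p_xi p_yi
  selfJ <- diag(J)
  D <- -log(J / sqrt(outer(selfJ, selfJ)))
  diag(D) <- 0
  if (any(is.infinite(D))) {
    cap <- max(D[is.finite(D)]) + 1
    warning("populations without shared haplotypes: infinite Nei distances capped at ",
            signif(cap, 4))
    D[is.infinite(D)] <- cap
  } else {
    cap <- NA_real_
  }
  dimnames(D) <- list(rownames(pops$counts), rownames(pops$counts))
  res <- distance_matrix(D, units = "nei")
  attr(res, "cap") <- cap
  res
}

#' Export the scatterplot data behind an isolation-by-distance analysis
#'
#' @param d_gen,d_geo labelled distance matrices.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ibd_pairs <- function(d_gen, d_geo, path) {
  common <- intersect(rownames(d_gen), rownames(d_geo))
  A <- unclass(d_gen)[common, common]
  B <- unclass(d_geo)[common, common]
  idx <- which(lower.tri(A), arr.ind = TRUE)
  df <- data.frame(pop1 = common[idx[, 2]], pop2 = common[idx[, 1]],
                   genetic = A[idx], km = B[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
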