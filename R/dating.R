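## Net between-lineage divergence and molecular-clock dating.

#' Net between-group per-site divergence
#'
#' Frequency-weighted mean pairwise per-site differences between two groups
#' of populations (`d_XY`) and within each group (`d_X`, `d_Y`), and the
#' net divergence `d_A = d_XY - (d_X + d_Y) / 2`, which removes the
#' ancestral polymorphism carried by both lineages. Individuals are pooled
#' across each group's populations; all means are plug-in frequency means
#' (`sum_ij p_i p_j pi_ij`), which makes `d_A` exactly zero for identical
#' group compositions and exactly invariant to duplicating every
#' individual.
#'
#' @param pops an [population_table()].
#' @param pi haplotype step [distance_matrix()].
#' @param group_a,group_b disjoint character vectors of population codes.
#' @param n_sites number of coded characters used to normalize distances
#'   per site.
#' @return An object of class `hg_dating`: `d_XY`, `d_X`, `d_Y`, `d_A`,
#'   `n_sites` (and `mu`, `T_years` once [divergence_time()] is applied).
#' @export
net_between_group_distance <- function(pops, pi, group_a, group_b, n_sites) {
  stopifnot(inherits(pops, "hg_pops"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (!length(group_a) || !length(group_b)) stop("groups must be nonempty")
  D <- .align_kernel(pops, pi)
  ca <- colSums(pops$counts[group_a, , drop = FALSE])
  cb <- colSums(pops$counts[group_b, , drop = FALSE])
  na <- sum(ca); nb <- sum(cb)
  d_XY <- as.numeric(ca %*% D %*% cb) / (na * nb) / n_sites
  within <- function(cv, n) {
    if (n < 2) {
      warning("group with a single individual: within-group term is 0")
      return(0)
    }
    as.numeric(cv %*% D %*% cv) / (n * n) / n_sites
  }
  d_X <- within(ca, na)
  d_Y <- within(cb, nb)
  structure(list(d_XY = d_XY, d_X = d_X, d_Y = d_Y,
                 d_A = d_XY - (d_X + d_Y) / 2,
                 n_sites = n_sites, mu = NA_real_, T_years = NA_real_),
            class = "hg_dating")
}

#' Molecular-clock divergence time
#'
#' `T = d_A / (2 mu)` under a strict clock with per-lineage substitution
#' rate `mu` (substitutions/site/year). The default rate is the standard
#' estimate for non-coding plastid spacers, 1.01e-9.
#'
#' @param d_A net per-site divergence, or an `hg_dating` result.
#' @param mu substitution rate per site per year (> 0).
#' @return If `d_A` is a number, the time in years; if an `hg_dating`, the
#'   object with `mu` and `T_years` filled in.
#' @export
divergence_time <- function(d_A, mu = 1.01e-9) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (inherits(d_A, "hg_dating")) {
    d_A$mu <- mu
    d_A$T_years <- d_A$d_A / (2 * mu)
    return(d_A)
  }
  if (d_A < 0) stop("d_A must be nonnegative")
  d_A / (2 * mu)
}

#' @export
print.hg_dating <- function(x, ...) {
  cat(sprintf("d_XY = %.5g  d_X = %.5g  d_Y = %.5g  d_A = %.5g (per site, %d characters)\n",
              x$d_XY, x$d_X, x$d_Y, x$d_A, x$n_sites))
  if (!is.na(x$T_years)) {
    cat(sprintf("T = %.3g years (mu = %.3g)\n", x$T_years, x$mu))
  }
  invisible(x)
}
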