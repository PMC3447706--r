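## Ordered and unordered gene-diversity estimators with equal population
## weights, and the permutation test for phylogeographic structure.
##
## The unordered statistics (h_S, h_T, G_ST) are the special case of the
## ordered ones (v_S, v_T, N_ST) with the identity mismatch kernel
## pi_ij = 1(i != j), so a single kernel-based implementation serves both.

# counts: K x I matrix; kernel: I x I symmetric, zero diagonal.
# Estimators (equal population weights, populations treated as a sample
# from the region):
#   v_k  = n_k/(n_k-1) * sum_ij pi_ij p_ki p_kj        (within population)
#   v_S  = mean_k v_k
#   v_T  = sum_ij pi_ij pbar_i pbar_j                  (plug-in total)
#          - (1/K) sum_ij pi_ij cov_k(p_ki, p_kj)      (among-pop sampling)
#          + v_S / (ntilde K)                          (within-pop sampling)
# with pbar the unweighted mean frequencies and ntilde the harmonic mean
# sample size. With the identity kernel these reduce to the classical
# unbiased h_S and h_T.
.v_stats <- function(counts, kernel) {
  n <- rowSums(counts)
  K <- nrow(counts)
  if (K < 2) stop("need at least two populations")
  if (any(n < 2)) stop("every population needs n_k >= 2")
  P <- counts / n
  vk <- (n / (n - 1)) * rowSums((P %*% kernel) * P)
  vS <- mean(vk)
  pbar <- colMeans(P)
  CV <- stats::cov(P)
  ntilde <- 1 / mean(1 / n)
  vT <- as.numeric(pbar %*% kernel %*% pbar) -
    sum(kernel * CV) / K + vS / (ntilde * K)
  list(vk = vk, vS = vS, vT = vT,
       ST = if (vT > 0) 1 - vS / vT else NA_real_)
}

.identity_kernel <- function(ids) {
  k <- 1 - diag(length(ids))
  dimnames(k) <- list(ids, ids)
  k
}

.align_kernel <- function(pops, pi) {
  ids <- colnames(pops$counts)
  miss <- setdiff(ids, rownames(pi))
  if (length(miss)) stop("kernel lacks haplotypes: ", paste(miss, collapse = ", "))
  unclass(pi)[ids, ids]
}

#' Unordered gene-diversity statistics h_S, h_T and G_ST
#'
#' Within-population unbiased gene diversity
#' `h_k = n_k (1 - sum_i p_ki^2) / (n_k - 1)`, its unweighted mean `h_S`,
#' the bias-corrected total diversity `h_T` computed from the unweighted
#' mean haplotype frequencies (with small-sample corrections for both the
#' sampling of individuals within populations and of populations within the
#' region), and `G_ST = 1 - h_S / h_T`. Populations receive equal weight
#' regardless of sample size.
#'
#' @param pops an [population_table()].
#' @param scope label recorded on the result (e.g. a region name).
#' @return An object of class `hg_diversity` with `h_S`, `h_T`, `G_ST`,
#'   per-population `h_k`, `n_pops` and `n_haplotypes`. `G_ST` is `NA` when
#'   `h_T = 0` (all populations fixed for one haplotype).
#' @export
gene_diversity_stats <- function(pops, scope = "total") {
  stopifnot(inherits(pops, "hg_pops"))
  st <- .v_stats(pops$counts, .identity_kernel(colnames(pops$counts)))
  if (is.na(st$ST)) warning("h_T = 0: G_ST undefined")
  structure(list(h_S = st$vS, h_T = st$vT, G_ST = st$ST, h_k = st$vk,
                 n_pops = nrow(pops$counts),
                 n_haplotypes = sum(colSums(pops$counts) > 0),
                 scope = scope),
            class = "hg_diversity")
}

#' Ordered diversity statistics v_S, v_T and N_ST
#'
#' The ordered analogues of [gene_diversity_stats()], in which the identity
#' mismatch kernel is replaced by a matrix of genetic distances between
#' haplotypes (here, mutational steps), so that distantly related
#' haplotypes contribute more to the diversity than close ones.
#' `N_ST = 1 - v_S / v_T`; `N_ST` significantly above `G_ST` indicates
#' phylogeographic structure.
#'
#' @inheritParams gene_diversity_stats
#' @param pi a [distance_matrix()] over haplotypes (symmetric, zero
#'   diagonal) covering every counted haplotype.
#' @return An object of class `hg_diversity` with `v_S`, `v_T`, `N_ST`.
#' @export
ordered_diversity_stats <- function(pops, pi, scope = "total") {
  stopifnot(inherits(pops, "hg_pops"))
  st <- .v_stats(pops$counts, .align_kernel(pops, pi))
  if (is.na(st$ST)) warning("v_T = 0: N_ST undefined")
  structure(list(v_S = st$vS, v_T = st$vT, N_ST = st$ST, v_k = st$vk,
                 n_pops = nrow(pops$counts),
                 n_haplotypes = sum(colSums(pops$counts) > 0),
                 scope = scope),
            class = "hg_diversity")
}

#' @export
print.hg_diversity <- function(x, ...) {
  cat("Diversity (", x$scope, "): ", x$n_pops, " populations, ",
      x$n_haplotypes, " haplotypes\n", sep = "")
  if (!is.null(x$h_S)) {
    cat(sprintf("  h_S = %.3f  h_T = %.3f  G_ST = %.3f\n",
                x$h_S, x$h_T, x$G_ST))
  } else {
    cat(sprintf("  v_S = %.3f  v_T = %.3f  N_ST = %.3f\n",
                x$v_S, x$v_T, x$N_ST))
  }
  invisible(x)
}

#' Permutation test for phylogeographic structure (N_ST > G_ST)
#'
#' The null distribution is generated by randomly permuting haplotype
#' identities on the distance kernel (rows and columns jointly), which
#' leaves `G_ST` unchanged while destroying any association between
#' haplotype relatedness and geography. The one-tailed p-value uses the
#' add-one correction `p = (1 + #{N*_ST - G_ST >= N_ST - G_ST}) /
#' (n_perm + 1)`.
#'
#' @inheritParams ordered_diversity_stats
#' @param n_perm number of random label permutations.
#' @param seed optional integer seed for reproducible p-values.
#' @return An object of class `hg_permtest` with `G_ST`, `N_ST`,
#'   `difference`, `p_value`, `n_perm`.
#' @export
permutation_test_nst_gst <- function(pops, pi, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(pops, "hg_pops"))
  if (!is.null(seed)) set.seed(seed)
  counts <- pops$counts
  used <- colSums(counts) > 0
  counts <- counts[, used, drop = FALSE]
  kern <- .align_kernel(population_table(pops$meta, counts), pi)
  H <- ncol(counts)
  if (H < 3) warning("fewer than 3 distinct haplotypes: test is degenerate")
  gst <- .v_stats(counts, .identity_kernel(colnames(counts)))$ST
  nst <- .v_stats(counts, kern)$ST
  obs <- nst - gst
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(H)
    nst_b <- .v_stats(counts, kern[idx, idx, drop = FALSE])$ST
    if (!is.na(nst_b) && nst_b - gst >= obs - 1e-12) hits <- hits + 1L
  }
  structure(list(G_ST = gst, N_ST = nst, difference = obs,
                 p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "hg_permtest")
}

#' @export
print.hg_permtest <- function(x, ...) {
  cat(sprintf("N_ST = %.3f vs G_ST = %.3f; one-tailed p = %.4g (%d permutations)\n",
              x$N_ST, x$G_ST, x$p_value, x$n_perm))
  invisible(x)
}

#' Diversity and differentiation by group
#'
#' Reruns [gene_diversity_stats()], [ordered_diversity_stats()] and the
#' N_ST/G_ST permutation test on population subsets defined by a grouping
#' scheme, plus the full table, yielding one row per scope.
#'
#' @inheritParams permutation_test_nst_gst
#' @param scheme named character vector population code -> group label, or
#'   `NULL` for the total only. Groups with fewer than two populations are
#'   skipped.
#' @param total include the all-populations row labelled `"total"`.
#' @return data frame with columns `scope`, `n_pops`, `n_haplotypes`,
#'   `h_S`, `h_T`, `G_ST`, `N_ST`, `p_value`.
#' @export
diversity_by_group <- function(pops, pi, scheme = NULL, n_perm = 1000,
                               seed = NULL, total = TRUE) {
  scopes <- list()
  if (!is.null(scheme)) {
    .check_scheme(pops, scheme)
    for (g in unique(scheme)) {
      members <- names(scheme)[scheme == g]
      if (length(members) >= 2) scopes[[g]] <- members
    }
  }
  if (total) scopes[["total"]] <- pops$meta$pop
  rows <- lapply(names(scopes), function(g) {
    sub <- subset_populations(pops, scopes[[g]], drop_haplotypes = TRUE)
    un <- gene_diversity_stats(sub, scope = g)
    or <- ordered_diversity_stats(sub, pi, scope = g)
    pt <- permutation_test_nst_gst(sub, pi, n_perm = n_perm, seed = seed)
    data.frame(scope = g, n_pops = un$n_pops, n_haplotypes = un$n_haplotypes,
               h_S = un$h_S, h_T = un$h_T, G_ST = un$G_ST,
               v_S = or$v_S, v_T = or$v_T, N_ST = or$N_ST,
               p_value = pt$p_value)
  })
  do.call(rbind, rows)
}

# grouping scheme: named vector pop -> group; must cover every population
# exactly once
.check_scheme <- function(pops, scheme) {
  if (is.null(names(scheme))) stop("grouping scheme must be named by population")
  missing <- setdiff(pops$meta$pop, names(scheme))
  if (length(missing)) {
    stop("grouping scheme misses populations: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Built-in grouping schemes
#'
#' Constructs the standard grouping schemes from the population metadata:
#' `three_regions` (the `region` column), `two_subspecies` (habit, annual
#' vs perennial), `two_variants` (flower colour), and, when a lineage
#' bipartition is supplied, `two_lineages` (populations inherit the lineage
#' of the haplotypes they carry).
#'
#' @param pops an [population_table()].
#' @param bipartition optional result of [lineage_bipartition()].
#' @return named list of grouping schemes (named character vectors).
#' @export
builtin_groupings <- function(pops, bipartition = NULL) {
  meta <- pops$meta
  out <- list()
  if (!is.null(meta$region)) {
    out$three_regions <- stats::setNames(as.character(meta$region), meta$pop)
  }
  if (!is.null(bipartition)) {
    out$two_lineages <- bipartition$population_groups
  }
  if (!is.null(meta$habit)) {
    out$two_subspecies <- stats::setNames(as.character(meta$habit), meta$pop)
  }
  if (!is.null(meta$flower)) {
    out$two_variants <- stats::setNames(as.character(meta$flower), meta$pop)
  }
  out
}
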