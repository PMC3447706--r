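## Hierarchical analysis of molecular variance (Excoffier-style) on squared
## inter-individual distances, with permutation significance, plus pairwise
## population Phi_ST / F_ST.
##
## All sums of squared deviations reduce to quadratic forms in per-set
## haplotype count vectors: for a set with counts c over haplotypes and
## squared-distance kernel D (zero diagonal),
##   SSD(set) = sum_{i<j in set} d2_ij / n = (c' D c) / (2 n).
## Individuals are conceptually expanded from the counts; the permutation
## schemes operate on literal individual-level haplotype vectors.

.ssd <- function(cv, D) as.numeric(cv %*% D %*% cv) / (2 * sum(cv))

# counts: P x I; D: I x I squared distances; grp: group label per population.
# Returns variance components, percentages and Phi statistics. With a
# single group the decomposition collapses to the two-level AMOVA
# (sigma_a = 0).
.amova_decomp <- function(counts, D, grp) {
  n <- rowSums(counts)
  N <- sum(n)
  P <- nrow(counts)
  grp <- as.character(grp)
  G <- length(unique(grp))
  gsplit <- split(seq_len(P), grp)
  SSD_T <- .ssd(colSums(counts), D)
  SSD_WP <- sum(vapply(seq_len(P), function(k) .ssd(counts[k, ], D), 0))
  SSD_g <- vapply(gsplit, function(ix) .ssd(colSums(counts[ix, , drop = FALSE]), D), 0)
  Ng <- vapply(gsplit, function(ix) sum(n[ix]), 0)
  SSD_AP <- sum(SSD_g) - SSD_WP
  SSD_AG <- SSD_T - sum(SSD_g)
  df_wp <- N - P
  df_ap <- P - G
  df_ag <- G - 1
  sig_c <- SSD_WP / df_wp
  if (G == 1) {
    nc <- (N - sum(n^2) / N) / (P - 1)
    sig_b <- (SSD_AP / df_ap - sig_c) / nc
    sig_a <- 0
  } else {
    sum_nk2_g <- vapply(gsplit, function(ix) sum(n[ix]^2), 0)
    n1 <- (N - sum(sum_nk2_g / Ng)) / df_ap
    n2 <- (sum(sum_nk2_g / Ng) - sum(n^2) / N) / df_ag
    n3 <- (N - sum(Ng^2) / N) / df_ag
    sig_b <- (SSD_AP / df_ap - sig_c) / n1
    sig_a <- (SSD_AG / df_ag - sig_c - n2 * sig_b) / n3
  }
  tot <- sig_a + sig_b + sig_c
  list(ssd = c(among_groups = SSD_AG, among_pops = SSD_AP, within = SSD_WP),
       df = c(df_ag, df_ap, df_wp),
       sigma = c(a = sig_a, b = sig_b, c = sig_c),
       pct = 100 * c(sig_a, sig_b, sig_c) / tot,
       phi = c(CT = sig_a / tot, SC = sig_b / (sig_b + sig_c),
               ST = (sig_a + sig_b) / tot))
}

# fast re-tabulation of counts from an individual-level haplotype index
# vector (pop_id, hap_id integer vectors)
.tab_counts <- function(pop_id, hap_id, P, I) {
  matrix(tabulate(pop_id + P * (hap_id - 1L), nbins = P * I), nrow = P)
}

#' Three-level analysis of molecular variance
#'
#' Partitions the total variance in squared inter-individual genetic
#' distances into among-group, among-population-within-group and
#' within-population components, with Phi statistics and permutation
#' p-values. The squared distance between two individuals is the number of
#' coded characters at which their haplotypes differ (pairwise-difference
#' convention). Negative variance components are reported as computed, not
#' clamped.
#'
#' Permutation schemes (one-tailed, add-one correction):
#' * `Phi_CT` / among groups: whole populations permuted among groups;
#' * `Phi_SC` / among populations: individuals permuted among populations
#'   within their group;
#' * `Phi_ST` / within populations: individuals permuted among all
#'   populations.
#'
#' @param pops an [population_table()].
#' @param pi a [distance_matrix()] of haplotype step distances.
#' @param grouping named character vector population code -> group label.
#' @param n_perm number of permutations for each significance test (0 to
#'   skip).
#' @param seed optional integer seed.
#' @param name label stored on the result.
#' @return An object of class `hg_amova` with the SSD table, variance
#'   components `sigma`, `percent`, `phi` (`CT`, `SC`, `ST`) and `p_values`.
#' @export
amova_three_level <- function(pops, pi, grouping, n_perm = 1023, seed = NULL,
                              name = "grouping") {
  stopifnot(inherits(pops, "hg_pops"))
  .check_scheme(pops, grouping)
  if (!is.null(seed)) set.seed(seed)
  counts <- pops$counts[, colSums(pops$counts) > 0, drop = FALSE]
  D <- .align_kernel(population_table(pops$meta, counts), pi)
  grp <- as.character(grouping[rownames(counts)])
  if (any(vapply(split(rowSums(counts), grp), sum, 0) == 0)) {
    stop("a group has zero individuals")
  }
  obs <- .amova_decomp(counts, D, grp)

  p_values <- c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
  if (n_perm > 0) {
    P <- nrow(counts); I <- ncol(counts)
    n <- rowSums(counts)
    pop_id <- rep(seq_len(P), n)
    hap_id <- unlist(lapply(seq_len(P), function(k) rep(seq_len(I), counts[k, ])),
                     use.names = FALSE)
    gsplit <- split(seq_along(pop_id), grp[pop_id])
    hits <- c(CT = 0L, SC = 0L, ST = 0L)
    G <- length(unique(grp))
    for (b in seq_len(n_perm)) {
      if (G > 1) {
        grp_b <- grp[sample.int(P)]
        st <- .amova_decomp(counts, D, grp_b)
        if (isTRUE(st$phi["CT"] >= obs$phi["CT"] - 1e-12)) hits["CT"] <- hits["CT"] + 1L
        hap_b <- hap_id
        for (ix in gsplit) hap_b[ix] <- hap_b[ix][sample.int(length(ix))]
        st <- .amova_decomp(.tab_counts(pop_id, hap_b, P, I), D, grp)
        if (isTRUE(st$phi["SC"] >= obs$phi["SC"] - 1e-12)) hits["SC"] <- hits["SC"] + 1L
      }
      st <- .amova_decomp(.tab_counts(pop_id, hap_id[sample.int(length(hap_id))],
                                      P, I), D, grp)
      if (isTRUE(st$phi["ST"] >= obs$phi["ST"] - 1e-12)) hits["ST"] <- hits["ST"] + 1L
    }
    p_values <- (1 + hits) / (n_perm + 1)
    if (G == 1) p_values[c("CT", "SC")] <- NA_real_
  }

  structure(list(grouping = name,
                 groups = sort(unique(grp)),
                 ssd = obs$ssd, df = obs$df, sigma = obs$sigma,
                 percent = stats::setNames(obs$pct,
                   c("among_groups", "among_pops_within", "within_pops")),
                 phi = obs$phi, p_values = p_values, n_perm = n_perm,
                 seed = seed),
            class = "hg_amova")
}

#' @export
print.hg_amova <- function(x, ...) {
  cat("AMOVA (", x$grouping, "): ", length(x$groups), " groups\n", sep = "")
  tab <- data.frame(source = names(x$percent), df = x$df,
                    sigma = round(x$sigma, 5), percent = round(x$percent, 2),
                    p = signif(x$p_values, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("Phi_CT = %.4f  Phi_SC = %.4f  Phi_ST = %.4f\n",
              x$phi["CT"], x$phi["SC"], x$phi["ST"]))
  invisible(x)
}

#' Pairwise population differentiation (Phi_ST / F_ST)
#'
#' For every population pair, the among-population component of a two-level
#' AMOVA, either with the mutational-step kernel (`Phi_ST`, the default) or
#' with the identity kernel (haplotype-frequency `F_ST`). A pair of
#' populations fixed for the same haplotype has no variance at all and is
#' assigned 0. Values are clamped to `[0, 1]` for downstream matrix
#' correlation; raw values are retained in attribute `raw`.
#'
#' @param pops an [population_table()].
#' @param pi haplotype step [distance_matrix()]; ignored for the identity
#'   kernel.
#' @param kernel `"steps"` or `"identity"`.
#' @param clamp clamp values into `[0, 1]`.
#' @return A [distance_matrix()] over populations, units `"F_ST"`.
#' @export
pairwise_fst <- function(pops, pi = NULL, kernel = c("steps", "identity"),
                         clamp = TRUE) {
  stopifnot(inherits(pops, "hg_pops"))
  kernel <- match.arg(kernel)
  counts <- pops$counts
  if (nrow(counts) < 2) stop("need at least two populations")
  D <- if (kernel == "steps") {
    if (is.null(pi)) stop("pi required for the step kernel")
    .align_kernel(pops, pi)
  } else {
    .identity_kernel(colnames(counts))
  }
  P <- nrow(counts)
  out <- matrix(0, P, P, dimnames = list(rownames(counts), rownames(counts)))
  for (a in seq_len(P - 1)) {
    for (b in seq(a + 1, P)) {
      c1 <- counts[a, ]; c2 <- counts[b, ]
      n1 <- sum(c1); n2 <- sum(c2); N <- n1 + n2
      SSD_T <- .ssd(c1 + c2, D)
      if (SSD_T == 0) { out[a, b] <- out[b, a] <- 0; next }
      SSD_W <- .ssd(c1, D) + .ssd(c2, D)
      sig_w <- SSD_W / (N - 2)
      nc <- N - (n1^2 + n2^2) / N
      sig_a <- ((SSD_T - SSD_W) - sig_w) / nc
      out[a, b] <- out[b, a] <- sig_a / (sig_a + sig_w)
    }
  }
  raw <- out
  if (clamp) out <- pmin(pmax(out, 0), 1)
  # raw values can be slightly negative, so skip the nonnegativity check
  res <- structure(out, units = "F_ST", raw = raw, kernel = kernel,
                   class = c("hg_dist", "matrix", "array"))
  res
}
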