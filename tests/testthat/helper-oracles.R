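# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately use naive loops and different
# algebra from the package code paths.

# naive per-column, per-pair Hamming distance with pairwise deletion
o_hamming <- function(states) {
  n <- nrow(states)
  D <- matrix(0, n, n, dimnames = list(rownames(states), rownames(states)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- 0
    for (k in seq_len(ncol(states))) {
      a <- states[i, k]; b <- states[j, k]
      if (a != "N" && b != "N" && a != b) d <- d + 1
    }
    D[i, j] <- d
  }
  D
}

# loop-based transcription of the equal-weight diversity estimators
o_diversity <- function(counts, kernel = NULL) {
  K <- nrow(counts); I <- ncol(counts)
  if (is.null(kernel)) {
    kernel <- matrix(1, I, I) - diag(I)
  }
  n <- rowSums(counts)
  vk <- numeric(K)
  for (k in seq_len(K)) {
    p <- counts[k, ] / n[k]
    acc <- 0
    for (i in seq_len(I)) for (j in seq_len(I)) acc <- acc + kernel[i, j] * p[i] * p[j]
    vk[k] <- n[k] / (n[k] - 1) * acc
  }
  vS <- mean(vk)
  pbar <- numeric(I)
  for (i in seq_len(I)) pbar[i] <- mean(counts[, i] / n)
  plug <- 0
  for (i in seq_len(I)) for (j in seq_len(I)) plug <- plug + kernel[i, j] * pbar[i] * pbar[j]
  covcorr <- 0
  for (i in seq_len(I)) for (j in seq_len(I)) {
    cij <- sum((counts[, i] / n - pbar[i]) * (counts[, j] / n - pbar[j])) / (K - 1)
    covcorr <- covcorr + kernel[i, j] * cij
  }
  ntilde <- K / sum(1 / n)
  vT <- plug - covcorr / K + vS / (ntilde * K)
  list(vS = vS, vT = vT, ST = 1 - vS / vT)
}

# within-population ordered diversity by exhaustive double sum over
# expanded individuals: v_k = mean of kernel over ordered non-self
# individual pairs (same-haplotype pairs contribute 0), which equals the
# n/(n-1)-corrected frequency form
o_vk_bruteforce <- function(cnt, kernel) {
  haps <- rep(seq_along(cnt), cnt)
  n <- length(haps)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) acc <- acc + kernel[haps[i], haps[j]]
  }
  acc / (n * (n - 1))
}

# direct SSD-based AMOVA on expanded individuals (naive double loops)
o_amova <- function(counts, D, grp) {
  K <- nrow(counts)
  hap_of <- unlist(lapply(seq_len(K), function(k) rep(seq_len(ncol(counts)), counts[k, ])))
  pop_of <- rep(seq_len(K), rowSums(counts))
  N <- length(hap_of)
  d2 <- function(i, j) D[hap_of[i], hap_of[j]]
  ssd_set <- function(members) {
    if (length(members) < 2) return(0)
    acc <- 0
    for (a in seq_along(members)) for (b in seq_along(members)) {
      if (a < b) acc <- acc + d2(members[a], members[b])
    }
    acc / length(members)
  }
  SSD_T <- ssd_set(seq_len(N))
  SSD_WP <- sum(sapply(seq_len(K), function(k) ssd_set(which(pop_of == k))))
  groups <- unique(grp)
  G <- length(groups)
  SSD_WG <- sum(sapply(groups, function(g) ssd_set(which(grp[pop_of] == g))))
  SSD_AP <- SSD_WG - SSD_WP
  SSD_AG <- SSD_T - SSD_WG
  n <- rowSums(counts)
  Ng <- sapply(groups, function(g) sum(n[grp == g]))
  sig_c <- SSD_WP / (N - K)
  if (G == 1) {
    nc <- (N - sum(n^2) / N) / (K - 1)
    sig_b <- (SSD_AP / (K - G) - sig_c) / nc
    sig_a <- 0
  } else {
    s2g <- sapply(groups, function(g) sum(n[grp == g]^2))
    n1 <- (N - sum(s2g / Ng)) / (K - G)
    n2 <- (sum(s2g / Ng) - sum(n^2) / N) / (G - 1)
    n3 <- (N - sum(Ng^2) / N) / (G - 1)
    sig_b <- (SSD_AP / (K - G) - sig_c) / n1
    sig_a <- (SSD_AG / (G - 1) - sig_c - n2 * sig_b) / n3
  }
  tot <- sig_a + sig_b + sig_c
  list(sigma = c(sig_a, sig_b, sig_c), pct = 100 * c(sig_a, sig_b, sig_c) / tot)
}

# two-level Phi_ST for one population pair via o_amova with one group
o_pair_phist <- function(c1, c2, D) {
  counts <- rbind(c1, c2)
  res <- o_amova(counts, D, c("g", "g"))
  res$sigma[2] / (res$sigma[2] + res$sigma[3])
}

# exact one-sided Mantel permutation distribution by full enumeration
o_mantel_exact <- function(A, B) {
  n <- nrow(A)
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  hits <- 0; tot <- 0
  for (p in perms(seq_len(n))) {
    tot <- tot + 1
    if (cor(A[lt], B[p, p][lt]) >= r_obs - 1e-12) hits <- hits + 1
  }
  hits / tot
}

# exact N_ST - G_ST permutation distribution over all label permutations
o_nstgst_exact <- function(counts, kernel) {
  H <- ncol(counts)
  gst <- o_diversity(counts)$ST
  obs <- o_diversity(counts, kernel)$ST - gst
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  hits <- 0; tot <- 0
  for (p in perms(seq_len(H))) {
    tot <- tot + 1
    d <- o_diversity(counts, kernel[p, p])$ST - gst
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  hits / tot
}

# spherical law of cosines great-circle distance (vs haversine)
o_great_circle <- function(lat1, lon1, lat2, lon2, R = 6371) {
  r <- pi / 180
  ang <- sin(lat1 * r) * sin(lat2 * r) +
    cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)
  R * acos(pmin(1, pmax(-1, ang)))
}

# Monte-Carlo estimate of the parsimony probability model: per-site
# Poisson hits at rate theta over m sites; a connection of j observed
# differences is parsimonious iff total hits == j
o_parsimony_mc <- function(m, theta, n_sim = 2e5, seed = 1) {
  set.seed(seed)
  hits <- matrix(rpois(m * n_sim, theta), nrow = m)
  p_diff_given_n <- function(n) 0.75 * (1 - (-1 / 3)^n)
  differ <- matrix(runif(m * n_sim) < p_diff_given_n(hits), nrow = m)
  j_obs <- colSums(differ)
  total <- colSums(hits)
  pars <- total == j_obs
  # P(parsimony | j) for each observed j
  tab <- tapply(pars, j_obs, mean)
  cnt <- table(j_obs)
  list(j = as.integer(names(tab)), p = as.numeric(tab),
       n = as.integer(cnt))
}

# random small population-count fixture
r_counts <- function(K, I, n = NULL) {
  if (is.null(n)) n <- sample(4:9, K, replace = TRUE)
  cnt <- t(sapply(seq_len(K), function(k) {
    as.integer(rmultinom(1, n[k], runif(I, 0.2, 1)))
  }))
  colnames(cnt) <- paste0("H", seq_len(I))
  rownames(cnt) <- paste0("P", seq_len(K))
  cnt
}

# drop zero-count haplotype columns and relabel sequentially so that
# freshly drawn kernels line up with the columns
drop_zero <- function(cnt) {
  cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  colnames(cnt) <- paste0("H", seq_len(ncol(cnt)))
  cnt
}

# random symmetric integer step kernel with zero diagonal
r_kernel <- function(I, max_steps = 6) {
  M <- matrix(sample(1:max_steps, I * I, replace = TRUE), I, I)
  M <- M + t(M)
  diag(M) <- 0
  dimnames(M) <- list(paste0("H", seq_len(I)), paste0("H", seq_len(I)))
  M
}

# hg_pops wrapper around a counts matrix with arbitrary coordinates
as_pops <- function(cnt, lat = NULL, lon = NULL) {
  K <- nrow(cnt)
  population_table(
    data.frame(pop = rownames(cnt),
               lat = if (is.null(lat)) runif(K, 20, 50) else lat,
               lon = if (is.null(lon)) runif(K, 90, 130) else lon),
    cnt)
}

# random coded character matrix over haplotypes
r_coded <- function(H, L, states = c("A", "C", "G", "T")) {
  m <- matrix(sample(states, H * L, replace = TRUE), H, L)
  rownames(m) <- paste0("H", seq_len(H))
  coded_matrix(m)
}

fixture_pops <- function() load_fixture("table1")
fixture_coded <- function() load_fixture("table2")
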