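test_that("two-population worked example matches hand-computed estimators", {
  # populations {A:3,B:1} and {A:1,B:3}: h_k = 4/3 * (1 - 10/16) = 0.5,
  # h_S = 0.5; pbar = (.5,.5); among-pop variance term = 0.125;
  # within-sampling term = 0.5/8; h_T = 0.5 + 0.125 + 0.0625 = 0.6875
  cnt <- rbind(P1 = c(A = 3, B = 1), P2 = c(A = 1, B = 3))
  pops <- as_pops(cnt)
  d <- gene_diversity_stats(pops)
  expect_equal(d$h_S, 0.5)
  expect_equal(d$h_T, 0.6875)
  expect_equal(d$G_ST, 1 - 0.5 / 0.6875)
})

test_that("all populations fixed for one haplotype gives zero diversity", {
  cnt <- rbind(P1 = c(A = 5, B = 0), P2 = c(A = 7, B = 0))
  pops <- as_pops(cnt)
  expect_warning(d <- gene_diversity_stats(pops), "undefined")
  expect_equal(d$h_S, 0)
  expect_equal(d$h_T, 0)
  expect_true(is.na(d$G_ST))
})

test_that("identity kernel reduces the ordered statistics to the unordered ones", {
  set.seed(31)
  for (rep in 1:20) {
    cnt <- r_counts(sample(3:6, 1), sample(3:5, 1))
    cnt <- drop_zero(cnt)
    if (ncol(cnt) < 2) next
    pops <- as_pops(cnt)
    I <- ncol(cnt)
    ones <- distance_matrix(matrix(1, I, I) - diag(I),
                            units = "steps")
    dimnames(ones) <- list(colnames(cnt), colnames(cnt))
    un <- gene_diversity_stats(pops)
    or <- ordered_diversity_stats(pops, ones)
    expect_equal(or$v_S, un$h_S)
    expect_equal(or$v_T, un$h_T)
    expect_equal(or$N_ST, un$G_ST)
  }
})

test_that("estimators match the loop-based oracle on random instances", {
  set.seed(32)
  for (rep in 1:40) {
    K <- sample(3:7, 1); I <- sample(3:6, 1)
    cnt <- r_counts(K, I)
    cnt <- drop_zero(cnt)
    if (ncol(cnt) < 2) next
    kern <- r_kernel(ncol(cnt))
    pops <- as_pops(cnt)
    pi <- distance_matrix(kern, units = "steps")
    un <- gene_diversity_stats(pops)
    o_un <- o_diversity(cnt)
    expect_equal(un$h_S, o_un$vS)
    expect_equal(un$h_T, o_un$vT)
    or <- ordered_diversity_stats(pops, pi)
    o_or <- o_diversity(cnt, kern)
    expect_equal(or$v_S, o_or$vS)
    expect_equal(or$v_T, o_or$vT)
    expect_equal(or$N_ST, o_or$ST)
    # within-population terms against the exhaustive individual-pair sum
    for (k in seq_len(nrow(cnt))) {
      expect_equal(unname(or$v_k[k]), o_vk_bruteforce(cnt[k, ], kern))
    }
  }
})

test_that("N_ST is invariant to positive rescaling of the kernel", {
  set.seed(33)
  cnt <- r_counts(5, 4)
  cnt <- drop_zero(cnt)
  kern <- r_kernel(ncol(cnt))
  pops <- as_pops(cnt)
  a <- ordered_diversity_stats(pops, distance_matrix(kern, "steps"))
  b <- ordered_diversity_stats(pops, distance_matrix(kern * 7.3, "steps"))
  expect_equal(a$N_ST, b$N_ST)
})

test_that("estimators converge to plug-in values at large n", {
  set.seed(34)
  I <- 4
  probs <- list(c(.7, .2, .05, .05), c(.1, .6, .2, .1), c(.25, .25, .25, .25))
  cnt <- t(sapply(probs, function(p) as.integer(rmultinom(1, 1e4, p))))
  colnames(cnt) <- paste0("H", 1:I); rownames(cnt) <- paste0("P", 1:3)
  pops <- as_pops(cnt)
  d <- gene_diversity_stats(pops)
  plug_hS <- mean(sapply(probs, function(p) 1 - sum(p^2)))
  pbar <- colMeans(do.call(rbind, probs))
  # the population-sampling variance term stays: compare against the
  # K-population plug-in total, not the infinite-population one
  s2 <- apply(do.call(rbind, probs), 2, var)
  plug_hT <- 1 - sum(pbar^2) + sum(s2) / 3
  expect_equal(d$h_S, plug_hS, tolerance = 0.01)
  expect_equal(d$h_T, plug_hT, tolerance = 0.01)
})

test_that("fixture h_S is the direct mean over the ten polymorphic populations", {
  pops <- fixture_pops()
  P <- pops$counts / rowSums(pops$counts)
  hk <- 15 / 14 * (1 - rowSums(P^2))
  expect_equal(sum(hk > 0), 10)
  d <- gene_diversity_stats(pops)
  expect_equal(d$h_S, sum(hk[hk > 0]) / 47)
})

test_that("permutation test matches exhaustive enumeration on 3 haplotypes", {
  set.seed(35)
  cnt <- rbind(P1 = c(H1 = 6, H2 = 2, H3 = 0),
               P2 = c(H1 = 1, H2 = 5, H3 = 2),
               P3 = c(H1 = 0, H2 = 2, H3 = 6))
  kern <- matrix(c(0, 1, 5, 1, 0, 4, 5, 4, 0), 3, 3,
                 dimnames = list(colnames(cnt), colnames(cnt)))
  pops <- as_pops(cnt)
  q_exact <- o_nstgst_exact(cnt, kern)
  pt <- permutation_test_nst_gst(pops, distance_matrix(kern, "steps"),
                                 n_perm = 4000, seed = 9)
  # sampler estimate converges on the exact permutation fraction
  expect_equal(pt$p_value, q_exact, tolerance = 0.03)
})

test_that("constant off-diagonal kernel gives zero difference and p near 1", {
  cnt <- r_counts(4, 3)
  cnt <- drop_zero(cnt)
  I <- ncol(cnt)
  ones <- matrix(1, I, I) - diag(I)
  dimnames(ones) <- list(colnames(cnt), colnames(cnt))
  pops <- as_pops(cnt)
  pt <- permutation_test_nst_gst(pops, distance_matrix(ones, "steps"),
                                 n_perm = 99, seed = 2)
  expect_equal(pt$difference, 0)
  expect_equal(pt$p_value, 1)
})

test_that("grouped diversity table reproduces every printed regional row", {
  pops <- fixture_pops()
  pi <- pairwise_step_distances(fixture_coded())
  scheme <- setNames(pops$meta$region, pops$meta$pop)
  tab <- diversity_by_group(pops, pi, scheme, n_perm = 0, seed = 1)
  tab <- tab[match(c("NEQTP", "SEQTP", "N", "total"), tab$scope), ]
  expect_equal(round(tab$h_S, 3), c(0.064, 0.064, 0.127, 0.106))
  expect_equal(round(tab$h_T, 3), c(0.536, 0.908, 0.282, 0.677))
  expect_equal(round(tab$G_ST, 3), c(0.880, 0.929, 0.548, 0.843))
  expect_equal(round(tab$N_ST, 3), c(0.938, 0.960, 0.546, 0.975))
})
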