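test_that("connection limit: parameter checks and basic behaviour", {
  expect_error(parsimony_connection_limit(1381, alpha = 0), "alpha")
  expect_error(parsimony_connection_limit(1381, alpha = 1), "alpha")
  expect_error(parsimony_connection_limit(0), "n_characters")
  # fixture-scale input keeps both lineages connectable (limit >= 11)
  pi <- pairwise_step_distances(fixture_coded())
  lim <- parsimony_connection_limit(1381, alpha = 0.05, pi = pi)
  expect_gte(lim, 11)
  # a stricter alpha can only lower the limit
  expect_lte(parsimony_connection_limit(1381, alpha = 0.01, pi = pi), lim)
  # no observed divergence floors the limit at one step
  expect_equal(parsimony_connection_limit(500, mean_pairwise_steps = 0), 1L)
})

test_that("connection limit probabilities match the Monte-Carlo oracle at small n", {
  m <- 100
  mean_steps <- 1.5
  q <- mean_steps / m
  theta <- -0.75 * log(1 - 4 * q / 3)
  mc <- o_parsimony_mc(m, theta, n_sim = 4e5, seed = 7)
  # closed-form parsimony probability of a j-step connection
  r1 <- theta * exp(-theta) / q
  r0 <- exp(-theta) / (1 - q)
  model_p <- function(j) r1^j * r0^(m - j)
  # simulated conditional parsimony probabilities agree with the model
  # within 3 binomial standard errors wherever support is decent
  supported <- which(mc$n >= 300 & mc$j >= 1)
  expect_gte(length(supported), 5)
  for (k in supported) {
    se <- sqrt(model_p(mc$j[k]) * (1 - model_p(mc$j[k])) / mc$n[k])
    expect_lt(abs(mc$p[k] - model_p(mc$j[k])), 3 * se + 1e-6)
  }
  # the limit implied by the oracle-validated model at alpha = 0.05
  expect_identical(parsimony_connection_limit(m, alpha = 0.05,
                                              mean_pairwise_steps = mean_steps),
                   9L)
})

test_that("network construction keeps all tied minimal edges and spans", {
  # two haplotypes one step apart: a single edge
  cm <- coded_matrix(rbind(A = c("A", "C"), B = c("G", "C")))
  net <- build_network(pairwise_step_distances(cm))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 1)
  expect_error(build_network(coded_matrix(matrix(character(0), 0, 0))))
})

test_that("resolved spanning weight equals the classic MST weight oracle", {
  set.seed(51)
  for (rep in 1:30) {
    H <- sample(5:8, 1)
    cm <- r_coded(H, sample(10:25, 1))
    pi <- pairwise_step_distances(cm)
    if (any(pi[upper.tri(pi)] == 0)) next  # duplicate haplotypes
    net <- build_network(pi)
    res <- resolve_loops(net)
    # spanning tree: nodes - 1 edges, acyclic by construction
    expect_equal(nrow(res$edges), H - 1)
    g <- igraph::graph_from_adjacency_matrix(unclass(pi), mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_equal(sum(res$edges$steps), mst_w)
  }
})

test_that("fixture network shows the published loop and resolves it by frequency", {
  pops <- fixture_pops()
  pi <- pairwise_step_distances(fixture_coded())
  freqs <- colSums(pops$counts)
  net <- build_network(pi, frequencies = freqs, limit = 20, pops = pops)
  # ambiguous alternative connections involve H1, H5, H7, H11
  loop_members <- unique(unlist(lapply(net$ties, function(t) c(t$from, t$to))))
  expect_true(all(c("H1", "H5", "H7", "H11") %in% loop_members))
  expect_true(all(vapply(net$ties, function(t) all(t$steps == 12), TRUE)))
  res <- resolve_loops(net, pops)
  # acyclic afterwards: one component, nodes - 1 edges
  expect_equal(nrow(res$edges), 15)
  expect_true(nrow(res$resolution) >= 1)
  # the high-frequency connection H1-H7 is the one kept
  kept_12 <- res$edges[res$edges$steps == 12, ]
  expect_equal(sort(unlist(kept_12[, c("from", "to")], use.names = FALSE)),
               c("H1", "H7"))
  expect_false(any(res$resolution$from == "H1" & res$resolution$to == "H7"))
  # acyclic input returned unchanged
  res2 <- resolve_loops(res, pops)
  expect_equal(res2$edges, res$edges)
})

test_that("constructed square keeps the high-frequency corner connection", {
  # 4-node cycle with equal steps; node A has dominant frequency, its two
  # incident edges must survive
  pi <- matrix(c(0, 1, 2, 1,
                 1, 0, 1, 2,
                 2, 1, 0, 1,
                 1, 2, 1, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  net <- build_network(distance_matrix(pi, "steps"),
                       frequencies = c(A = 50, B = 2, C = 2, D = 2))
  res <- resolve_loops(net)
  expect_equal(nrow(res$edges), 3)
  kept <- paste(res$edges$from, res$edges$to)
  expect_true(all(c("A B", "A D") %in% kept | all(c("A B", "A D") %in%
                  paste(res$edges$to, res$edges$from))))
})

test_that("lineage bipartition recovers the two fixture clades", {
  pops <- fixture_pops()
  pi <- pairwise_step_distances(fixture_coded())
  net <- resolve_loops(build_network(pi, colSums(pops$counts), limit = 20,
                                     pops = pops), pops)
  bip <- lineage_bipartition(net, pops)
  north <- names(bip$haplotype_groups)[bip$haplotype_groups ==
                                         bip$haplotype_groups[["H1"]]]
  south <- names(bip$haplotype_groups)[bip$haplotype_groups ==
                                         bip$haplotype_groups[["H7"]]]
  expect_setequal(north, paste0("H", 1:6))
  expect_setequal(south, paste0("H", 7:16))
  expect_true(bip$split_steps %in% 11:12)
  expect_equal(length(bip$mixed_populations), 0)
  # inter-lineage graph distance within the published range
  expect_true(network_steps_between(net, "H1", "H7") %in% 11:12)
  # bipartition is invariant to haplotype input order
  perm <- sample(16)
  pi2 <- pi[perm, perm]
  net2 <- resolve_loops(build_network(distance_matrix(unclass(pi2), "steps"),
                                      colSums(pops$counts)[rownames(pi2)]))
  bip2 <- lineage_bipartition(net2)
  north2 <- names(bip2$haplotype_groups)[bip2$haplotype_groups ==
                                           bip2$haplotype_groups[["H1"]]]
  expect_setequal(north2, north)
})

test_that("equal-step star raises an ambiguity error for the bipartition", {
  pi <- matrix(1, 4, 4) - diag(4)
  dimnames(pi) <- list(letters[1:4], letters[1:4])
  net <- build_network(distance_matrix(pi, "steps"))
  net <- resolve_loops(net)
  expect_error(lineage_bipartition(net), "ambiguous")
})

test_that("synthetic two-lineage data recovers the planted bipartition", {
  sim <- simulate_phylogeography(simulation_config(
    n_pops_north = 6, n_pops_south = 6, n_per_pop = 10, n_sites = 400,
    split_steps = 9, within_lineage_steps = 4, seed = 99))
  pi <- pairwise_step_distances(sim$coded)
  net <- resolve_loops(build_network(pi, colSums(sim$pops$counts),
                                     pops = sim$pops), sim$pops)
  bip <- lineage_bipartition(net, sim$pops)
  truth <- sim$truth$bipartition[names(bip$haplotype_groups)]
  expect_equal(length(unique(paste(bip$haplotype_groups, truth))), 2)
})
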