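## Statistical-parsimony haplotype network: connection limit, agglomerative
## minimum-spanning construction retaining tied alternatives (loops),
## frequency/interiority/geography loop resolution, and the lineage
## bipartition.

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps `j` at which a connection between two
#' haplotypes is still considered parsimonious (no superimposed changes)
#' with probability at least `1 - alpha`.
#'
#' The probability model: each of `n_characters` sites accrues hits as an
#' independent Poisson process with per-site rate `theta`; a site hit `n`
#' times differs between the two sequences with probability
#' `3/4 (1 - (-1/3)^n)` (equal exchange among four states). A `j`-step
#' connection is parsimonious exactly when the total number of hits equals
#' `j`, so
#' `P(parsimony | j of m sites differ) = r1^j * r0^(m - j)` with
#' `r1 = P(N = 1) / P(differ)` and `r0 = P(N = 0) / P(same)`. The nuisance
#' rate `theta` is calibrated so that the expected fraction of differing
#' sites matches the observed mean pairwise difference, following the
#' practice of estimating the connection limit from the data themselves.
#'
#' @param n_characters number of coded characters (sequence length).
#' @param alpha significance level in (0, 1); the limit is the largest `j`
#'   with parsimony probability `>= 1 - alpha`.
#' @param mean_pairwise_steps observed mean pairwise step distance used to
#'   calibrate the per-site rate; alternatively supply `pi`.
#' @param pi optional haplotype step [distance_matrix()]; its off-diagonal
#'   mean is used when `mean_pairwise_steps` is missing.
#' @return integer connection limit (at least 1).
#' @export
parsimony_connection_limit <- function(n_characters, alpha = 0.05,
                                       mean_pairwise_steps = NULL, pi = NULL) {
  if (n_characters < 1) stop("n_characters must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.null(mean_pairwise_steps)) {
    if (is.null(pi)) stop("supply mean_pairwise_steps or pi")
    mean_pairwise_steps <- mean(pi[upper.tri(pi)])
  }
  m <- n_characters
  q <- mean_pairwise_steps / m
  if (q <= 0) return(1L)
  if (q >= 0.75) stop("mean pairwise difference too large for the model")
  theta <- -0.75 * log(1 - 4 * q / 3)
  p_diff <- q                      # by calibration
  r1 <- theta * exp(-theta) / p_diff
  r0 <- exp(-theta) / (1 - p_diff)
  limit <- 0L
  for (j in seq_len(m)) {
    logp <- j * log(r1) + (m - j) * log(r0)
    if (logp >= log1p(-alpha)) limit <- j else break
  }
  max(limit, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Agglomerative minimum-spanning construction: component pairs are joined
#' in increasing order of step distance and, at each distance, all minimal
#' inter-component edges are retained, so tied alternative connections
#' produce loops. Edges longer than the connection limit are excluded,
#' which may leave the network disconnected.
#'
#' @param x an [coded_matrix()] over haplotypes, or a step
#'   [distance_matrix()].
#' @param frequencies named vector of haplotype frequencies (individuals
#'   carrying each haplotype).
#' @param limit connection limit in steps (see
#'   [parsimony_connection_limit()]); `Inf` keeps all minimal connections.
#' @param pops optional [population_table()] used to annotate nodes with
#'   the populations carrying each haplotype.
#' @return An object of class `hg_network`: `nodes` (id, frequency,
#'   populations), `edges` (from, to, steps), `limit`, `ties` (tied
#'   alternative edge batches recorded during construction), and
#'   `n_components`.
#' @export
build_network <- function(x, frequencies = NULL, limit = Inf, pops = NULL) {
  pi <- if (inherits(x, "hg_coded")) pairwise_step_distances(x) else x
  ids <- rownames(pi)
  H <- length(ids)
  if (H == 0) stop("empty input")
  if (is.null(frequencies)) frequencies <- stats::setNames(rep(1, H), ids)
  carried <- rep("", H)
  if (!is.null(pops)) {
    carried <- vapply(ids, function(h) {
      if (!h %in% colnames(pops$counts)) return("")
      paste(rownames(pops$counts)[pops$counts[, h] > 0], collapse = ",")
    }, character(1))
  }
  nodes <- data.frame(id = ids, frequency = as.numeric(frequencies[ids]),
                      populations = carried)
  comp <- seq_len(H)
  edges <- list()
  ties <- list()
  for (d in sort(unique(pi[upper.tri(pi)]))) {
    if (d > limit) break
    if (d == 0) next
    idx <- which(upper.tri(pi) & pi == d, arr.ind = TRUE)
    # evaluate component membership before merging anything at this level
    cross <- idx[comp[idx[, 1]] != comp[idx[, 2]], , drop = FALSE]
    if (nrow(cross) == 0) next
    batch <- data.frame(from = ids[cross[, 1]], to = ids[cross[, 2]],
                        steps = d,
                        comp_a = pmin(comp[cross[, 1]], comp[cross[, 2]]),
                        comp_b = pmax(comp[cross[, 1]], comp[cross[, 2]]))
    edges[[length(edges) + 1L]] <- batch[, c("from", "to", "steps")]
    # tied alternatives: several minimal edges between one component pair
    key <- paste(batch$comp_a, batch$comp_b)
    for (k in unique(key[duplicated(key)])) {
      ties[[length(ties) + 1L]] <-
        batch[key == k, c("from", "to", "steps")]
    }
    for (r in seq_len(nrow(cross))) {
      ca <- comp[cross[r, 1]]; cb <- comp[cross[r, 2]]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), steps = numeric())
  structure(list(nodes = nodes, edges = edges, limit = limit, ties = ties,
                 n_components = length(unique(comp)),
                 resolution = NULL),
            class = "hg_network")
}

#' @export
print.hg_network <- function(x, ...) {
  cat("Haplotype network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, limit", x$limit, "steps,", x$n_components, "component(s)\n")
  if (length(x$ties)) {
    cat("Tied alternative connections (loops):", length(x$ties), "batch(es)\n")
  }
  if (!is.null(x$resolution) && nrow(x$resolution)) {
    cat("Loop resolution removed", nrow(x$resolution), "edge(s)\n")
  }
  invisible(x)
}

#' igraph view of a haplotype network
#'
#' @param net an `hg_network`.
#' @return an igraph graph with node attributes `frequency`, `populations`
#'   and edge attribute `steps`.
#' @export
network_graph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

# smallest cycle through any edge, as a data frame of its edges, or NULL
.find_cycle <- function(edges, nodes) {
  if (nrow(edges) == 0) return(NULL)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes["id"])
  for (e in seq_len(nrow(edges))) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = edges$from[e], to = edges$to[e],
                             output = "vpath"))$vpath[[1]]
    if (length(sp) > 0) {
      path <- names(sp)
      cyc_edges <- unique(c(e, vapply(seq_len(length(path) - 1), function(k) {
        which((edges$from == path[k] & edges$to == path[k + 1]) |
              (edges$to == path[k] & edges$from == path[k + 1]))[1]
      }, 1L)))
      return(edges[cyc_edges, , drop = FALSE])
    }
  }
  NULL
}

#' Resolve loops in a haplotype network
#'
#' Ambiguous alternative connections (cycles) are broken one edge at a
#' time. Within a cycle, only the longest (maximum-step) edges are
#' candidates for removal; candidates are ranked by (1) the total frequency
#' of the haplotypes they connect (connections to common haplotypes are
#' kept), (2) the total degree of their endpoints (connections to interior
#' haplotypes are kept), (3) the geographic distance between the
#' populations carrying the two haplotypes (shorter kept), with a final
#' lexicographic tie-break on labels for determinism. The lowest-ranked
#' candidate is removed and the search repeats until the network is
#' acyclic. Acyclic input is returned unchanged.
#'
#' @param net an `hg_network`.
#' @param pops optional [population_table()] supplying haplotype carrier
#'   coordinates for the geographic criterion.
#' @return the network with cycles removed; removals are recorded in
#'   `$resolution`.
#' @export
resolve_loops <- function(net, pops = NULL) {
  stopifnot(inherits(net, "hg_network"))
  edges <- net$edges
  freq <- stats::setNames(net$nodes$frequency, net$nodes$id)
  geo_dist <- function(h1, h2) {
    if (is.null(pops) || is.null(pops$meta$lat)) return(0)
    p1 <- pops$counts[, h1] > 0
    p2 <- pops$counts[, h2] > 0
    if (!any(p1) || !any(p2)) return(0)
    .haversine(mean(pops$meta$lat[p1]), mean(pops$meta$lon[p1]),
               mean(pops$meta$lat[p2]), mean(pops$meta$lon[p2]))
  }
  removed <- list()
  repeat {
    cyc <- .find_cycle(edges, net$nodes)
    if (is.null(cyc)) break
    cand <- cyc[cyc$steps == max(cyc$steps), , drop = FALSE]
    deg <- table(factor(c(edges$from, edges$to), levels = net$nodes$id))
    score_freq <- freq[cand$from] + freq[cand$to]
    score_deg <- as.numeric(deg[cand$from] + deg[cand$to])
    score_geo <- vapply(seq_len(nrow(cand)),
                        function(r) geo_dist(cand$from[r], cand$to[r]), 0)
    lab <- paste(cand$from, cand$to)
    ord <- order(score_freq, score_deg, -score_geo, rank(lab))
    worst <- cand[ord[1], ]
    reason <- c("frequency", "interiority", "geography", "label")[
      which.max(c(length(unique(score_freq)) > 1,
                  length(unique(score_deg)) > 1,
                  length(unique(score_geo)) > 1, TRUE) *
                c(4, 3, 2, 1))]
    removed[[length(removed) + 1L]] <-
      data.frame(from = worst$from, to = worst$to, steps = worst$steps,
                 rule = reason)
    drop <- which(edges$from == worst$from & edges$to == worst$to &
                  edges$steps == worst$steps)[1]
    edges <- edges[-drop, , drop = FALSE]
  }
  net$edges <- edges
  net$resolution <- if (length(removed)) do.call(rbind, removed) else
    data.frame(from = character(), to = character(), steps = numeric(),
               rule = character())
  net
}

#' Split a connected network into its two deepest lineages
#'
#' Removes the maximum-step edge class; the remaining graph must fall into
#' exactly two components, which define the lineage bipartition. Populations
#' inherit the lineage of the haplotypes they carry; populations carrying
#' haplotypes of both lineages are flagged.
#'
#' @param net an `hg_network` (resolve loops first if ties are present).
#' @param pops optional [population_table()] to map populations onto
#'   lineages.
#' @return An object of class `hg_bipartition`: `haplotype_groups` (named
#'   vector haplotype -> `"A"`/`"B"`), `split_steps`, `population_groups`,
#'   `mixed_populations`.
#' @export
lineage_bipartition <- function(net, pops = NULL) {
  stopifnot(inherits(net, "hg_network"))
  if (nrow(net$edges) == 0) stop("network has no edges")
  maxd <- max(net$edges$steps)
  keep <- net$edges[net$edges$steps < maxd, , drop = FALSE]
  g <- igraph::graph_from_data_frame(keep, directed = FALSE,
                                     vertices = net$nodes["id"])
  cmp <- igraph::components(g)
  if (cmp$no != 2) {
    stop("removing the ", maxd, "-step edge class yields ", cmp$no,
         " components; lineage bipartition ambiguous (candidates: ",
         paste(net$edges$from[net$edges$steps == maxd],
               net$edges$to[net$edges$steps == maxd], sep = "-",
               collapse = ", "), ")")
  }
  side <- c("A", "B")[cmp$membership]
  names(side) <- names(cmp$membership)
  side <- side[net$nodes$id]
  pop_groups <- NULL
  mixed <- character()
  if (!is.null(pops)) {
    pop_groups <- vapply(rownames(pops$counts), function(p) {
      carried <- colnames(pops$counts)[pops$counts[p, ] > 0]
      lg <- unique(side[carried])
      if (length(lg) > 1) "mixed" else lg
    }, character(1))
    mixed <- names(pop_groups)[pop_groups == "mixed"]
    if (length(mixed)) {
      warning("populations carry haplotypes of both lineages: ",
              paste(mixed, collapse = ", "))
    }
  }
  structure(list(haplotype_groups = side, split_steps = maxd,
                 population_groups = pop_groups,
                 mixed_populations = mixed),
            class = "hg_bipartition")
}

#' @export
print.hg_bipartition <- function(x, ...) {
  for (g in unique(x$haplotype_groups)) {
    cat("Lineage", g, ":",
        paste(names(x$haplotype_groups)[x$haplotype_groups == g],
              collapse = " "), "\n")
  }
  cat("Deepest split:", x$split_steps, "steps\n")
  invisible(x)
}

#' Graph distance between two haplotypes in a network
#'
#' Sum of edge steps along the shortest path.
#'
#' @param net an `hg_network`.
#' @param from,to haplotype ids.
#' @return numeric distance in steps (Inf if disconnected).
#' @export
network_steps_between <- function(net, from, to) {
  g <- network_graph(net)
  as.numeric(igraph::distances(g, v = from, to = to,
                               weights = igraph::E(g)$steps))
}
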