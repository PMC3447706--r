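## Synthetic phylogeographic data with known truth: two deeply split
## haplotype lineages, a star-like low-diversity lineage with spatially
## random haplotype placement (the "northern" pattern) and a serially
## diverging lineage whose haplotype frequencies follow an
## isolation-by-distance kernel along a transect (the "southern" pattern).

#' Configuration for the synthetic-data generator
#'
#' Defaults restate the reference survey's world: 31 + 16 populations of 15
#' individuals, 1381 coded characters, an 11-step inter-lineage split, 6
#' derived haplotypes per lineage (23 mutations in total) and 5 of the 23
#' mutations realized as binary indels.
#'
#' @param n_pops_north,n_pops_south population counts for the two regions.
#' @param n_per_pop individuals sampled per population.
#' @param n_sites coded characters in the matrix.
#' @param split_steps mutations separating the two lineage ancestors.
#' @param within_lineage_steps derived haplotypes per lineage (each one
#'   mutation: a star around the ancestor in the north, a serial chain in
#'   the south).
#' @param ibd_strength decay rate of the southern frequency-distance
#'   kernel (0 = no isolation by distance).
#' @param star_dominance frequency of the central northern haplotype in
#'   (0, 1].
#' @param indel_fraction fraction of mutations realized as binary indel
#'   characters; the count is `round(indel_fraction * total mutations)`.
#' @param segment_split coded position ending the first of the two
#'   concatenated segments.
#' @param indel_sites optional explicit coded positions for the indel
#'   mutations.
#' @param seed optional integer seed.
#' @return A validated list of class `hg_simconfig`.
#' @export
simulation_config <- function(n_pops_north = 31, n_pops_south = 16,
                              n_per_pop = 15, n_sites = 1381,
                              split_steps = 11, within_lineage_steps = 6,
                              ibd_strength = 8, star_dominance = 0.8,
                              indel_fraction = 5 / 23, segment_split = 372,
                              indel_sites = NULL, seed = NULL) {
  cfg <- list(n_pops_north = n_pops_north, n_pops_south = n_pops_south,
              n_per_pop = n_per_pop, n_sites = n_sites,
              split_steps = split_steps,
              within_lineage_steps = within_lineage_steps,
              ibd_strength = ibd_strength, star_dominance = star_dominance,
              indel_fraction = indel_fraction, segment_split = segment_split,
              indel_sites = indel_sites, seed = seed)
  with(cfg, {
    stopifnot(n_pops_north >= 1, n_pops_south >= 1, n_per_pop >= 2,
              split_steps >= 1, within_lineage_steps >= 0,
              ibd_strength >= 0, star_dominance > 0, star_dominance <= 1,
              indel_fraction >= 0, indel_fraction <= 1)
    total <- split_steps + 2 * within_lineage_steps
    if (total > n_sites) {
      stop("more requested mutations (", total, ") than sites (", n_sites, ")")
    }
  })
  structure(cfg, class = "hg_simconfig")
}

.mutate_state <- function(state, is_indel) {
  if (is_indel) {
    if (state == "1") "0" else "1"
  } else {
    sample(setdiff(c("A", "C", "G", "T"), state), 1)
  }
}

#' Simulate a two-lineage phylogeographic survey
#'
#' Generates a random root sequence, derives the two lineage ancestors by
#' `split_steps` mutations at distinct sites (infinite-sites model, so
#' step distances equal mutation counts exactly), adds
#' `within_lineage_steps` single-mutation derived haplotypes per lineage
#' (star topology in the north, serial chain in the south), and samples
#' haplotype counts per population: northern populations draw from a fixed
#' star-dominated frequency vector (spatially random), southern
#' populations from an exponential isolation-by-distance kernel linking
#' transect position to chain position.
#'
#' @param config an [simulation_config()].
#' @return list with `pops` (an `hg_pops`), `coded` (an `hg_coded` over
#'   all haplotypes), and `truth` (`bipartition`, `split_steps`,
#'   `d_A_expected`, expected frequency vectors, `config`).
#' @export
simulate_phylogeography <- function(config = simulation_config()) {
  stopifnot(inherits(config, "hg_simconfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$n_sites
  wls <- config$within_lineage_steps
  total_mut <- config$split_steps + 2 * wls
  n_indel <- round(config$indel_fraction * total_mut)

  if (is.null(config$indel_sites)) {
    # adjacent indel sites would fuse into a single gap run when the
    # matrix is materialized as an alignment, merging two mutations into
    # one character; redraw until indel sites are pairwise non-adjacent
    for (try in 1:100) {
      sites <- sample.int(L, total_mut)
      indel_sites <- if (n_indel > 0) sites[seq_len(n_indel)] else integer()
      if (length(indel_sites) < 2 || min(diff(sort(indel_sites))) > 1) break
    }
    sites <- sample(sites)               # mutation order independent of type
  } else {
    indel_sites <- config$indel_sites
    if (length(indel_sites) != n_indel) {
      stop("indel_sites must supply exactly ", n_indel, " positions")
    }
    rest <- sample(setdiff(seq_len(L), indel_sites), total_mut - n_indel)
    sites <- sample(c(indel_sites, rest))
  }
  is_indel_col <- rep(FALSE, L)
  is_indel_col[indel_sites] <- TRUE

  root <- ifelse(is_indel_col, "1", sample(c("A", "C", "G", "T"), L,
                                           replace = TRUE))
  apply_mut <- function(hap, site) {
    hap[site] <- .mutate_state(hap[site], is_indel_col[site])
    hap
  }
  split_sites <- sites[seq_len(config$split_steps)]
  north_sites <- sites[config$split_steps + seq_len(wls)]
  south_sites <- sites[config$split_steps + wls + seq_len(wls)]

  north <- list(root)
  for (s in north_sites) north[[length(north) + 1L]] <- apply_mut(root, s)
  south_anc <- Reduce(apply_mut, split_sites, accumulate = FALSE, init = root)
  south <- list(south_anc)
  for (s in south_sites) {
    south[[length(south) + 1L]] <- apply_mut(south[[length(south)]], s)
  }
  haps <- c(north, south)
  ids <- c(paste0("N", seq_along(north) - 1L), paste0("S", seq_along(south) - 1L))
  states <- do.call(rbind, haps)
  rownames(states) <- ids
  seg <- data.frame(name = c("seg1", "seg2"),
                    start = c(1L, config$segment_split + 1L),
                    end = c(config$segment_split, L))
  cm <- coded_matrix(states, data.frame(
    position = seq_len(L),
    origin = ifelse(is_indel_col, "indel_binary", "substitution"),
    segment = ifelse(seq_len(L) <= config$segment_split, "seg1", "seg2"),
    source_start = seq_len(L), source_end = seq_len(L)))

  # expected per-population frequency vectors
  n_haps <- length(ids)
  north_probs <- c(config$star_dominance,
                   rep((1 - config$star_dominance) / max(wls, 1), wls))
  if (wls == 0) north_probs <- 1
  transect <- function(n) if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  xs <- transect(config$n_pops_south)
  us <- transect(wls + 1)
  south_probs <- vapply(xs, function(x) {
    w <- exp(-config$ibd_strength * abs(x - us))
    w / sum(w)
  }, numeric(wls + 1))
  south_probs <- matrix(south_probs, nrow = wls + 1)  # x n_pops_south

  counts <- matrix(0L, config$n_pops_north + config$n_pops_south, n_haps)
  colnames(counts) <- ids
  for (j in seq_len(config$n_pops_north)) {
    counts[j, seq_along(north)] <-
      as.integer(stats::rmultinom(1, config$n_per_pop, north_probs))
  }
  for (j in seq_len(config$n_pops_south)) {
    counts[config$n_pops_north + j, length(north) + seq_along(south)] <-
      as.integer(stats::rmultinom(1, config$n_per_pop, south_probs[, j]))
  }
  xn <- transect(config$n_pops_north)
  meta <- data.frame(
    pop = c(sprintf("NP%02d", seq_len(config$n_pops_north)),
            sprintf("SP%02d", seq_len(config$n_pops_south))),
    region = rep(c("north", "south"),
                 c(config$n_pops_north, config$n_pops_south)),
    lat = c(rep(40, config$n_pops_north), rep(29.5, config$n_pops_south)),
    lon = c(104 + 20 * xn, 99 + 7 * xs))
  rownames(counts) <- meta$pop
  pops <- population_table(meta, counts)

  pi <- pairwise_step_distances(cm)
  EN <- c(north_probs, rep(0, length(south)))
  ES <- c(rep(0, length(north)), rowMeans(south_probs))
  D <- unclass(pi)
  d_XY <- as.numeric(EN %*% D %*% ES) / L
  d_A <- d_XY - (as.numeric(EN %*% D %*% EN) / L +
                 as.numeric(ES %*% D %*% ES) / L) / 2
  truth <- list(
    bipartition = stats::setNames(rep(c("north", "south"),
                                      c(length(north), length(south))), ids),
    split_steps = config$split_steps,
    d_A_expected = d_A,
    north_probs = EN, south_probs = ES,
    indel_sites = sort(indel_sites),
    config = config)
  list(pops = pops, coded = cm, truth = truth)
}

#' Materialize a synthetic survey as a raw gapped alignment
#'
#' Expands the simulated haplotypes into one sequence per individual, with
#' each binary indel character realized as a gap run of the requested
#' length (present haplotypes carry bases, absent ones gaps), so that
#' [code_indels()] followed by [collapse_haplotypes()] recovers the coded
#' matrix. Raw segment boundaries are shifted by the extra indel bases.
#'
#' @param sim result of [simulate_phylogeography()].
#' @param indel_lengths integer vector of run lengths for the indel
#'   columns in coded-position order (recycled); default all 1.
#' @return An [aligned_sequences()] over individuals, with attribute
#'   `haplotype` mapping rows to haplotype ids.
#' @export
synthetic_alignment <- function(sim, indel_lengths = 1L) {
  cm <- sim$coded
  indel_cols <- which(cm$columns$origin == "indel_binary")
  lens <- rep_len(as.integer(indel_lengths), length(indel_cols))
  L <- ncol(cm$states)
  raw_len_of <- rep(1L, L)
  raw_len_of[indel_cols] <- lens
  # bases filling each indel run when present
  fillers <- lapply(lens, function(l) sample(c("A", "C", "G", "T"), l,
                                             replace = TRUE))
  names(fillers) <- as.character(indel_cols)
  expand_row <- function(states) {
    out <- vector("list", L)
    for (j in seq_len(L)) {
      out[[j]] <- if (raw_len_of[j] == 1L && !(j %in% indel_cols)) {
        states[j]
      } else if (states[j] == "1") {
        fillers[[as.character(j)]]
      } else if (states[j] == "0") {
        rep("-", raw_len_of[j])
      } else states[j]
    }
    unlist(out)
  }
  hap_raw <- t(apply(cm$states, 1, expand_row))
  ex <- expand_individuals(sim$pops, cm)
  hap_of_ind <- ex$haplotype
  seqs <- hap_raw[hap_of_ind, , drop = FALSE]
  rownames(seqs) <- rownames(ex$coded$states)
  split_coded <- sim$truth$config$segment_split
  extra_seg1 <- sum(raw_len_of[seq_len(split_coded)] - 1L)
  segs <- data.frame(name = c("seg1", "seg2"),
                     start = c(1L, split_coded + extra_seg1 + 1L),
                     end = c(split_coded + extra_seg1, sum(raw_len_of)))
  aln <- aligned_sequences(rownames(seqs), seqs, segs)
  attr(aln, "haplotype") <- stats::setNames(hap_of_ind, rownames(seqs))
  aln
}
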