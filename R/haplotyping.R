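## Indel coding, haplotype collapsing, polymorphic-site accounting and
## inter-haplotype step distances.

#' Code gap runs of an alignment as binary indel characters
#'
#' Every maximal shared gap run becomes one binary character (`1` = bases
#' present, `0` = absent); multi-base runs therefore shorten the matrix by
#' `run length - 1` columns each. Staggered runs that differ in boundaries
#' across sequences are split at every distinct boundary, and each
#' resulting sub-run is coded as one binary character, which keeps the
#' coding deterministic and independent of input order. Non-gap columns
#' pass through unchanged as substitution columns. If sequences that carry
#' bases inside an indel interval disagree among themselves, those sites
#' are additionally emitted as substitution columns with `N` for the
#' deleted sequences (with a warning).
#'
#' @param aln an [aligned_sequences()] object.
#' @return An [coded_matrix()] whose column metadata records origin
#'   (`substitution` / `indel_binary`), coded position, segment, and source
#'   span in the uncoded alignment.
#' @export
code_indels <- function(aln) {
  stopifnot(inherits(aln, "hg_alignment"))
  seqm <- aln$seq
  L <- ncol(seqm)
  isgap <- seqm == "-"
  # breakpoints: every distinct run boundary across all sequences
  cut <- rep(FALSE, L + 1L)
  for (i in seq_len(nrow(seqm))) {
    r <- rle(isgap[i, ])
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    cut[starts[r$values]] <- TRUE
    cut[ends[r$values] + 1L] <- TRUE
  }
  anygap <- colSums(isgap) > 0
  segment_of <- function(p) {
    aln$segments$name[p >= aln$segments$start & p <= aln$segments$end][1]
  }
  states_list <- list()
  meta <- list()
  j <- 1L
  while (j <= L) {
    if (!anygap[j]) {
      states_list[[length(states_list) + 1L]] <- seqm[, j]
      meta[[length(meta) + 1L]] <- list(origin = "substitution",
                                        segment = segment_of(j),
                                        source_start = j, source_end = j)
      j <- j + 1L
    } else {
      e <- j
      while (e + 1L <= L && anygap[e + 1L] && !cut[e + 1L]) e <- e + 1L
      block <- isgap[, j:e, drop = FALSE]
      full <- rowSums(block) == (e - j + 1L)
      none <- rowSums(block) == 0L
      if (!all(full | none)) {
        stop("conflicting gap-run boundaries in span ", j, "-", e)
      }
      states_list[[length(states_list) + 1L]] <- ifelse(full, "0", "1")
      meta[[length(meta) + 1L]] <- list(origin = "indel_binary",
                                        segment = segment_of(j),
                                        source_start = j, source_end = e)
      # substitution variation among the sequences carrying bases
      sub <- seqm[!full, j:e, drop = FALSE]
      if (nrow(sub) > 1) {
        for (k in seq_len(ncol(sub))) {
          if (length(unique(sub[, k])) > 1) {
            warning("substitution variation inside indel span ", j, "-", e,
                    "; emitted with N for deleted sequences")
            col <- rep("N", nrow(seqm))
            col[!full] <- seqm[!full, j + k - 1L]
            states_list[[length(states_list) + 1L]] <- col
            meta[[length(meta) + 1L]] <- list(origin = "substitution",
                                              segment = segment_of(j),
                                              source_start = j + k - 1L,
                                              source_end = j + k - 1L)
          }
        }
      }
      j <- e + 1L
    }
  }
  states <- do.call(cbind, states_list)
  rownames(states) <- rownames(seqm)
  columns <- data.frame(
    position = seq_along(meta),
    origin = vapply(meta, `[[`, "", "origin"),
    segment = vapply(meta, `[[`, "", "segment"),
    source_start = vapply(meta, function(x) as.integer(x$source_start), 1L),
    source_end = vapply(meta, function(x) as.integer(x$source_end), 1L))
  coded_matrix(states, columns)
}

#' Collapse identical coded rows into haplotypes
#'
#' Two individuals share a haplotype if and only if their coded rows are
#' identical. Haplotypes are enumerated in first-appearance order of the
#' input. Rows containing missing states (`N`) are collapsed like any other
#' state but flagged as ambiguous, and should be excluded from distance
#' computations.
#'
#' @param cm an [coded_matrix()] over individuals.
#' @param prefix label prefix for new haplotype ids.
#' @return list with `coded` (an `hg_coded` over haplotypes), `assignment`
#'   (named character vector individual -> haplotype id), `frequencies`
#'   (named integer vector), and `ambiguous` (ids of rows containing `N`).
#' @export
collapse_haplotypes <- function(cm, prefix = "H") {
  stopifnot(inherits(cm, "hg_coded"))
  key <- apply(cm$states, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  hap_id <- paste0(prefix, match(key, key[first]))  # first-appearance order
  hap_states <- cm$states[first, , drop = FALSE]
  rownames(hap_states) <- paste0(prefix, seq_len(sum(first)))
  assignment <- stats::setNames(hap_id, rownames(cm$states))
  ambiguous <- rownames(cm$states)[apply(cm$states == "N", 1, any)]
  if (length(ambiguous)) {
    warning(length(ambiguous), " rows contain missing states; flagged ambiguous")
  }
  freqs <- table(factor(hap_id, levels = rownames(hap_states)))
  list(coded = coded_matrix(hap_states, cm$columns),
       assignment = assignment,
       frequencies = stats::setNames(as.integer(freqs), names(freqs)),
       ambiguous = ambiguous)
}

#' Count polymorphic coded characters
#'
#' A character is polymorphic when it shows at least two distinct non-missing
#' states. A single-row matrix has zero polymorphic characters by
#' convention.
#'
#' @param cm an [coded_matrix()].
#' @return list with `total` and `indel` (the binary-indel subcount).
#' @export
count_polymorphic_sites <- function(cm) {
  stopifnot(inherits(cm, "hg_coded"))
  if (nrow(cm$states) < 2) return(list(total = 0L, indel = 0L))
  nstate <- apply(cm$states, 2, function(s) length(setdiff(unique(s), "N")))
  poly <- nstate >= 2
  list(total = sum(poly),
       indel = sum(poly & cm$columns$origin == "indel_binary"))
}

#' Pairwise mutational step distances between haplotypes
#'
#' `d_ij` = number of coded characters at which two rows differ. Characters
#' with a missing state in either member of a pair are skipped for that
#' pair (pairwise deletion).
#'
#' @param cm an [coded_matrix()] over haplotypes.
#' @return A [distance_matrix()] in units of steps.
#' @export
pairwise_step_distances <- function(cm) {
  stopifnot(inherits(cm, "hg_coded"))
  s <- cm$states
  n <- nrow(s)
  D <- matrix(0, n, n, dimnames = list(rownames(s), rownames(s)))
  for (j in seq_len(ncol(s))) {
    v <- s[, j]
    ok <- v != "N"
    D <- D + (outer(v, v, "!=") & outer(ok, ok, "&"))
  }
  distance_matrix(D, units = "steps")
}

#' Expand a population table into one coded row per individual
#'
#' @param pops an [population_table()].
#' @param cm an [coded_matrix()] over haplotypes covering every counted
#'   haplotype.
#' @return list with `coded` (individuals x characters) and `population`
#'   (factor of population codes, one per individual).
#' @export
expand_individuals <- function(pops, cm) {
  stopifnot(inherits(pops, "hg_pops"), inherits(cm, "hg_coded"))
  cnt <- pops$counts
  used <- colnames(cnt)[colSums(cnt) > 0]
  missing <- setdiff(used, rownames(cm$states))
  if (length(missing)) {
    stop("counted haplotypes missing from coded matrix: ",
         paste(missing, collapse = ", "))
  }
  hap_of_ind <- rep(rep(colnames(cnt), nrow(cnt)), as.vector(t(cnt)))
  pop_of_ind <- rep(rep(rownames(cnt), each = ncol(cnt)), as.vector(t(cnt)))
  states <- cm$states[hap_of_ind, , drop = FALSE]
  rownames(states) <- paste0(pop_of_ind, "_", seq_along(pop_of_ind))
  list(coded = coded_matrix(states, cm$columns),
       population = factor(pop_of_ind, levels = rownames(cnt)),
       haplotype = hap_of_ind)
}

#' Write a coded matrix as CSV
#'
#' Inverse of [read_coded_matrix()]; columns are named `c<position>`.
#'
#' @param cm an [coded_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coded_matrix <- function(cm, path) {
  df <- data.frame(haplotype = rownames(cm$states),
                   cm$states, check.names = FALSE)
  colnames(df)[-1] <- paste0("c", cm$columns$position)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
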