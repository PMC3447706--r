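test_that("indel coding collapses gap runs to binary characters", {
  aln <- aligned_sequences(c("a", "b"), c("AATG", "A-TG"))
  cm <- code_indels(aln)
  expect_equal(ncol(cm$states), 4)
  expect_equal(sum(cm$columns$origin == "indel_binary"), 1)
  j <- which(cm$columns$origin == "indel_binary")
  expect_equal(unname(cm$states[, j]), c("1", "0"))
  # substitution columns pass through byte-for-byte
  expect_equal(unname(cm$states[, -j]), unname(aln$seq[, -2]))
})

test_that("coded length follows the closed form on planted gap runs", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(60:120, 1)
    n <- sample(4:8, 1)
    base <- matrix(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   n, L, byrow = TRUE)
    runs <- list()
    pos <- 1
    for (k in 1:3) {
      len <- sample(1:7, 1)
      start <- pos + sample(3:10, 1)
      if (start + len - 1 >= L) break
      runs[[k]] <- c(start, start + len - 1)
      pos <- start + len
    }
    carriers <- sample(n, max(1, n %/% 2))
    for (r in runs) base[carriers, r[1]:r[2]] <- "-"
    aln <- aligned_sequences(paste0("s", 1:n), base)
    cm <- code_indels(aln)
    expect_equal(ncol(cm$states),
                 L - sum(vapply(runs, function(r) r[2] - r[1], 0)))
    expect_equal(sum(cm$columns$origin == "indel_binary"), length(runs))
  }
})

test_that("paper-shaped alignment codes 1396 raw to 1381 characters", {
  # indel lengths {1,1,5,6,7}: coded length 1396 - (4+5+6) = 1381
  cfg <- simulation_config(seed = 5)
  sim <- simulate_phylogeography(cfg)
  aln <- synthetic_alignment(sim, indel_lengths = c(6, 1, 1, 5, 7))
  expect_equal(nrow(aln$seq), 705)
  expect_equal(ncol(aln$seq), 1396)
  cm <- code_indels(aln)
  expect_equal(ncol(cm$states), 1381)
})

test_that("staggered gap runs split deterministically at boundaries", {
  aln <- aligned_sequences(c("a", "b", "c"),
                           c("AAAAAA", "A---AA", "A--AAA"))
  cm <- code_indels(aln)
  # run 2-4 (b) and 2-3 (c) share a boundary at 2, split at 4: two
  # binary characters (2-3 and 4-4) plus the 3 untouched columns
  expect_equal(sum(cm$columns$origin == "indel_binary"), 2)
  expect_equal(ncol(cm$states), 5)
  spans <- cm$columns[cm$columns$origin == "indel_binary",
                      c("source_start", "source_end")]
  expect_equal(unname(as.matrix(spans)), rbind(c(2L, 3L), c(4L, 4L)))
})

test_that("haplotype collapsing is exact, idempotent and order-invariant", {
  m <- r_coded(6, 12)
  dup <- coded_matrix(m$states[rep(1:6, each = 3), , drop = FALSE])
  rownames_states <- paste0("ind", 1:18)
  coll <- collapse_haplotypes(dup)
  expect_equal(nrow(coll$coded$states), 6)
  expect_true(all(coll$frequencies == 3))
  # permuting input rows permutes assignment but not the haplotype set
  perm <- sample(18)
  coll2 <- collapse_haplotypes(coded_matrix(dup$states[perm, , drop = FALSE]))
  key1 <- sort(unname(apply(coll$coded$states, 1, paste, collapse = "")))
  key2 <- sort(unname(apply(coll2$coded$states, 1, paste, collapse = "")))
  expect_equal(key1, key2)
  # identical rows collapse to one haplotype
  one <- collapse_haplotypes(coded_matrix(m$states[rep(1, 10), , drop = FALSE]))
  expect_equal(nrow(one$coded$states), 1)
  # rows with missing data are flagged ambiguous
  mm <- m$states
  mm[2, 5] <- "N"
  expect_warning(res <- collapse_haplotypes(coded_matrix(mm)), "ambiguous")
  expect_equal(res$ambiguous, rownames(mm)[2])
})

test_that("polymorphic site counting matches construction", {
  m <- matrix("A", 5, 50)
  rownames(m) <- paste0("h", 1:5)
  vary <- sample(50, 7)
  for (j in vary) m[sample(5, 2), j] <- "G"
  counts <- count_polymorphic_sites(coded_matrix(m))
  expect_equal(counts$total, 7)
  expect_equal(counts$indel, 0)
  # identical rows give zero; single row gives zero by convention
  expect_equal(count_polymorphic_sites(coded_matrix(m[c(1, 1), ]))$total, 0)
  expect_equal(count_polymorphic_sites(
    coded_matrix(m[1, , drop = FALSE]))$total, 0)
})

test_that("step distances equal the naive per-column oracle", {
  set.seed(21)
  for (rep in 1:25) {
    m <- r_coded(sample(3:8, 1), sample(5:30, 1))
    s <- m$states
    if (rep %% 3 == 0) s[sample(length(s), 3)] <- "N"  # missing data
    D <- suppressWarnings(pairwise_step_distances(coded_matrix(s)))
    expect_equal(unclass(D), o_hamming(s), ignore_attr = TRUE)
  }
})

test_that("fixture distances match the printed polymorphic table", {
  pi <- pairwise_step_distances(fixture_coded())
  expect_equal(pi["H1", "H2"], 1)
  expect_equal(pi["H1", "H1"], 0)
  expect_equal(pi["H1", "H6"], 2)
  expect_equal(pi["H1", "H7"], 12)
  expect_equal(pi["H5", "H11"], 12)
  # triangle inequality on the whole matrix
  H <- nrow(pi)
  for (i in 1:H) for (j in 1:H) {
    expect_true(all(pi[i, j] <= pi[i, ] + pi[, j]))
  }
})

test_that("expanding the fixture reconstitutes 705 individuals and 16 haplotypes", {
  pops <- fixture_pops()
  cm <- fixture_coded()
  ex <- expand_individuals(pops, cm)
  expect_equal(nrow(ex$coded$states), 705)
  coll <- collapse_haplotypes(ex$coded)
  expect_equal(nrow(coll$coded$states), 16)
  counts <- count_polymorphic_sites(ex$coded)
  expect_equal(counts$total, 23)
  expect_equal(counts$indel, 5)
})

test_that("coded matrices round-trip through CSV", {
  cm <- fixture_coded()
  tmp <- tempfile(fileext = ".csv")
  write_coded_matrix(cm, tmp)
  back <- read_coded_matrix(tmp)
  expect_equal(back$states, cm$states)
  expect_equal(back$columns$position, cm$columns$position)
  expect_equal(back$columns$origin, cm$columns$origin)
})
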