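#' haplogeo: chloroplast haplotype phylogeography
#'
#' Tools for intraspecific cpDNA phylogeography: haplotype coding and
#' collapsing, ordered/unordered diversity statistics with a permutation
#' test for phylogeographic structure, hierarchical AMOVA, a
#' statistical-parsimony haplotype network, isolation-by-distance Mantel
#' analysis, and net-divergence molecular-clock dating.
#'
#' @keywords internal
#' @aliases haplogeo-package
"_PACKAGE"

## ---------------------------------------------------------------------------
## Domain containers
## ---------------------------------------------------------------------------

VALID_CODED_STATES <- c("A", "C", "G", "T", "0", "1", "N")
VALID_ALIGN_STATES <- c("A", "C", "G", "T", "N", "-")

#' Construct an aligned sequence set
#'
#' Container for a gapped multi-sequence DNA alignment together with the
#' spans of the concatenated segments (e.g. two plastid spacers). All
#' sequences must have identical length and the segment spans must tile the
#' alignment without overlap.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character matrix (sequences x sites) over `A,C,G,T,N,-`, or a
#'   character vector of equal-length strings.
#' @param segments data frame with columns `name`, `start`, `end` (1-based,
#'   inclusive). Defaults to a single segment spanning the alignment.
#' @return An object of class `hg_alignment` with elements `seq` (character
#'   matrix) and `segments`.
#' @export
aligned_sequences <- function(ids, seqs, segments = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- toupper(as.matrix(seqs))
  if (length(ids) != nrow(seqs)) stop("length(ids) != number of sequences")
  if (anyDuplicated(ids)) stop("duplicate sequence identifiers")
  bad <- setdiff(unique(as.vector(seqs)), VALID_ALIGN_STATES)
  if (length(bad)) stop("invalid alignment states: ", paste(bad, collapse = " "))
  rownames(seqs) <- ids
  L <- ncol(seqs)
  if (is.null(segments)) {
    segments <- data.frame(name = "aligned", start = 1L, end = L)
  }
  segments <- as.data.frame(segments)
  stopifnot(all(c("name", "start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (segments$start[1] != 1L || segments$end[nrow(segments)] != L ||
      (nrow(segments) > 1 &&
       any(segments$start[-1] != segments$end[-nrow(segments)] + 1L))) {
    stop("segment spans must tile the alignment 1..", L, " without overlap")
  }
  structure(list(seq = seqs, segments = segments), class = "hg_alignment")
}

#' @export
print.hg_alignment <- function(x, ...) {
  cat("Aligned sequence set:", nrow(x$seq), "sequences x", ncol(x$seq),
      "sites\n")
  cat("Segments:", paste(sprintf("%s (%d-%d)", x$segments$name,
                                 x$segments$start, x$segments$end),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a gapped multi-FASTA alignment, rejecting ragged alignments and
#' duplicated identifiers rather than repairing them.
#'
#' @param path path to a FASTA file.
#' @param segment_boundaries optional data frame (`name`, `start`, `end`)
#'   giving the spans of concatenated segments.
#' @return An [aligned_sequences()] object.
#' @export
read_fasta_alignment <- function(path, segment_boundaries = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  }
  m <- toupper(as.character(as.matrix(dna)))
  aligned_sequences(names(dna), m, segment_boundaries)
}

#' Write an aligned sequence set as FASTA
#'
#' @param aln an `hg_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hg_alignment"))
  dna <- ape::as.DNAbin(tolower(aln$seq))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Construct a coded character matrix
#'
#' The universal genetic input: haplotypes (or individuals) by coded
#' characters, where each character is either a substitution column (states
#' `A,C,G,T`) or a binary indel column (states `0/1`); `N` marks missing
#' data.
#'
#' @param states character matrix with row names (haplotype or individual
#'   ids) and one column per coded character.
#' @param columns optional data frame of per-column metadata with columns
#'   `position` (1-based position in the coded matrix coordinate system),
#'   `origin` (`"substitution"` or `"indel_binary"`), `segment`,
#'   `source_start`, `source_end`.
#' @return An object of class `hg_coded`.
#' @export
coded_matrix <- function(states, columns = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) {
    rownames(states) <- paste0("seq", seq_len(nrow(states)))
  }
  bad <- setdiff(unique(as.vector(states)), VALID_CODED_STATES)
  if (length(bad)) stop("invalid coded states: ", paste(bad, collapse = " "))
  if (any(apply(states, 2, function(s) all(s == "N")))) {
    stop("column with no observed (non-missing) state")
  }
  if (is.null(columns)) {
    columns <- data.frame(position = seq_len(ncol(states)),
                          origin = "substitution",
                          segment = "coded",
                          source_start = seq_len(ncol(states)),
                          source_end = seq_len(ncol(states)))
  }
  columns <- as.data.frame(columns)
  stopifnot(nrow(columns) == ncol(states))
  two_state <- vapply(seq_len(ncol(states)), function(j) {
    length(setdiff(unique(states[, j]), "N")) <= 2
  }, logical(1))
  if (any(columns$origin == "indel_binary" & !two_state)) {
    stop("indel_binary columns must have exactly two observed states")
  }
  structure(list(states = states, columns = columns), class = "hg_coded")
}

#' @export
print.hg_coded <- function(x, ...) {
  cat("Coded matrix:", nrow(x$states), "rows x", ncol(x$states),
      "characters (", sum(x$columns$origin == "indel_binary"),
      "indel-coded )\n")
  invisible(x)
}

#' Construct a population table
#'
#' Per-population metadata (coordinates, optional morphotype and region
#' labels) plus haplotype counts. Population codes are the primary keys.
#'
#' @param meta data frame with at least `pop`, `lat`, `lon` (decimal degrees
#'   or DMS strings); optional `locality`, `flower`, `habit`, `region`.
#' @param counts integer matrix populations x haplotypes; row names must
#'   equal `meta$pop`.
#' @return An object of class `hg_pops` with elements `meta` and `counts`.
#' @export
population_table <- function(meta, counts) {
  meta <- as.data.frame(meta)
  stopifnot("pop" %in% names(meta))
  if (anyDuplicated(meta$pop)) stop("duplicate population codes")
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) rownames(counts) <- meta$pop
  if (!identical(rownames(counts), as.character(meta$pop))) {
    stop("counts row names must match meta$pop")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("haplotype counts must be nonnegative integers")
  }
  if (any(rowSums(counts) < 1)) stop("every population needs n_k >= 1")
  for (cc in c("lat", "lon")) {
    if (cc %in% names(meta) && is.character(meta[[cc]])) {
      meta[[cc]] <- dms_to_decimal(meta[[cc]])
    }
  }
  if (!is.null(meta$lat) &&
      any(meta$lat < -90 | meta$lat > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90]")
  }
  if (!is.null(meta$lon) &&
      any(meta$lon < -180 | meta$lon > 180, na.rm = TRUE)) {
    stop("longitude out of [-180, 180]")
  }
  structure(list(meta = meta, counts = counts), class = "hg_pops")
}

#' @export
print.hg_pops <- function(x, ...) {
  cat("Population table:", nrow(x$counts), "populations,",
      ncol(x$counts), "haplotype columns,",
      sum(x$counts), "individuals\n")
  invisible(x)
}

#' Subset a population table
#'
#' @param pops an `hg_pops`.
#' @param which population codes or logical/integer index on rows.
#' @param drop_haplotypes drop haplotype columns with zero total count.
#' @return An `hg_pops` restricted to the selected populations.
#' @export
subset_populations <- function(pops, which, drop_haplotypes = FALSE) {
  stopifnot(inherits(pops, "hg_pops"))
  if (is.character(which)) which <- match(which, pops$meta$pop)
  if (anyNA(which)) stop("unknown population code")
  cnt <- pops$counts[which, , drop = FALSE]
  if (drop_haplotypes) cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  population_table(pops$meta[which, , drop = FALSE], cnt)
}

#' Construct a labelled distance matrix
#'
#' Symmetric nonnegative distance matrix over haplotypes or populations,
#' tagged with its units (`"steps"`, `"per-site"`, `"F_ST"`, `"km"`, ...).
#'
#' @param values square numeric matrix with dimnames.
#' @param units unit tag.
#' @return The matrix with class `hg_dist` and attribute `units`.
#' @export
distance_matrix <- function(values, units = "steps") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (max(abs(values - t(values))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(diag(values) != 0)) stop("distance matrix must have zero diagonal")
  if (any(values < 0)) stop("distances must be nonnegative")
  structure(values, units = units, class = c("hg_dist", "matrix", "array"))
}

#' @export
print.hg_dist <- function(x, ...) {
  cat("Distance matrix (", attr(x, "units"), "): ", nrow(x), " x ", ncol(x),
      "\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

## ---------------------------------------------------------------------------
## Coordinate parsing
## ---------------------------------------------------------------------------

#' Convert degree-minute-second coordinates to decimal degrees
#'
#' Accepts strings such as `30°03'54.2″` with an optional hemisphere letter
#' (`N`, `S`, `E`, `W`) before or after the numbers; `S` and `W` negate the
#' value. Inputs that already parse as plain numbers pass through unchanged.
#'
#' @param text character vector of coordinates.
#' @return numeric vector of decimal degrees (`D + M/60 + S/3600`).
#' @examples
#' dms_to_decimal("30°03'54.2″")
#' @export
dms_to_decimal <- function(text) {
  out <- suppressWarnings(as.numeric(text))
  todo <- which(is.na(out) & !is.na(text))
  if (!length(todo)) return(out)
  pat <- paste0("^\\s*([NSEWnsew])?\\s*([0-9]+)\\s*[°d]\\s*",
                "([0-9]+)\\s*['′m]\\s*([0-9]+(?:\\.[0-9]+)?)\\s*",
                "[\"″’'s]*\\s*([NSEWnsew])?\\s*$")
  for (i in todo) {
    m <- regmatches(text[i], regexec(pat, text[i]))[[1]]
    if (length(m) == 0L) stop("cannot parse DMS coordinate: ", text[i])
    d <- as.numeric(m[3]); mn <- as.numeric(m[4]); sc <- as.numeric(m[5])
    if (mn >= 60 || sc >= 60) {
      stop("minutes/seconds out of range in coordinate: ", text[i])
    }
    hemi <- toupper(paste0(m[2], m[6]))
    sgn <- if (grepl("S|W", hemi)) -1 else 1
    out[i] <- sgn * (d + mn / 60 + sc / 3600)
  }
  out
}

## ---------------------------------------------------------------------------
## Readers and packaged fixtures
## ---------------------------------------------------------------------------

#' Read a population table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row: a `pop` column of
#' population codes, coordinate columns `lat`/`lon` (decimal degrees or DMS
#' strings), optional `locality`, `flower`, `habit`, `region` columns, and
#' wide haplotype-count columns named `H1`, `H2`, ...
#'
#' @param path CSV path.
#' @return An [population_table()] object.
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  hcols <- grep("^H[0-9]+$", names(df), value = TRUE)
  if (!length(hcols)) stop("no haplotype count columns (H1, H2, ...) in ", path)
  meta_cols <- setdiff(names(df), hcols)
  counts <- as.matrix(df[, hcols, drop = FALSE])
  rownames(counts) <- df$pop
  pops <- population_table(df[, meta_cols, drop = FALSE], counts)
  if (!is.null(df$n) && any(rowSums(counts) != df$n)) {
    stop("declared n column disagrees with haplotype count sums")
  }
  pops
}

#' Read a coded haplotype matrix from CSV
#'
#' First column `haplotype` carries row labels; remaining columns are coded
#' characters, named `c<position>` where `<position>` is the 1-based position
#' in the coded coordinate system. Columns whose states are all `0`/`1` are
#' classified as binary indel characters.
#'
#' @param path CSV path.
#' @param segments optional data frame (`name`, `start`, `end`) over coded
#'   positions used to tag each column with its segment.
#' @return An [coded_matrix()] object.
#' @export
read_coded_matrix <- function(path, segments = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character")
  stopifnot(names(df)[1] == "haplotype")
  states <- as.matrix(df[, -1, drop = FALSE])
  rownames(states) <- df$haplotype
  pos <- as.integer(sub("^c", "", colnames(states)))
  if (anyNA(pos)) pos <- seq_len(ncol(states))
  origin <- vapply(seq_len(ncol(states)), function(j) {
    s <- setdiff(unique(states[, j]), "N")
    if (all(s %in% c("0", "1"))) "indel_binary" else "substitution"
  }, character(1))
  seg <- rep("coded", length(pos))
  if (!is.null(segments)) {
    for (k in seq_len(nrow(segments))) {
      seg[pos >= segments$start[k] & pos <= segments$end[k]] <- segments$name[k]
    }
  }
  coded_matrix(states, data.frame(position = pos, origin = origin,
                                  segment = seg, source_start = pos,
                                  source_end = pos))
}

#' Load a packaged reference fixture
#'
#' Two fixtures transcribe the reference survey shipped with the package:
#' `"table1"`, a 47-population table (15 individuals each, 705 total) with
#' DMS coordinates, morphotype and region labels, and counts of haplotypes
#' H1-H16; and `"table2"`, the 16 x 23 coded haplotype matrix (23 variable
#' characters of a 1381-character coded cpDNA matrix, 5 of them binary
#' indel codes). Opaque indel symbols of the printed table are stored as
#' `0`/`1`; distances depend only on state identity.
#'
#' @param name `"table1"` or `"table2"`.
#' @return An `hg_pops` (table1) or `hg_coded` (table2).
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  if (name == "table1") {
    read_population_table(system.file("extdata", "table1_populations.csv",
                                      package = "haplogeo", mustWork = TRUE))
  } else {
    read_coded_matrix(system.file("extdata", "table2_haplotypes.csv",
                                  package = "haplogeo", mustWork = TRUE),
                      segments = data.frame(
                        name = c("trnH-psbA", "trnS-trnfM"),
                        start = c(1L, 373L), end = c(372L, 1381L)))
  }
}

## ---------------------------------------------------------------------------
## Report and network serialization
## ---------------------------------------------------------------------------

#' Write a results bundle as JSON
#'
#' Values round-trip to machine precision ([read_report()] returns the same
#' numbers).
#'
#' @param results named list of results (may be empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' Read back a JSON results bundle
#'
#' @param path path written by [write_report()].
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a haplotype network as GML and TSV
#'
#' Nodes carry haplotype frequency (and carrying populations when known);
#' edges carry mutational steps as weights.
#'
#' @param net an `hg_network` (see [build_network()]).
#' @param gml_path output GML path.
#' @param tsv_path optional output path for a tab-separated edge list.
#' @return `gml_path`, invisibly.
#' @export
write_network <- function(net, gml_path, tsv_path = NULL) {
  g <- network_graph(net)
  igraph::E(g)$weight <- igraph::E(g)$steps
  igraph::write_graph(g, gml_path, format = "gml")
  if (!is.null(tsv_path)) {
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gml_path)
}
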