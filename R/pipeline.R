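## Orchestration: run the full analysis from a configuration list (or JSON
## file) and assemble the machine-readable report.

#' Default pipeline configuration
#'
#' The defaults reproduce the reference analysis settings: 1000
#' permutations for the N_ST/G_ST test, 1023 for AMOVA, 999 for Mantel
#' tests, the standard plastid spacer substitution rate 1.01e-9, a 95%
#' parsimony connection limit, and the step-distance Phi_ST flavour of
#' pairwise differentiation.
#'
#' @param out_dir output directory for report files (`NULL` = no files).
#' @param seed master seed; each stage derives its own stream from it.
#' @return named list of class `hg_config`.
#' @export
default_config <- function(out_dir = NULL, seed = 1L) {
  structure(list(
    input = list(fixtures = TRUE, alignment = NULL, populations = NULL,
                 segment_boundaries = NULL),
    n_perm_diversity = 1000L,
    n_perm_amova = 1023L,
    n_perm_mantel = 999L,
    seed = as.integer(seed),
    mu = 1.01e-9,
    alpha = 0.05,
    fst_kernel = "steps",
    resolve_loops = TRUE,
    fixed_limit = NULL,
    out_dir = out_dir), class = "hg_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unspecified fields fall back to [default_config()] values.
#'
#' @param path JSON file.
#' @return `hg_config` list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

# per-stage reproducible seeds derived from the master seed
.stage_seed <- function(seed, stage) {
  offsets <- c(diversity = 11L, amova = 23L, mantel = 37L, synthetic = 53L)
  (as.integer(seed) + offsets[[stage]] * 1009L) %% .Machine$integer.max
}

#' Run the full phylogeographic pipeline
#'
#' Stages, in order: input loading (packaged fixtures or user files),
#' haplotyping (indel coding and collapsing when a raw alignment is given),
#' step distances, parsimony network with loop resolution and lineage
#' bipartition, diversity and differentiation per grouping with the
#' N_ST/G_ST permutation test, three-level AMOVA per grouping, pairwise
#' Phi_ST, regional Mantel tests with gene-flow/drift classification, and
#' net-divergence dating of the two lineages. Writes `report.json`,
#' CSV/TSV tables and the network GML into `out_dir` when set, and logs
#' stage timings to stderr.
#'
#' @param config an `hg_config` list, or path to a JSON configuration.
#' @return the report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  t0 <- Sys.time()
  log_stage <- function(...) {
    message(sprintf("[haplogeo %6.2fs] ", as.numeric(Sys.time() - t0, "secs")),
            ...)
  }

  ## --- inputs ---------------------------------------------------------
  if (isTRUE(config$input$fixtures)) {
    pops <- load_fixture("table1")
    coded <- load_fixture("table2")
    n_sites_total <- 1381L
  } else {
    if (is.null(config$input$populations)) stop("no population table configured")
    meta_tab <- utils::read.csv(config$input$populations, check.names = FALSE,
                                fileEncoding = "UTF-8")
    if (is.null(meta_tab$pop) || nrow(meta_tab) == 0) {
      stop("empty population table")
    }
    if (is.null(config$input$alignment)) stop("no alignment configured")
    aln <- read_fasta_alignment(config$input$alignment,
                                config$input$segment_boundaries)
    coded_ind <- code_indels(aln)
    coll <- collapse_haplotypes(coded_ind)
    coded <- coll$coded
    n_sites_total <- ncol(coded$states)
    # individuals are tied to populations by the "<pop>_" id prefix;
    # counts are derived from the collapse so labels always agree with
    # the coded matrix. The table supplies metadata (and its optional
    # H columns are cross-checked as per-population totals).
    ind_pop <- sub("_[^_]*$", "", names(coll$assignment))
    unknown <- setdiff(unique(ind_pop), meta_tab$pop)
    if (length(unknown)) {
      stop("alignment individuals reference unknown populations: ",
           paste(unknown, collapse = ", "))
    }
    counts <- table(factor(ind_pop, levels = meta_tab$pop),
                    factor(coll$assignment,
                           levels = rownames(coded$states)))
    counts <- matrix(as.integer(counts), nrow = nrow(meta_tab),
                     dimnames = list(meta_tab$pop, rownames(coded$states)))
    hcols <- grep("^H[0-9]+$", names(meta_tab), value = TRUE)
    if (length(hcols)) {
      declared <- rowSums(meta_tab[, hcols, drop = FALSE])
      if (any(declared != rowSums(counts))) {
        stop("population table haplotype totals disagree with the alignment")
      }
    }
    meta_cols <- setdiff(names(meta_tab), hcols)
    pops <- population_table(meta_tab[, meta_cols, drop = FALSE], counts)
  }
  if (nrow(pops$counts) == 0 || sum(pops$counts) == 0) {
    stop("empty population table")
  }
  log_stage("inputs: ", nrow(pops$counts), " populations, ",
            sum(pops$counts), " individuals")

  ## --- haplotyping ----------------------------------------------------
  poly <- count_polymorphic_sites(coded)
  pi <- pairwise_step_distances(coded)
  freqs <- colSums(pops$counts)
  log_stage("haplotyping: ", nrow(coded$states), " haplotypes, ",
            poly$total, " variable characters (", poly$indel, " indel)")

  ## --- network --------------------------------------------------------
  limit <- if (!is.null(config$fixed_limit)) config$fixed_limit else
    parsimony_connection_limit(n_sites_total, alpha = config$alpha, pi = pi)
  net <- build_network(pi, frequencies = freqs, limit = limit, pops = pops)
  net_res <- if (isTRUE(config$resolve_loops)) resolve_loops(net, pops) else net
  # the bipartition needs a connected graph; the parsimony limit may sever
  # the deepest connection, so derive lineages from the unlimited network
  bip_net <- if (net_res$n_components > 1) {
    full <- build_network(pi, frequencies = freqs, limit = Inf, pops = pops)
    if (isTRUE(config$resolve_loops)) resolve_loops(full, pops) else full
  } else net_res
  bip <- lineage_bipartition(bip_net, pops)
  log_stage("network: limit ", limit, " steps, ", length(net$ties),
            " tied batch(es), split ", bip$split_steps, " steps")

  ## --- groupings ------------------------------------------------------
  groupings <- builtin_groupings(pops, bip)
  if (!length(groupings)) stop("no grouping labels available")
  for (g in names(groupings)) .check_scheme(pops, groupings[[g]])

  ## --- diversity ------------------------------------------------------
  div_scheme <- if (!is.null(groupings$three_regions)) {
    groupings$three_regions
  } else groupings[[1]]
  diversity <- diversity_by_group(pops, pi, div_scheme,
                                  n_perm = config$n_perm_diversity,
                                  seed = .stage_seed(config$seed, "diversity"))
  log_stage("diversity: total G_ST = ",
            round(diversity$G_ST[diversity$scope == "total"], 3),
            ", N_ST = ", round(diversity$N_ST[diversity$scope == "total"], 3))

  ## --- AMOVA ----------------------------------------------------------
  amova <- lapply(names(groupings), function(g) {
    amova_three_level(pops, pi, groupings[[g]],
                      n_perm = config$n_perm_amova,
                      seed = .stage_seed(config$seed, "amova"), name = g)
  })
  names(amova) <- names(groupings)
  log_stage("amova: ", length(amova), " grouping(s)")

  ## --- pairwise differentiation + IBD ---------------------------------
  fst <- pairwise_fst(pops, pi, kernel = config$fst_kernel)
  km <- great_circle_matrix(pops)
  region_sets <- list(all = pops$meta$pop)
  if (!is.null(pops$meta$region)) {
    for (rg in unique(pops$meta$region)) {
      region_sets[[rg]] <- pops$meta$pop[pops$meta$region == rg]
    }
    if (all(c("NEQTP", "SEQTP") %in% pops$meta$region)) {
      region_sets$EQTP <- pops$meta$pop[pops$meta$region %in% c("NEQTP", "SEQTP")]
    }
  }
  ibd <- list()
  for (sc in names(region_sets)) {
    members <- region_sets[[sc]]
    if (length(members) < 4) next
    sub_fst <- unclass(fst)[members, members]
    sub_km <- unclass(km)[members, members]
    mt <- mantel_test(sub_fst, sub_km, n_perm = config$n_perm_mantel,
                      seed = .stage_seed(config$seed, "mantel"), scope = sc)
    cls <- if (length(members) >= 5) {
      classify_ibd_regime(sub_fst, sub_km, mt, alpha = config$alpha)
    } else NULL
    ibd[[sc]] <- list(scope = sc, n_populations = mt$n_populations,
                      r = mt$r, p_value = mt$p_value,
                      n_perm = mt$n_perm,
                      case = if (!is.null(cls)) cls$case else NA_character_)
  }
  log_stage("ibd: ", length(ibd), " scope(s)")

  ## --- dating ---------------------------------------------------------
  pg <- bip$population_groups
  lineage_a <- names(pg)[pg == "A"]
  lineage_b <- names(pg)[pg == "B"]
  dating <- net_between_group_distance(pops, pi, lineage_a, lineage_b,
                                       n_sites = n_sites_total)
  dating <- divergence_time(dating, mu = config$mu)
  log_stage("dating: d_A = ", signif(dating$d_A, 4), ", T = ",
            signif(dating$T_years, 4), " years")

  ## --- report ---------------------------------------------------------
  report <- list(
    parameters = list(seed = config$seed,
                      n_perm_diversity = config$n_perm_diversity,
                      n_perm_amova = config$n_perm_amova,
                      n_perm_mantel = config$n_perm_mantel,
                      mu = config$mu, alpha = config$alpha,
                      fst_kernel = config$fst_kernel,
                      connection_limit = limit),
    haplotyping = list(n_haplotypes = nrow(coded$states),
                       n_variable = poly$total,
                       n_variable_indel = poly$indel,
                       n_individuals = sum(pops$counts)),
    diversity = diversity,
    amova = lapply(amova, function(a) list(
      grouping = a$grouping,
      percent_among_groups = a$percent[["among_groups"]],
      percent_among_pops_within = a$percent[["among_pops_within"]],
      percent_within_pops = a$percent[["within_pops"]],
      phi_CT = a$phi[["CT"]], phi_SC = a$phi[["SC"]], phi_ST = a$phi[["ST"]],
      p_CT = a$p_values[["CT"]], p_SC = a$p_values[["SC"]],
      p_ST = a$p_values[["ST"]], n_perm = a$n_perm)),
    network = list(connection_limit = limit,
                   n_edges = nrow(net_res$edges),
                   n_ties = length(net$ties),
                   loop_haplotypes = unique(unlist(lapply(net$ties, function(t)
                     c(t$from, t$to)))),
                   removed_edges = net_res$resolution,
                   lineages = as.list(bip$haplotype_groups),
                   split_steps = bip$split_steps),
    ibd = ibd,
    dating = list(d_XY = dating$d_XY, d_X = dating$d_X, d_Y = dating$d_Y,
                  d_A = dating$d_A, mu = dating$mu,
                  T_years = dating$T_years))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    utils::write.csv(diversity, file.path(config$out_dir, "diversity.csv"),
                     row.names = FALSE)
    amova_df <- do.call(rbind, lapply(amova, function(a) data.frame(
      grouping = a$grouping, among_groups = a$percent[["among_groups"]],
      among_pops_within = a$percent[["among_pops_within"]],
      within_pops = a$percent[["within_pops"]],
      p_CT = a$p_values[["CT"]], p_SC = a$p_values[["SC"]],
      p_ST = a$p_values[["ST"]])))
    utils::write.csv(amova_df, file.path(config$out_dir, "amova.csv"),
                     row.names = FALSE)
    write_network(net_res, file.path(config$out_dir, "network.gml"),
                  file.path(config$out_dir, "network_edges.tsv"))
    write_ibd_pairs(fst, km, file.path(config$out_dir, "ibd_pairs.tsv"))
    log_stage("report written to ", config$out_dir)
  }
  invisible(report)
}
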