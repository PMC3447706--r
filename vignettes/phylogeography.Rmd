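---
title: "Methods: haplotype phylogeography with haplogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype phylogeography with haplogeo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

haplogeo implements the standard desk analysis of an intraspecific
chloroplast-DNA survey: individuals sequenced for one or more non-coding
plastid spacers, collapsed into haplotypes, scored per population, and
interrogated for geographic structure. Because cpDNA is effectively
non-recombining and (in most angiosperms) maternally inherited, its
haplotypes travel as units with seeds, and their spatial arrangement
preserves the history of range fragmentation, drift and seed-mediated gene
flow. This vignette documents the models, estimators, parameter choices
and numerical conventions; the package README shows the worked example.

## Input model

The genetic input is a *coded character matrix*: one row per haplotype (or
individual), one column per character. Substitution characters carry
nucleotide states; insertions/deletions are coded as binary
presence/absence characters, with a multi-base gap run counted as a single
mutation (one column), the usual simple indel coding. `code_indels()`
performs this reduction from a gapped alignment; a run of length L
replaces L alignment columns by one binary column, so the coded length is
the alignment length minus `sum(L - 1)` over multi-base runs. Staggered
runs (different boundaries in different sequences) are split at every
distinct boundary and each sub-run coded separately — a deterministic,
order-independent convention; note it cannot distinguish one long indel
from adjacent independent ones, which is a genuine ambiguity of indel
coding rather than an implementation choice. Genetic distance between
haplotypes is the number of differing coded characters ("steps"),
computed with pairwise deletion when missing states are present.

The survey input is a *population table*: per-population coordinates
(decimal degrees internally; degree-minute-second strings accepted on
input), optional morphotype and region labels, and per-haplotype counts.
Equal sample sizes are not required, but several estimators below weight
populations equally, which is most defensible when sizes are comparable.

## Diversity and differentiation (h~S~, h~T~, G~ST~, N~ST~)

With counts `c_ki` for haplotype *i* in population *k* (`n_k`
individuals, `K` populations, frequencies `p_ki`), the package computes
the classical equal-weight estimators in their ordered (distance-aware)
form; the unordered form is the special case with the identity mismatch
kernel `pi_ij = 1(i != j)`:

* within population: `v_k = n_k/(n_k - 1) * sum_ij pi_ij p_ki p_kj`,
  and `v_S` is the unweighted mean over populations;
* total: `v_T = sum_ij pi_ij pbar_i pbar_j - (1/K) sum_ij pi_ij c^_ij
  + v_S/(ñ K)`, where `pbar` is the unweighted mean frequency vector,
  `c^_ij` the sample covariance of `(p_ki, p_kj)` across populations and
  `ñ` the harmonic mean sample size;
* differentiation: `N_ST = 1 - v_S/v_T` (unordered case: `G_ST`).

The middle term of `v_T` matters: it treats the surveyed populations as a
sample from the region, correcting the plug-in total for the among-
population sampling variance (in the unordered case it reduces to
`+ sum_i var_k(p_ki)/K`). Without it the total diversity of a strongly
structured survey is biased downward by roughly `D_ST/K`; with it the
estimator matches the convention of the classical permutation-test
software for these statistics, which the packaged reference data
reproduce to their printed precision. The last term is the usual small-sample correction for
sampling individuals within populations and is negligible unless `n_k`
is tiny. `G_ST`/`N_ST` are reported as `NA` when the total diversity is
zero.

`N_ST` exceeding `G_ST` means that co-occurring haplotypes are more
closely related than random ones — phylogeographic structure.
`permutation_test_nst_gst()` permutes haplotype identities on the
distance kernel (which leaves `G_ST` untouched), recomputes `N_ST`, and
reports the one-tailed Monte-Carlo p-value with the add-one correction
`p = (1 + #{N*_ST - G_ST >= N_ST - G_ST})/(n_perm + 1)`, so p is never
exactly zero. Default 1000 permutations. The test has little power in
subsets with few haplotypes (three or fewer distinct haplotypes make it
essentially degenerate, and a warning is raised).

## AMOVA

`amova_three_level()` partitions squared inter-individual distances into
among-group, among-population-within-group and within-population
components using the standard nested ANOVA expectations with unequal
sizes. The squared distance between two individuals is the step distance
between their haplotypes ("pairwise difference" convention), so all sums
of squares reduce to quadratic forms in per-set haplotype count vectors —
the implementation never materializes the 705 x 705 individual matrix,
but the permutation schemes do operate on literal individual-level
haplotype vectors:

* `Phi_CT` (among groups): whole populations permuted among groups;
* `Phi_SC` (among populations within groups): individuals permuted among
  populations of the same group;
* `Phi_ST`: individuals permuted among all populations.

Default 1023 permutations, one-tailed, add-one correction. Negative
variance components are reported as computed (not clamped); percentages
are computed on the raw components and therefore always sum to 100.
`pairwise_fst()` applies the same decomposition to population pairs,
either with the step kernel (`Phi_ST`, the default) or the identity
kernel (haplotype-frequency `F_ST`). A pair with no variance at all
(both populations fixed for the same haplotype) is defined as 0. For
downstream matrix correlation the values are clamped into [0, 1]; the
raw values are kept in an attribute.

## Statistical-parsimony network

`parsimony_connection_limit()` reproduces the usual "95% connection
limit": the longest mutational connection that is still parsimonious
(free of superimposed changes) with probability at least `1 - alpha`.
The probability model places Poisson hits independently on each of the
`m` coded characters; a site hit `n` times differs between two sequences
with probability `3/4 (1 - (-1/3)^n)` (equal exchange among four
states), and a `j`-step connection is parsimonious exactly when the
total hit count equals `j`. Hence
`P(parsimony | j of m differ) = r1^j r0^(m-j)` with
`r1 = P(N=1)/P(differ)` and `r0 = P(N=0)/P(same)`. The per-site rate is
calibrated so that the expected differing fraction equals the observed
mean pairwise difference of the input — the data-driven nuisance
estimate used in practice. The limit grows with sequence length (more
sites over which to spread hits); for a ~1.4 kb matrix with shallow
divergence it lands in the high teens of steps, comfortably above the
deepest split in the reference survey. A Monte-Carlo simulation of the
same generative model validates the closed form in the tests. A fixed
limit can be supplied instead (`--fixed-limit`).

`build_network()` joins haplotype components in increasing step order
and, at each distance, retains *all* minimal inter-component edges, so
tied alternatives form loops exactly where the genealogy is ambiguous;
edges beyond the limit are dropped. Missing intermediate haplotypes are
implicit in edge weights rather than drawn as nodes. `resolve_loops()`
breaks cycles one edge at a time among each cycle's longest edges,
ranking removal candidates by (1) total frequency of the connected
haplotypes, then (2) total degree (interior vs tip), then (3) geographic
proximity of the carrying populations, with a lexicographic final
tie-break so the result is deterministic. The criteria are the classical
plausibility rules for resolving ambiguous connections (common, interior,
nearby haplotypes are the likely ancestors); their order is a package
choice, since the source heuristics do not prescribe one.
`lineage_bipartition()` removes the deepest edge class and requires
exactly two remaining components; populations inherit the lineage of the
haplotypes they carry, and mixed populations are flagged.

## Isolation by distance

Geographic distances are haversine great circles on a 6371.0 km sphere.
`mantel_test()` correlates the off-diagonal entries of the genetic and
geographic matrices and permutes population labels of one matrix
(default 999 permutations, one-tailed toward positive association —
the isolation-by-distance hypothesis — with the add-one correction).

`classify_ibd_regime()` assigns the qualitative gene-flow/drift cases
used for regional scatterplots: Case I (significant positive
association: regional equilibrium, isolation by distance), Case II (no
association, uniformly low scatter: gene flow dominant), Case III (no
association, substantial scatter: drift dominant), Case IV (significant
negative association: non-equilibrium). Two operational constants are
documented rather than hidden: the significance threshold (0.05) and the
"low scatter" bound (mean absolute regression residual below 0.05 F~ST~
units). The residual-scatter trend (Spearman correlation of distance vs
absolute residuals) is reported descriptively but deliberately *not*
used to gate Case I: with differentiation bounded in [0, 1], residual
spread necessarily shrinks near the ceiling, so demanding increasing
scatter would misclassify textbook isolation-by-distance clines whose
far pairs saturate at F~ST~ = 1. Classification is declined for fewer
than five populations. `nei_distance_matrix()` provides Nei's standard
distance as an alternative genetic matrix; infinite values (no shared
haplotypes) are capped at the maximum finite value plus one, with the
cap recorded.

## Divergence dating

`net_between_group_distance()` computes mean pairwise per-site distances
between (`d_XY`) and within (`d_X`, `d_Y`) two pooled groups, and the
net divergence `d_A = d_XY - (d_X + d_Y)/2`, which subtracts the
polymorphism already present in the common ancestor. All three are
plug-in frequency means (`sum_ij p_i p_j pi_ij / sites`); this makes
`d_A` exactly zero for identical group compositions and exactly
invariant to duplicating every individual, at the cost of an O(1/n)
downward bias in the within terms that is far below the other
uncertainties here. Distances are normalized by the *coded* matrix
length, since steps are counted on coded characters.
`divergence_time()` applies the strict-clock formula `T = d_A / (2 mu)`.
The default rate, `mu = 1.01e-9` substitutions/site/year, is the
standard synonymous-rate estimate for non-coding plastid spacers in seed
plants; it enters the result linearly, so any preferred rate can be
substituted (`--mu`). No confidence interval is attached: the dominant
uncertainty is the rate itself, for which no dispersion is available.

## Synthetic data: what it emulates, and what a green test means

`simulate_phylogeography()` generates the world the analysis assumes,
with exact truth:

* a random root sequence over `n_sites` coded characters
  (default 1381);
* two lineage ancestors separated by `split_steps` mutations (default
  11) at distinct sites — an infinite-sites model, so step distances
  equal mutation counts exactly and the planted `d_A` is known;
* `within_lineage_steps` (default 6) derived haplotypes per lineage,
  each one further mutation: a star around the ancestor in the
  "northern" lineage, a serial chain in the "southern" one — the two
  canonical post-glacial vs topographically fragmented shapes;
* `indel_fraction` (default 5/23) of mutations realized as binary indel
  characters, pairwise non-adjacent so that materializing them as gap
  runs and re-coding is lossless;
* per-population haplotype counts (`n_per_pop` = 15 individuals in 31
  northern + 16 southern populations): northern populations draw from a
  fixed star-dominated frequency vector (`star_dominance` = 0.8,
  matching the observed ~0.84 share of the dominant northern haplotype)
  with no spatial signal; southern populations sit on a transect and
  draw from an exponential kernel `exp(-ibd_strength * |x - u|)`
  linking transect position to chain position (`ibd_strength` = 8,
  chosen to give the strong within-region isolation-by-distance the
  southern survey shows while keeping neighbouring populations
  polymorphic).

Defaults restate the reference survey's dimensions (47 populations, 705
individuals, 1381 characters, 23 mutations, 5 indels), so the default
synthetic world has the same shape as the packaged fixtures. What the
generator does *not* emulate: coalescent genealogy within haplotype
classes, recurrent or back mutation, recombination, selection, uneven
sample sizes, and real two-dimensional geography (coordinates lie on
per-region transects). A green synthetic test therefore establishes that
the estimators recover planted structure under the model's own
assumptions — not that those assumptions hold for any particular
empirical system.

## Numerical conventions

* All Monte-Carlo p-values use the add-one correction and `>=` with a
  1e-12 slack so ties count as exceedances.
* Permutation counts default to 1000 (diversity), 1023 (AMOVA) and 999
  (Mantel), the conventional settings of the programs this workflow
  replaces; every stochastic routine takes an explicit seed, and the
  pipeline derives per-stage seeds from one master seed so stages are
  individually reproducible.
* Degenerate inputs fail loudly: ragged alignments, duplicate
  identifiers, out-of-range coordinates or minute/second fields,
  uncovered populations in a grouping, empty groups, and matrices whose
  counted haplotypes are missing from the distance kernel all raise
  errors rather than being repaired.
* The JSON report is byte-identical for identical configuration and
  seed.

## Known limitations

* The coded-character model treats every character equally; no rate
  heterogeneity or weighting of indels vs substitutions.
* The connection-limit model ignores the genealogical correlation
  between sites (as the original procedure effectively does); its limit
  should be read as a conventional threshold, not a sharp probability.
* Regional diversity subsets with few haplotypes give the N~ST~/G~ST~
  permutation test little power; significance claims there should rest
  on the species-level test.
* Equal population weighting is assumed throughout the diversity
  estimators; strongly unequal sample sizes deserve the weighted
  variants, which are not implemented.
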