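---
title: "Simulating admixed genotypes without reusing genetic material"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating admixed genotypes without reusing genetic material}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsped)
```

## The problem

To judge how well a clustering or assignment method will work on a real
data set, one simulates individuals of known ancestry from the empirical
reference samples and asks how well the method recovers that ancestry.
The common shortcut — estimating allele frequencies from the samples and
drawing new genotypes from them *with replacement* — quietly assumes the
population has exactly the sample's frequencies.  Each simulated
individual then shares the sample's frequency noise, and with thousands
of markers this shared noise masquerades as assignment signal: apparent
power appears even between two samples drawn from one panmictic
population (resampling-induced spurious power inflation, RISPI).  A
second shortcut — treating linked loci as independent — shrinks the
variance of simulated admixture fractions far below what chromosomes
really deliver, making hybrid categories look separable when they are
not.

`gsped` avoids both shortcuts.  Admixed genotypes are built by dropping
*segments of real chromosomes* through a user-specified pedigree, and
alleles are painted onto those segments from empirical genotypes that
are permuted within populations — moved around, never copied.  Every
input gene copy ends up exactly once in either a simulated hybrid or a
retained reference individual.

## Genomic simulation pedigrees

A genomic simulation pedigree (GSP) has founder nodes (each carrying two
haploid genomes labelled with a population), non-founder nodes, and
sample nodes where the simulated individuals are collected.  Each edge
carries the number of gametes segregated down it.  Unlike an ordinary
pedigree, a non-founder node may pass several gametes to the same
daughter node, so one pedigree node can stand for several simulated
meioses.

For the accounting to deliver every founder gene copy exactly once, a
GSP must satisfy, in addition to having no inbreeding loops:

1. total samples = number of founders;
2. each founder segregates exactly two gametes (over at most two edges);
3. the two parent edges into a non-founder carry equal gamete counts;
4. a non-founder with no sample node passes on what it receives;
5. a non-founder with only a sample node receives `2 * S` gametes for its
   `S` samples;
6. a non-founder with both receives `2 * S` plus what it passes on.

`validate_gsp()` reports every violated condition with the offending
nodes.  The loop rule is implemented as: the two parents of every
non-founder must have disjoint ancestor sets (and the graph must be
acyclic) — a shared ancestor is precisely what would let one founder
gene copy reach a node twice.  Inbred *founders* are still perfectly
usable: related individuals used as founders produce effectively inbred
offspring without any loop in the GSP itself.

`create_gsp()` supplies presets.  Single-category presets are minimal
pedigrees yielding only that category (2 founders/2 samples for F1;
4/4 for F2; 4/4 for BC1 via two backcross nodes sharing one F1 node;
8/8 for BC2).  With all four flags a single 6-founder pedigree yields
1 F1, 2 F2, 1 BC1 and 2 BC2 per replicate.  Because conditions (1)-(6)
are local, any other flag combination is served as the disjoint union of
the single-category presets.  `gsp_bc1xbc2()`, `create_bc_ladder()` and
`gsp_for_q()` construct the deeper pedigrees used in the experiments,
including exact pedigrees for nominal admixture fractions 3/8 and 5/8
(an F1 mated to a BC1).

## Meiosis and the recombination model

Recombination is simulated at the boundaries of a recombination map
(`build_rec_map()`).  Each boundary carries the probability `r` that a
gamete switches parental haplotype there, computed from the genetic
length `d` (Morgans) of the interval ending at the boundary via the
Haldane map function `r = (1 - exp(-2d)) / 2`, i.e. crossovers occur as
a Poisson process without interference, thinned to marker-observable
switches.  Choices worth knowing:

* Crossovers happen exactly at boundary positions.  Markers are the only
  observation points, so sub-interval placement is unobservable, and
  boundary-exact breakpoints keep segment arithmetic integer-exact.
* Which haplotype a gamete starts on is a fair coin per chromosome
  (independent assortment).
* When a map carries no genetic positions, a uniform rate (default
  1 cM/Mb, a conventional genome average) converts physical to genetic
  distance.  Boundaries go at marker positions (`"markers"`) or on a
  regular grid (e.g. `boundary_spacing_bp = 1e6`).
* Each meiosis returns the gamete *and its complement* (opposite
  parental haplotype at every base).  Segregating complements in pairs is
  what makes exact conservation possible, and doubles as antithetic
  variates; for relatedness studies one should sample one offspring per
  mating rather than complement pairs.

`segregate()` walks the pedigree in topological order with one derived
RNG sub-seed per (replicate, node), so node-level results are
reproducible regardless of how many random draws other nodes consume.
Gamete pairing at a node, the choice of which united pairs become
samples, and the dealing of meiosis products to outgoing edges are all
uniform random (the accounting guarantees the counts fit).  Adjacent
same-origin segments are merged eagerly so segment lists are canonical
and exact-equality testable.  `check_founder_conservation()` verifies
the central guarantee — each founder haplotype's genome is tiled exactly
once by the union of sample segments — and the test suite asserts it on
randomized pedigrees on every run.

## Permutation and painting

`segments2markers()` turns segments into marker genotypes.  The input
genotype matrix (N rows, 2L allele columns) is first permuted within
populations under a `permutation_plan()`:

* `preserve_individuals = TRUE` — whole individuals are the permuted
  unit (all their alleles stay together);
* `"BY_CHROM"` — each individual's homologous chromosome pair moves
  intact, independently per chromosome, preserving within-chromosome LD
  while breaking between-chromosome associations;
* `FALSE` — single gene copies are shuffled per locus (maximal
  scrambling), or, with `preserve_haplotypes = TRUE` on phased data,
  whole per-chromosome haplotype blocks are the shuffled unit.

`preserve_haplotypes` changes nothing under `TRUE`/`BY_CHROM` because
those units already keep haplotypes intact; the option exists to choose
the unit under `FALSE`.  Missing alleles permute like any value, so
per-population allele *and* missingness counts are conserved exactly.
The filled plan records a provenance bijection, so permutations are
invertible (`unpermute_genotypes()`) and no allele can change
population.

Permuted individuals are then assigned, in order (replicate-major,
ascending founder id), to the founder nodes of their population, and
every marker of every simulated sample is copied from the assigned
founder's haplotype that the marker's segment descends from (half-open
intervals: a marker at a crossover boundary belongs to the right-hand
segment).  Individuals not consumed as founders are returned as the
retained reference — the pure individuals one would feed to a downstream
analysis.  Founders must have both haplotypes from the same population
to be painted from whole individuals; mixed-label founders are supported
in segregation but not in painting.

## The synthetic study system

The package's experiments do not ship data; they generate it:

* **Reference panels** (`sim_reference_panels()`): allele frequencies for
  L biallelic loci from Beta(1, 8) (mean 1/9, mimicking an
  SNP-discovery skew toward low minor-allele frequencies), then two
  panels of N diploids each drawn from the *same* frequencies under
  Hardy-Weinberg equilibrium.  Any apparent power to tell the panels
  apart is therefore spurious by construction.
* **Genome** (`pig_genome()`): 18 autosomes proportioned like the pig
  genome and rescaled to exactly 2.35 Gb, with a uniform 1 cM/Mb map.
  This emulates the published study system's scale; it does not attempt
  the real pig recombination landscape (hot/cold spots,
  chromosome-specific rates), so absolute segment-length distributions
  are stylized while means and orders of magnitude are realistic.
* **Estimator**: `supervised_q_mle()` maximizes the admixture-model
  likelihood for one individual with *fixed* reference frequencies (EM,
  tolerance 1e-6, at most 500 iterations; a flat likelihood stays at
  the 0.5 starting value, which doubles as the tie-break; frequencies
  are clamped into `[clamp, 1 - clamp]`, with `clamp = 1/(2N+1)`
  recommended, to keep fixed loci finite).  `supervised_admixture_em()`
  is the stand-in for a supervised ADMIXTURE run: cluster frequencies
  are re-estimated each iteration from the labeled references plus the
  soft-assigned unknowns.  The joint version matters in the pedigree
  experiment, where the unknowns carry a large share of all genetic
  material: holding frequencies fixed at the depleted retained-sample
  values induces a systematic repulsion of estimates away from the
  simulated composition, an artefact of the estimator rather than of
  the simulation, which joint re-estimation removes.
* **Experiment layout** (`run_rispi_experiment()`): per replicate, one
  panel pair and *one* analysis data set containing new individuals at
  every nominal admixture fraction in
  {0, 1/8, ..., 1}.  In the pedigree arm the nine pedigrees are
  segregated together as one disjoint-union GSP (20 founders per
  population per union replicate), so conservation holds across the
  whole replicate; the labeled references are the retained individuals.
  In the with-replacement arm nothing is consumed and the full panels
  are the references.

What passing these experiments shows — and what it does not: the
simulations demonstrate the *mechanism* (resampling inflates apparent
power; segment-based, no-reuse simulation does not; linkage widens
admixture-fraction distributions) on idealized panels with independent
loci frequencies and no missing data.  Real data add LD within
populations, missingness and genotyping error, which affect estimators
but not the conservation guarantees.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; PLINK files are read and
  written 1-based.
* Segment arithmetic is exact in doubles (positions are integers well
  below 2^53); conservation checks use exact equality, not tolerances.
* An all-zero genetic-position column in a `.map` file is treated as
  "no genetic map" (the PLINK convention), falling back to `cM_per_Mb`.
* Chromosome length defaults to the last marker position + 1 when only a
  marker map is given (the minimal genome covering all markers).
* `r` values are capped by construction at 0.5 (Haldane); a zero-rate
  map yields intact chromosomes; a population of size one permutes to
  itself; an empty simulation request returns empty containers.
* EM tolerances: 1e-6 on the fixed-frequency MLE; 1e-4 (with a
  200-iteration cap) on the joint estimator, an order below the
  precision at which admixture fractions are interpreted.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen so Monte Carlo error is a
fraction of each tolerance: 2,000 simulated individuals per hybrid
category for genome-fraction triplets (tolerance 0.02), 1,000 for mean
admixture fractions (tolerance 0.01), 40 replicates of the L = 1,000 /
N = 50 no-RISPI experiment, 180 union replicates (360 individuals per
nominal fraction) for the per-fraction bias check at L = 10,000 /
N = 25, and 200 individuals per arm for the linked-versus-unlinked
spread comparison at L = 100,000.

## Known limitations

* No mutation, gene conversion, crossover interference, or sex
  chromosomes; no sex-specific maps.
* Painting requires called genotypes; genotype likelihoods are out of
  scope by design.
* Pedigrees with inbreeding loops are rejected, not repaired; gamete
  counts are validated, not auto-balanced.
* The joint estimator models two clusters only (the supervised
  two-population setting of the experiments).
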