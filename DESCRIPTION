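Package: gsped
Title: Simulation of Admixed Genotypes by Gene Dropping Through Genomic
    Simulation Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Creates admixed individual genotypes from empirical reference
    panels by segregating genome segments through user-specified genomic
    simulation pedigrees (GSPs) with map-based recombination, then painting
    alleles onto the inherited segments by permuting genotypes within
    populations -- never sampling with replacement.  Because every founder
    gene copy is delivered exactly once to the simulated samples or retained
    in the reference, the simulations avoid the spurious inflation of
    assignment power that arises when new genotypes are resampled from
    observed allele frequencies.  Includes preset pedigrees for F1, F2 and
    first- and second-generation backcrosses, readers and writers for PLINK
    .ped/.map text files, several within-population permutation schemes, a
    supervised EM estimator of admixture fractions, and runnable simulation
    experiments contrasting resampling-based, unlinked and pedigree-based
    hybrid simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
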