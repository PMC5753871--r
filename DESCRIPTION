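Package: continuitest
Title: Testing Continuity of Ancient and Modern Populations from Low-Coverage Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood inference of the population-genetic drift times
    separating an ancient panel from a modern population, directly from
    per-site ancestral/derived read counts at SNPs whose modern derived-allele
    frequencies are known. The sampling distribution of ancient alleles
    conditional on the modern frequency is obtained from binomial moments of
    the Wright-Fisher diffusion, computed by matrix exponentiation of sparse
    tridiagonal moment generators. Read data enter through diploid genotype
    likelihoods under a symmetric error model, so no genotype calls are
    required and arbitrarily low coverage is handled coherently. Includes a
    likelihood-ratio test of direct ancestry ("continuity", ancient-side drift
    time equal to zero) with a boundary-corrected null distribution,
    nonparametric bootstrap confidence intervals, a model-exact simulator plus
    an independent forward Wright-Fisher simulator (with secondary-contact and
    ghost admixture scenarios, sequencing error and contamination), tabular
    and VCF input routes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
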