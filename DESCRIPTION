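Package: mrknockoff
Title: Multi-Resolution Group Knockoffs for Genome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes trait-associated genetic variants at multiple levels of
    resolution while controlling the false discovery rate. Genotypes are
    modeled with a haplotype-cluster hidden Markov model (fastPHASE-style),
    from which group knockoffs -- synthetic negative-control genotypes that
    are exchangeable with the originals over predefined groups of variants --
    are sampled. Nested, contiguous groups of variants are built by
    adjacency-constrained hierarchical clustering of linkage disequilibrium,
    and conditional-association hypotheses are tested at each resolution with
    the knockoff filter applied to sparse-regression importance statistics.
    Includes a genotype/trait simulator with clustered causal architectures
    and liability-threshold case-control designs, PLINK BED/BIM/FAM input and
    output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
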