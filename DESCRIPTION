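Package: pedmi
Title: Fast Pedigree Inbreeding Coefficients via Indirect and Cholesky
    Methods with Metafounders
Version: 0.1.0
Authors@R:
    person("pedmi", "developers", email = "pedmi@example.org", role = c("aut", "cre"))
Description: Computes pedigree-based inbreeding coefficients F for large
    livestock pedigrees. Implements the classical tabular method, a
    memoized recursive kinship oracle, the Meuwissen-Luo and
    Sargolzaei-Iwaisaki Cholesky-based algorithms, the indirect method of
    Sargolzaei et al., and a modified indirect method that replaces
    backward substitution by direct computation of one row of the
    Cholesky factor L and restricts forward substitution to flagged
    recursion over the ancestors of a sire's mates. Unknown parents are
    handled through metafounders assigned by birth-year bins, pedigrees
    are sorted by longest ancestral path (LAP) so that equal-LAP blocks
    can be processed in parallel, and a synthetic pedigree simulator
    reproduces factorial half-sib mating designs with growth and
    truncation-selection replacement. Includes pedigree cleaning rules
    (birth-year imputation, severing of parents born no earlier than
    their progeny) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17, optionally OpenMP
Config/testthat/edition: 3
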