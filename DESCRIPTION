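Package: ystrmatch
Title: Pedigree-Based Y-STR Haplotype Match Probabilities by Importance Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the probability that untyped patrilineal relatives of a
    suspect share his Y-chromosomal short tandem repeat (Y-STR) haplotype,
    given the pedigree structure, the haplotypes of typed pedigree members and
    per-marker single-step mutation rates. Implements an importance-sampling
    estimator for the probability P(h^v) of the observed typed haplotypes and
    for the conditional match-count probabilities p_x, together with exact
    reference computations (bounded enumeration and a sum-product tree dynamic
    program) for small pedigrees, a catalogue of elementary validation
    pedigrees with closed-form results, and a command-line interface. Pedigrees
    are read from Trivial Graph Format (TGF) files, haplotypes and mutation
    rates from CSV or JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
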