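Package: ssecons
Title: Secondary Structure Consistency Between Homologous Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the agreement of protein secondary structure between
    homologous proteins and aggregates it into estimates of the accuracy
    limits of secondary structure prediction. Implements residue-level Q3/Q8
    consistency and the segment-based SOV (v'99) score over residue
    correspondences obtained from built-in global/local affine-gap dynamic
    programming aligners or from external (e.g. structural) alignments;
    DSSP output parsing with 8-to-3 state reduction; identity-binned
    weighted aggregation with family/fold strata and repeat statistics; a
    random-pairing lower bound; and a seeded synthetic homolog-family
    generator for end-to-end testing without database downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
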