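Package: lethalscan
Title: Missing-Homozygosity Scans for Recessive Lethal Haplotypes in
    Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects recessive lethal haplotypes in SNP-genotyped,
    pedigreed livestock populations from the absence or deficit of
    homozygous animals. Phased haplotypes are enumerated in sliding
    genomic windows, expected homozygote counts are derived from
    genotyped parent-offspring trios by the transmission-product rule,
    and observed counts are tested with a two-sided exact binomial
    test. Includes carrier-mating contrasts on litter traits (total
    born, born alive, stillborn, mummified), runs-of-homozygosity
    detection, and a gene-drop simulator of a closed breeding line
    with embedded lethal haplotypes for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
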