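Package: phasemotif
Title: Motif Enrichment and Minimalistic Peptide Design for
    Phase-Separating Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers short peptide motifs (3-6 residues) enriched in the
    droplet-promoting regions (DPRs) of liquid-liquid phase separating
    proteins relative to a negative protein set, scores motif trios by
    their co-occurrence and symmetry across DPRs, and designs minimalistic
    (<20 residue) phase-separation-prone peptides by merging motif trios
    into minimal superstrings.  Includes in-package implementations of the
    charge-patterning and disorder sequence parameters used for candidate
    filtering (FCR, NCPR, kappa, Kyte-Doolittle mean hydropathy, fraction
    of disorder-promoting residues), a seedable synthetic database
    generator with compositional biases and planted motifs for end-to-end
    testing, amino-acid composition profiling, and the closed-form
    turbidity and encapsulation-efficiency assay calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
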