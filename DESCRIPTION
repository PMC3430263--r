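Package: pocketrank
Title: Ligand Binding-Site Detection and Multi-View Rank Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate ligand-binding pockets on protein structures
    with a grid-based protein-solvent-protein (PSP) scan, scores each pocket
    by four properties (convex-hull volume, distance from the protein
    centroid, mean evolutionary conservation, number of hydrophobic
    residues), combines the per-property rankings into a consensus list by
    Cross-Entropy minimisation of the weighted Spearman footrule distance,
    and evaluates predictions with the 4 Angstrom hit criterion, TOP-n
    success rates, residue-level Matthews correlation, and paired one-sided
    Wilcoxon signed-rank comparisons. Ships a synthetic-fixture generator
    (toy structures with carved cavities, planted ligands and conservation
    profiles) so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
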