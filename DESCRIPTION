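Package: pocketscreen
Title: Binding-Site Similarity Screening for Drug Repurposing with
    Microtubule Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structure-based drug-repurposing screen built on binding-site
    microenvironment similarity. Extracts ligand-binding pockets from
    protein-ligand co-crystal structures (residues within a distance cutoff
    of the bound ligand), describes each pocket residue by a 480-length
    physicochemical microenvironment vector (6 concentric 1 Angstrom shells
    x 80 descriptors), and scores pocket pairs by a Tanimoto-based optimal
    one-to-one residue matching yielding a PocketFeature-style similarity
    score (more negative = more similar). Includes drug-like compound
    library preparation (Lipinski filtering, structure-key deduplication),
    docking-score post-processing (Boltzmann conversion to inhibition
    constants and confidence filtering), target-family enrichment, a
    chemical-similarity network over circular fingerprints, and
    quantification of tubulin polymerization kinetics (Vmax, maximum
    end-point, fold changes), microtubule phenotype scores, and EC50
    potency estimation from live-cell growth and death series. Ships a
    synthetic-data module generating toy complexes, compound tables and
    assay curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
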