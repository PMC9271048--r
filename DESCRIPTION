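Package: privconf
Title: Privileged-Conformation Occupancy Analysis for Strigolactone
    Receptor Ensembles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying near-attack ("privileged") conformations
    of serine-hydrolase strigolactone receptors from conformational
    ensembles.  Reads and writes multi-model PDB and XYZ ensembles, computes
    catalytic-triad and ligand reaction-geometry distance series, classifies
    frames against closed distance windows and estimates the privileged-
    conformation occupancy P_PC with a moving-block bootstrap confidence
    interval.  Includes a seeded two-state Markov generator of synthetic
    triad/ligand ensembles with controllable occupancy, a hierarchical
    2D-fingerprint Tanimoto screening cascade with Taylor-Butina clustering
    and cluster-center selection, monoisotopic mass and b/y fragment-ion
    calculators for covalently modified peptides (histidine-linked
    butenolide-derived adducts), and assay statistics: germination rate,
    fluorogenic-substrate initial hydrolysis rates, relative inhibition,
    four-parameter logistic IC50/EC50 fits, first-order decay half-lives and
    percent hydrolysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
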