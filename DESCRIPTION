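Package: xfms
Title: Residue-Level Solvation Mapping from X-Ray Footprinting Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for hydroxy-radical protein footprinting (XFMS) analysis at
    single-residue resolution. Matches MASCOT-style peptide identifications to
    LC-MS peak lists, compiles per-residue oxidized/unoxidized peak areas across
    an X-ray dose series, fits weighted single-exponential dose responses and
    converts the fitted rates to protection factors (PF = S/IR). Computes
    per-residue solvent-accessible surface area (Shrake-Rupley) from PDB
    structures, calibrates the SASA-Log10(PF) regression with a 95% confidence
    band and flags anomalously low-PF residues diagnostic of structured water.
    Builds the protein-water hydrogen-bond network and its betweenness
    centrality profile, scores native residue contacts against identity-
    randomized decoy distributions (contact frustration), and computes
    real-valued evolutionary-trace scores combining per-column alignment
    entropy with phylogenetic partitioning. A fixtures module generates
    synthetic inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    igraph,
    minpack.lm,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
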