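Package: umamidp
Title: Umami Dipeptide Screening and Receptor Recognition Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and screens the complete database of 400 dipeptides by
    physicochemical properties (molecular weight, isoelectric point,
    Henderson-Hasselbalch net charge, hydropathy) and imported docking and
    umami-probability scores, and provides the trajectory analytics used to
    characterise dipeptide recognition by the T1R1/T1R3 umami taste receptor:
    Kabsch superposition with RMSD/RMSF profiles, threshold clustering with
    lowest-energy representatives, geometric hydrogen-bond detection and
    occupancy, Shrake-Rupley solvent accessible surface area, pocket
    hydrophobicity and pocket-water counting, HOLE-style channel radius
    profiling with contact residues and acid-base summaries, solvated
    interaction energy (SIE) scoring with a generalized-Born reaction field,
    and reduced density gradient (NCI) weak-interaction fields on a
    promolecular density.  A synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable without external
    engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
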