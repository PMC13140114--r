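Package: nrf2ctdna
Title: Circulating NRF2 Pathway Mutation Triage and Comparative Trajectory
    Analysis for Non-Small Cell Lung Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence-tiered triage of somatic variants called from circulating
    tumor DNA, classification of NRF2 pathway (NFE2L2/KEAP1/CUL3) activation,
    blood-based tumor mutational burden and ctDNA concentration metrics,
    cohort contingency and biomarker statistics (Fisher exact co-occurrence,
    Mann-Whitney, ROC with Youden cut-point optimization), and comparative
    molecular-dynamics trajectory statistics (Kabsch superposition, per-residue
    RMSF differential testing, directed Hausdorff distances with Ward
    clustering, Gaussian elastic network eigenvalue bootstrap, ligand RMSD
    stability testing) used to functionalize rare KEAP1 variants. Includes a
    synthetic-data module generating cohorts and elastic-network trajectory
    ensembles with known truth so every stage is testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    bio3d
Config/testthat/edition: 3
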