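Package: dosemedium
Title: Dose-to-Medium Versus Dose-to-Water Analysis for Monte Carlo Treatment Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing Monte-Carlo-reported dose-to-medium (Dm) with
    dose-to-water (Dw) in external-beam radiotherapy. Provides voxel-wise
    Bragg-Gray conversion through density-indexed stopping-power-ratio tables,
    CT-number to electron-density to mass-density calibration, cumulative
    dose-volume histograms with Dx%/Vx% indices and paired cohort statistics,
    prescription-normalised 3-D dose-difference maps, a local-normalisation
    gamma-index engine with criteria sweeps, and seeded synthetic phantom,
    pseudo-IMRT dose, and perturbed planar-measurement generators for
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
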