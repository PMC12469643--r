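Package: relaxsel
Title: Validation of Molecular Dynamics Ensembles Against Amide 15N
    Spin-Relaxation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Back-calculates amide 15N spin-relaxation observables (R1,
    heteronuclear NOE, CSA/dipole-dipole cross-correlated relaxation
    eta_xy, and R2) from molecular dynamics trajectory segments via P2
    autocorrelation functions of N-H bond vectors, multi-exponential
    fits and Lipari-Szabo spectral densities; estimates the global
    rotational correlation time and per-residue order parameters from
    experimental R1 and eta_xy; detects RMSD-plateau trajectory
    segments; and ranks candidate segments against experimental rate
    tables with the Mann-Whitney U test.  Includes synthetic-data
    generators (restricted-diffusion bond-vector simulations, noisy
    relaxation tables, peak-intensity decay series) with analytic
    ground truth, and readers for rate tables in CSV and NMR-STAR form.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
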