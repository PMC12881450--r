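Package: mirseize
Title: miRNA-Regulated TGF-beta/SMAD Signaling Dynamics for Seizure Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of antagomir-mediated
    inhibition of three seizure-modifying microRNAs (miR-21a-5p,
    miR-142a-5p, miR-10a-5p) and the downstream TGF-beta/SMAD signaling
    pathways in temporal lobe epilepsy. Provides the dimensional and
    dimensionless model systems with Hill-type inhibition kinetics,
    simulation of antagomir dosing regimens (bolus pre-injection,
    continuous infusion, multiple dosage) with exact impulse and clamp
    event handling, seizure/anti-seizure phenotype classification with
    critical-dose location, closed-form equilibria with Jacobian-based
    stability analysis and nullcline/phase-plane projections, an extended
    Fourier Amplitude Sensitivity Test (eFAST) implementation with
    resampling confidence intervals, and a synthetic-observation generator
    plus least-squares parameter estimation for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
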