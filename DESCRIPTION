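Package: cardiopbpk
Title: PBPK-Driven Cardiac Safety Simulation for Amitriptyline and Nortriptyline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Oral-absorption physiologically based pharmacokinetic (PBPK)
    simulation of amitriptyline and its active metabolite nortriptyline in
    virtual populations and patient-matched virtual twins; translation of
    plasma and heart-tissue concentrations into free cardiac exposure; a
    saturable Emax model linking plasma concentration to RR-interval length;
    a ventricular cardiomyocyte action-potential stage with IC50-based ion
    channel block that yields QT/QTc intervals and arrhythmia flags; and a
    two-stage parameter-fitting engine (controlled random search with local
    mutation followed by bounded quasi-Newton refinement) against
    concentration-time observations, with synthetic-data generators that make
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
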