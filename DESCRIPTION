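Package: ehgemd
Title: Preterm-Labor Prediction from Single-Channel Electrohysterograms
Version: 0.1.0
Authors@R:
    person("EHG", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying term versus preterm pregnancies from
    single-channel electrohysterogram (EHG) recordings. Implements the full
    pipeline: Butterworth band-pass preprocessing with transient trimming,
    empirical mode decomposition (EMD) of one-minute windows into intrinsic
    mode functions, extraction of root-mean-square, sample entropy and mean
    Teager-Kaiser energy from the first two IMFs, and evaluation of k-nearest
    neighbour, support vector machine and decision tree classifiers under
    repeated stratified 10-fold cross-validation with sensitivity,
    specificity, accuracy and ROC/AUC reporting. Includes a deterministic
    synthetic EHG generator emulating term/preterm contraction structure and
    minimal WFDB format-16 record input/output, so the whole pipeline is
    testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    quadprog,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
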