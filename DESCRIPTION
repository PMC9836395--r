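Package: runtcoop
Title: Thermodynamic Models of Runt Repression and Higher-Order
    Cooperativity in Synthetic hunchback P2 Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium states-and-weights (thermodynamic) models of
    transcriptional repression by the Runt repressor acting on
    Bicoid-activated hunchback P2 synthetic enhancers carrying zero to
    three Runt binding sites.  Provides microstate enumeration and
    closed-form transcription-rate predictions, an adaptive
    random-walk Metropolis sampler for Bayesian parameter inference, a
    hierarchical fix-then-infer cascade across enhancer architectures,
    nested-model comparison by AIC, conversion of cooperativities to
    interaction free energies in kBT units, a synthetic-embryo data
    generator (transcription-factor gradients, initial-rate profiles,
    MS2-style fluorescence traces), and trace-level preprocessing
    (time averaging, initial-rate line fits, anterior-posterior
    binning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
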