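Package: cdawm
Title: Contralateral Delay Activity and Working-Memory Modelling for
    Lateralized EEG Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the complete computational chain of a lateralized
    visual-working-memory EEG experiment: behavioural capacity estimation
    (Cowan's k) for delayed recognition, maximum-likelihood mixture modelling
    (target/nontarget/guess with von Mises precision) and target confusability
    competition (TCC) modelling of delayed-estimation responses using measured
    psychophysical similarity functions, and an ERP pipeline that derives
    contralateral and ipsilateral cluster waveforms, difference waves and the
    contralateral delay activity (CDA), with amplitude and sliding-window
    horizontal-EOG artifact rejection. A synthetic-data generator emulates the
    behavioural and electrophysiological structure of such studies with full
    ground-truth bookkeeping, so every stage of the pipeline is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
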