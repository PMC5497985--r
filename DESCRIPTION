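Package: teplab
Title: TMS-Evoked Potential, Cortical Inhibition and Behavioral Task Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined TMS-EEG and behavioral studies of
    prefrontal excitability. Quantifies early TMS-evoked potentials (rectified
    mean amplitude 15-40 ms over the coil electrodes) and long-interval
    cortical inhibition (LICI) from single- and paired-pulse epoch sets, using
    shift-and-subtract correction of the conditioning-pulse artifact and a
    rectified area-under-curve ratio. Scores four behavioral tasks: stop-signal
    (SSRT via the mean method under staircase tracking), monetary delay
    discounting (hyperbolic K by maximum likelihood), speeded arithmetic and
    recognition memory. Includes the study-level statistics layer (2-SD outlier
    exclusion, pooled two-sample t with Cohen's d, 2x2 mixed-design ANOVA with
    partial eta squared, Pearson correlations, Bonferroni correction) and a
    synthetic-cohort generator with known ground truth for end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
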