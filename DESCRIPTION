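Package: bimanbci
Title: Simulation and Decoding of Bimanual Brain-Computer Interface Cursor Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how motor-cortical population activity supports
    simultaneous two-cursor (bimanual) brain-computer interface control. Provides
    a linear directional-tuning encoding model with a direction-independent
    laterality dimension, context-dependent suppression and decorrelation of the
    non-dominant hand, and calibrated Gaussian noise; cross-validated
    ordinary-least-squares tuning statistics (unbiased coefficient-vector
    magnitudes and correlations), demixed-PCA marginalized variance, and
    electrode-level ANOVA/FVAF tuning tests; ridge, feed-forward network and
    context-gated recurrent (GRU) velocity decoders; a training-data augmentation
    method that dilates, compresses and shuffles snippets of the recorded stream;
    and a simulated closed-loop two-cursor target-acquisition task with dwell,
    timeout and assistance mechanics for measuring online generalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
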