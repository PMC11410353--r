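Package: oddwave
Title: Oddball Sequence Design, Synthetic ERP Data, and Cluster-Based
    Mismatch-Negativity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditory oddball experiments targeting the mismatch
    negativity (MMN): constrained pseudorandom trial-sequence generation,
    hierarchical synthetic EEG epoch simulation, epoch-level preprocessing
    (mastoid re-referencing, demeaning, baseline correction, amplitude-based
    artifact rejection, zero-phase FIR low-pass filtering, bad-channel
    interpolation), identity-MMN difference waves with pre-registered trial
    exclusions, from-scratch spatiotemporal cluster-based permutation tests
    over channel neighbour graphs, and simulation-based power analysis for
    nested participant-by-trial designs with a closed-form noncentral-t
    benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
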