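Package: stimcycle
Title: DBS On/Off Cycling fMRI and Stimulation-Field Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for deep brain stimulation (DBS) On/Off cycling
    fMRI experiments: synthetic cycling-paradigm BOLD studies with a labeled
    parcel/network atlas, motion and DVARS quality control with frame
    censoring, per-run ordinary-least-squares On-Off contrast maps in
    percent-signal units, group linear mixed-effects comparison of therapeutic
    versus non-therapeutic stimulation configurations with Monte-Carlo
    cluster-extent correction, spatial parcel-permutation network statistics,
    and stimulation-field (volume of activated tissue) streamline filtering
    with per-network connectivity fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
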