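Package: pushpull
Title: Simulation and Analysis of a Probabilistic Push/Pull Choice Task
    with Nigrostriatal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing a head-fixed probabilistic
    push/pull lever choice task and the neural signals recorded alongside it.
    Includes a deterministic-given-seed task simulator with block reversals,
    win-stay/lose-switch logistic regression of choice on recent outcomes,
    reward-rate statistics, fiber-photometry dLight processing (detrending,
    isosbestic correction, dF/F, z-scoring, event alignment), optogenetic
    unit identification by antidromic spike collision and direct tagging,
    putative cell-type classification by waveform and firing statistics,
    peri-event time histogram statistics with reward-rate correlation and
    Fisher z comparisons, and ground-truth synthetic generators for spike
    trains, photometry traces and collision-test trace ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
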