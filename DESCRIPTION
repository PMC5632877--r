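Package: braindex
Title: Brain Engagement Index from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Brain Engagement Index (BEI), a real-time attention
    marker derived from single-channel frontal EEG by template matching of a
    1500 ms event-related-potential waveform against delta-band filtered
    signal, with a cascade of amplitude-ratio noise rejection rules.  Provides
    session-level engagement summaries, a therapist feedback advisory state
    machine for neurofeedback-guided rehabilitation sessions, paired
    nonparametric outcome statistics (exact and approximate Wilcoxon
    signed-rank, 2x2 chi-square, categorical effect sizes), and a synthetic
    EEG generator with controllable template-embedding and artifact rates so
    the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
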