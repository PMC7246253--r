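Package: dnfsearch
Title: Dynamic Neural Fields for Visual Search and Scene Working Memory
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.com>
Description: Simulates an autonomous neural dynamic architecture for visual
    exploration, scene working memory, cue retention and conjunctive visual
    search, built from Amari-type dynamic neural fields with lateral
    interaction. Includes a feed-forward color/orientation/size feature and
    salience frontend, attentional selection with inhibition of return and
    spatial working memory, capacity-limited space/feature memory maps,
    match/mismatch (condition-of-satisfaction) detection, synthetic
    search-array generation for preview experiments, and closed-form
    capacity-limited serial-search models with set-size slope analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
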