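Package: neurodaq
Title: Direct-to-Drive Neural Data Acquisition Stream Format, Simulator, and
    Integrity Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact byte-level codec for the raw sequential on-disk stream
    produced by direct-to-drive multichannel electrophysiology acquisition
    modules (1024 neural channels plus 96 auxiliary channels at 30 kS/s,
    16-bit, written as zero-padded 4096-byte records in 128-sample blocks).
    Includes closed-form data-rate, overhead and drive-capacity arithmetic;
    a synthetic session generator emulating spiking extracellular signals,
    noise floor, GPIO lines and sample-index rollover; a post-acquisition
    session integrity validator with a full fault census; a UDP-style
    snapshot/stream packetizer with loss simulation and gap-reporting
    reassembly; and a multi-module clock synchronization and session merge
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
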