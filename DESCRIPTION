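Package: piitrack
Title: Path Identification Index for GPS Telemetry of Caching Foragers
Version: 0.1.0
Authors@R:
    person("piitrack", "developers", email = "piitrack@example.org",
           role = c("aut", "cre"))
Description: Segments GPS telemetry of caching foragers (e.g. large felids)
    into behavioral classes using the Path Identification Index (PII), a
    composite of four per-fix movement metrics: speed, absolute turn angle,
    a straightness (tortuosity) index, and a site-fidelity measure of
    spatiotemporal clustering. Provides fix-table ingestion and validation
    on a nominal collar schedule, per-animal metric standardization,
    autocorrelation-driven selection of a centered moving-average smoothing
    window, three-class behavioral classification with evaluation against
    field-verified sites, a paired use-versus-availability step-selection
    analysis stratified by circadian and behavioral class, and a
    multi-state caching-forager simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
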