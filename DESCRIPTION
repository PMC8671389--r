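Package: heatshift
Title: Occupational Heat Exposure, Labor Productivity Loss, and Workshift
    Adaptation Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying heavy-labor productivity losses from
    occupational heat exposure and the potential to recover them by shifting
    work to cooler hours of the day.  Computes simplified Wet Bulb Globe
    Temperature (sWBGT) from meteorological fields via an isobaric wet-bulb
    solver, converts heat exposure to hourly work-loss fractions through a
    cumulative-normal exposure-response function, accounts losses over
    workday hour classes (including a 4+4+4 twelve-hour workday method and
    diurnal hour ranking), estimates per-gridcell monthly warming patterns
    from a model ensemble and applies them at chosen global warming levels,
    weights gridded losses by working-age population and heavy-labor shares
    to produce country and global totals in hours and PPP-adjusted dollars,
    and computes workshift adaptation-potential metrics across warming
    levels.  A synthetic-data generator emulates the statistical structure
    of the required climate, population, and labor inputs so the full
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
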