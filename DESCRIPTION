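Package: greymarkov
Title: Grey-Markov SCGM(1,1)c Forecasting for Short Annual Count Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the single-variable system-cloud grey model SCGM(1,1)c to
    short, strictly positive annual count series (for example occupational
    accident death tolls), amends the exponential trend fit with iterated
    grey residual models, and adjusts forecasts through a Markov chain on
    interval states of the actual-to-predicted ratio. Provides data
    validation and CSV input/output, fit diagnostics, horizon forecasting
    with frozen parameters, synthetic series generators for testing, a JSON
    report writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
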