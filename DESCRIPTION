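Package: mitoswitch
Title: Dynamics and Bistability of the Mitotic Cdk1-Greatwall-PP2A/B55 Switch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action ordinary differential equation model of the
    mitotic entry and exit switch formed by Cdk1/Cyclin B, its Tyr15
    regulators Wee1 and Cdc25, and the Greatwall-ENSA/ARPP19-PP2A/B55
    phosphatase module. Provides stiff integration of the network,
    chemical-inhibitor perturbation protocols (mitotic entry by Cdk1
    inhibitor release or by okadaic acid, mitotic exit by Cdk1
    inhibition), three interchangeable assumptions about the Greatwall
    phosphatase, steady-state and saddle-node bifurcation analysis
    (balance curves in total Cyclin B, two-parameter bistability maps),
    and a synthetic pseudo-immunoblot readout layer with event-timing
    and ordering statistics for comparing model predictions with
    quantified phospho-signal time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
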