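Package: epflowsim
Title: Discrete-Event Simulation of Inpatient Electrophysiology Patient Flow
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulation of the inpatient care pathway of a
    hospital cardiology department in which three patient classes compete for
    ward beds while electrophysiology (EP) patients additionally queue for
    on-duty electrophysiologists and EP labs. Daily arrivals follow negative
    binomial distributions and stay/procedure durations follow truncated
    lognormal distributions fitted by the method of moments from summary
    statistics. Includes a scenario engine for quantifying throughput gains
    from reducing pre-operative stay, post-operative stay, or operative time
    under bed-limited and lab-limited regimes, replication statistics with
    validation against observed discharge counts, and a calibration module
    that estimates all model inputs from a raw patient-log table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
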