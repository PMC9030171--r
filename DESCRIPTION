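Package: clinicdes
Title: Discrete-Event Simulation of an Outpatient MRI Diagnostic Ward
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process-interaction discrete-event simulation of the patient flow in an
    outpatient magnetic resonance imaging (MRI) diagnostic ward. The package encodes the
    diagnostic pathway (registration, anamnesis, optional contrast-medium injection,
    examination, reporting) as data-driven activity graphs, simulates staffed resources
    with working calendars under three operating policies (ordinary, pandemic
    infection-control, and an improved pandemic organisation), and computes operational
    and productivity key performance indicators: patient time decomposition, weekly
    throughput, MRI utilization, a seven-category attribution of scanner downtime, and
    staff utilization. Seeded replication runs, scenario comparison and knob calibration
    by bisection are included.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
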