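Package: camosim
Title: Artificial Evolution of Camouflage Patterns Under Simulated Predation
Version: 0.1.0
Authors@R:
    person("Robin", "Carrow", email = "rcarrow@example.org",
           role = c("aut", "cre"))
Description: Tools for running artificial-prey camouflage evolution
    experiments and for simulating them end to end on the desk. Provides a
    fixed-length pattern genome decoded into oval prey targets, a genetic
    algorithm driven by attack-order fitness ranks with a rescue rule for
    previously top-ranked prey, receptor-noise-limited colour and luminance
    discrimination, frequency-weighted colour difference, granularity
    pattern analysis and GabRat edge-disruption metrics, arena assignment
    and attack-record parsing for field bookkeeping, and a procedural
    gravel-background generator plus a tunable simulated observer so that
    selection-versus-drift experiments run closed loop with no field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
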