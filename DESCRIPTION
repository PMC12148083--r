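Package: paleowalk
Title: Agent-Based Least-Cost-Path Simulation of Hominin Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cost-minimizing Levy walks of foraging agents over
    gridded landscape cost surfaces, the agent-based least-cost-path (AB-LCP)
    approach to modelling long-distance dispersal through unknown terrain.
    Provides construction of traversal-cost surfaces from elevation, annual
    precipitation, hydrology and glacier layers (slope-dependent walker cost,
    desert and river-crossing penalties, flood-filled paleolakes as barriers),
    a seedable walk engine with cone-constrained step selection, occupancy
    memory and new-territory step doubling, route statistics (success buffers,
    straight-segment extraction, occupancy-frequency maps, arrival-time
    estimates), and a synthetic-landscape generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, mgcv, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
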