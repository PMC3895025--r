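Package: dmsbox
Title: Zero-Dimensional Box Model of the Marine DMS(P) Sulfur Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates dimethylsulfoniopropionate (DMSP) and dimethylsulfide
    (DMS) dynamics in a well-mixed coastal water column: DMSP production by
    three phytoplankton functional types (diatoms, nanoflagellates,
    Phaeocystis colonies), release by lysis, grazing and sedimentation,
    bacterial DMSPd uptake partitioned between sulfur assimilation,
    demethylation and lyase cleavage, bacterial DMS consumption,
    photooxidation, and air-sea DMS emission under two gas-transfer-velocity
    parameterizations. Includes a synthetic seasonal-bloom forcing generator,
    an annual sulfur-budget accountant with percentage-share diagnostics, a
    sensitivity-experiment harness, and five published empirical
    chlorophyll-based DMS prediction algorithms for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
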