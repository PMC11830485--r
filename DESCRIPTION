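Package: glucotitr
Title: Algorithm-Guided Premixed-Insulin Titration and In-Silico SMBG Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rules engine for weekly, self-monitored blood glucose (SMBG)
    driven dose adjustment of twice-daily premixed insulin in type 2 diabetes,
    together with the safety and outcome analytics that accompany a
    treat-to-target titration study: hypoglycemia level classification and
    episode detection, SMBG adherence, per-period hypoglycemia incidence,
    glycemic and dose summaries, and NGSP/IFCC/estimated-average-glucose
    conversions. A virtual-patient cohort simulator runs the full closed loop
    (twice-daily readings, weekly algorithmic recommendations, a physician
    approval gate, urgent out-of-cycle hypoglycemia responses) so the whole
    intervention can be exercised and evaluated in silico with no external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
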