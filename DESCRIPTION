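Package: pibcast
Title: Long-Term Seizure Forecasting from Intracranial EEG Band Power
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for long-term seizure forecasting from continuous
    multichannel intracranial EEG. Computes spectral power-in-band (PIB)
    features on non-overlapping one-minute blocks, trains logistic
    regression classifiers with greedy forward feature selection under
    contiguous (blocked) cross-validation, converts classifier risk into
    variable-duration seizure warnings calibrated to a target time in
    warning, and assesses significance against a time-in-warning-matched
    Poisson-process chance predictor. Includes readers for EDF recordings
    and seizure catalogs, a chunked binary container for months-long
    records, and a synthetic-data generator (clustered seizure times,
    1/f background with band-limited oscillations, pre-ictal band-power
    shifts, invalid-data gaps) so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
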