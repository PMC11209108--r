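Package: coralcw
Title: SMILES Correlation-Weight QSAR Models with Monte Carlo Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds one-descriptor QSAR regression models for ecotoxicological
    endpoints (e.g. log NOEC, log EC50) from SMILES strings alone. Molecular
    structure enters through "SMILES attributes" -- single SMILES atoms and
    adjacent-atom pairs -- each carrying a real-valued correlation weight. The
    optimal descriptor DCW(T, N) is the sum of the weights over a molecule's
    attributes; weights are fitted by Monte Carlo coordinate ascent on a target
    function combining training-set correlations with the index of ideality of
    correlation (IIC) and the correlation intensity index (CII) evaluated on a
    calibration set. Includes the four-subset validation protocol (active
    training, passive training, calibration, validation), the full panel of
    validation statistics (R2, Q2 leave-one-out, IIC, CII, RMSE, MAE, Fisher F),
    an applicability domain based on the distributional defect of SMILES
    attributes, and a synthetic-data generator with planted attribute weights
    for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
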