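Package: cwqsar
Title: Correlation-Weight Optimal Descriptors for SMILES-Based QSAR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Descriptor-free QSAR modelling directly on SMILES strings.
    Molecular attributes (single tokens, adjacent pairs and triples,
    fragments of local symmetry, and atom-pair proportions) receive
    correlation weights tuned by Monte Carlo optimization of target
    functions that combine the training-set correlations with the index
    of ideality of correlation (IIC), the correlation intensity index
    (CII), and the coefficient of conformism of a correlative prediction
    (CCCP), all derived from a leave-one-out influence kernel on the
    Pearson correlation. Includes semi-correlation binary classification,
    a statistical-defect applicability domain, Las Vegas split selection,
    a synthetic-data generator with known ground truth, and a command-line
    workflow (split, train, stats, predict).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
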