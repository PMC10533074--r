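Package: gaunet
Title: Genetic-Algorithm Design of Compact U-Shaped Segmentation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evolutionary search over compact U-shaped encoder-decoder
    convolutional networks for binary biomedical image segmentation. A
    ten-gene integer/real genome encodes the architecture and training
    recipe (block count, filters, kernel size, activation, pooling, batch
    normalization, dropout, optimizer, learning rate, batch size); a
    genetic algorithm with elitist environmental selection searches the
    space, scoring each candidate by short training on a validation split.
    Includes an exact layer-by-layer parameter accountant, a built-in CNN
    training engine (convolution, pooling, transposed-convolution
    upsampling, batch normalization, Dice loss, four optimizers), a
    segmentation metric suite (accuracy, precision, recall, Dice, IoU,
    pixel-wise AUC), and a seeded organ-phantom generator so the whole
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
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
RoxygenNote: 7.3.3
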