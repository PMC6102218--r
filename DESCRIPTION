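Package: ascansig
Title: A-Scan-Level Classification of Serous Retinal Disease Signatures in OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify individual optical coherence tomography (OCT)
    amplitude scans (A-scans) as pigment epithelial detachment (PED), serous
    retinal detachment (RD), or neither, as seen in central serous
    chorioretinopathy. Reads volumetric OCT stacks and en face label masks,
    denoises and contrast-normalizes B-scans, locates the retinal pigment
    epithelium (RPE) per A-scan with a maximum mean intensity window search,
    extracts RPE-anchored reflectivity feature vectors, trains a small
    feed-forward neural network (sigmoid activations, binary cross-entropy,
    Adam) from scratch, evaluates it with Monte Carlo cross-validation and on
    held-out eyes, and renders en face signature-probability maps. Includes a
    synthetic CSCR scene generator with ground-truth labels so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
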