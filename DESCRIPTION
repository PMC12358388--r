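Package: trtdose
Title: Pre-Treatment Dosimetry for Targeted Radioligand Therapy from Dynamic PET
Version: 0.1.0
Authors@R:
    person("IGPC", "Dosimetry Lab", email = "dosimetry@example.org", role = c("aut", "cre"))
Description: Voxel-wise pre-treatment dosimetry for targeted radioligand
    therapy (e.g. 177Lu-PSMA-617) from a single dynamic diagnostic PET/CT
    study. Implements the decay-incorporated standard two-tissue compartment
    model, voxel-wise Logan graphical analysis yielding distribution-volume
    maps, image-derived arterial input function fitting and therapy-scaled
    extrapolation, time-integrated activity and kernel-based absorbed-dose
    maps, and an extended linear-quadratic model (Lea-Catcheside dose
    protraction factor) for biologically effective dose. Includes a digital
    pelvis phantom with ground-truth kinetics for end-to-end validation,
    per-ROI reporting, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
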