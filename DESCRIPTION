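Package: mgcekit
Title: Quantitative Analysis Toolbox for the Telehealth Myasthenia Gravis Core Examination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Digitizes the eight exercises of the Myasthenia Gravis Core
    Examination (MG-CE) as performed over telehealth video. Provides hybrid
    eye and eyelid segmentation at webcam resolution with ptosis and ocular
    alignment metrics, body-pose kinematics for the arm-hold and sit-to-stand
    maneuvers, mouth and cheek deformation features for the cheek-puff and
    tongue-to-cheek exercises, a voice-feature suite (speech-segment
    extraction, BS.1770 integrated loudness, pitch, breathing-band spectral
    energy, Teager-Kaiser energy, spectral entropy) for the counting
    exercises, and ordinal 0-3 severity grading. Seeded synthetic-fixture
    generators (eye image sequences, landmark streams, counting audio) with
    analytic ground truth make every metric testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
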