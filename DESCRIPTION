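Package: mfv
Title: Maternal-Fetal Vital-Sign Processing for Wireless Wearable Sensor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and analytics chain for a time-synchronized
    wireless maternal-fetal monitoring sensor network. Derives maternal heart
    rate (modified Pan-Tompkins QRS detection on chest ECG), SpO2
    (ratio-of-ratios on dual-wavelength PPG), respiratory rate (accelerometer
    and ECG-derived-respiration fusion), and temperature trends; fetal heart
    rate from Doppler ultrasound envelopes with S1/S2 pairing and
    autocorrelation confirmation; uterine contractions from two-channel
    electrohysterography; fetal ECG isolation by maternal template
    cancellation; cuffless continuous blood pressure from pulse arrival time
    with linear calibration; Gaussian-mixture body-posture classification;
    Bland-Altman device agreement and time-to-vital heat maps. Includes a
    synthetic session simulator with full ground truth, and EDF/CSV/WAV I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
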