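Package: thalied
Title: Thalamic Interictal Epileptiform Discharge Analysis for ANT-DBS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse interictal epileptiform discharges (IEDs)
    recorded from externalized anterior-thalamus (ANT) deep-brain-stimulation
    leads together with scalp EEG. Provides a ground-truthed synthetic
    recording generator (1/f background, spike-and-slow-wave morphology,
    state-dependent Poisson event rates, probabilistic thalamo-cortical
    coupling), EDF read/write with annotation sidecars, bipolar/monopolar
    montage construction, automated spike vs sharp-transient detection,
    IED-triggered average potentials with follower/preceder/no-connection
    classification, DBS contact-to-region assignment with lead hit logic,
    and cohort-level outcome statistics (response rates, odds ratios,
    Fisher exact and Wilcoxon tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
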