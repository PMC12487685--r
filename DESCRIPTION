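Package: calmquant
Title: Quantitative Phenotyping for a Murine Calmodulinopathy Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for quantitative phenotyping of mice carrying
    an arrhythmogenic calmodulin missense allele. Implements allele-resolved
    transcript quantification (FPKM, allele fractions, mutant transcript
    share, 2^-ddCt chamber estimates), stable-isotope-dilution absolute
    quantification of wild-type and mutant calmodulin protein,
    cycloheximide-chase protein-turnover analysis, telemetric ECG statistics
    (signal averaging, rate-correction exponent fitting, QTc, arrhythmia
    scoring), calcium-dependent inactivation statistics (r50, f50) from
    whole-cell current traces, optical-mapping action-potential-duration and
    conduction-velocity maps, fibrosis and striation quantification from
    histology images, and Mendelian-ratio cohort statistics. A companion
    synthetic-data module generates inputs with the statistical structure
    each stage assumes, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
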