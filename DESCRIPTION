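Package: fgfr2axis
Title: Integrated Copy-Number, Methylation and Isoform Expression Analysis
    of the FGFR2/ESRP1 Axis in Gastric Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based calling of gene-level copy-number status from
    segment-mean (SEG) files and GISTIC gene-level tables, promoter
    methylation status from Illumina array beta-values and paired
    tumour/normal RRBS methylated-CpG counts, exon-surrogate
    quantification of the FGFR2-IIIb and FGFR2-IIIc splice isoforms with
    normal-median thresholding, integration of per-tumour states
    (including the ESRP1-amplified / FGFR2-normal / FGFR2-IIIc-high axis),
    and the downstream clinico-pathological association and Kaplan-Meier
    survival layer. Ships a synthetic paired tumour/normal multi-omic
    cohort generator so the whole pipeline runs end to end without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
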