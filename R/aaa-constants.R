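# Shared controlled vocabularies. This file collates first.

EVIDENCE_CLASSES <- c("clinical_approved", "clinical", "preclinical",
                      "in_silico", "frequency")
CLINICAL_CLASSES <- c("clinical_approved", "clinical")
OBJECT_KINDS <- c("oncogenicity", "target", "compound")
ACMG_CLASSES <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                  "pathogenic", "unclassified")
VARIANT_TYPES <- c("SNV", "indel", "CNV", "fusion", "biomarker")
MSI_MARKERS <- c("NR-21", "NR-24", "BAT-25", "BAT-26", "MONO-27")
ESCAT_LEVELS <- c("I", "II", "III", "IV", "none")

`%||%` <- function(a, b) if (is.null(a)) b else a
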