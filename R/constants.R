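# Shared vocabularies (defined here so every module sees them at load time).

CODING_TYPES <- c("missense", "stopgain", "stoploss", "startloss",
                  "frameshift_insertion", "frameshift_deletion",
                  "nonframeshift_insertion", "nonframeshift_deletion")
VARIANT_TYPES <- c(CODING_TYPES, "splicing", "synonymous", "ncRNA")
PREDICTOR_TOOLS <- c("sift", "polyphen2", "mutationtaster",
                     "primateai", "dann", "cadd")
INHERITANCE_MODES <- c("de_novo", "autosomal_dominant", "autosomal_recessive",
                       "compound_het_in_trans", "x_linked")
FEATURE_NAMES <- c("pheno_dir", "pheno_ppi", "gerp", "clinvar", "max_maf",
                   paste0("score_", PREDICTOR_TOOLS), "lit")
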