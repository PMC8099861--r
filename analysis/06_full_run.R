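#!/usr/bin/env Rscript
# End-to-end orchestrated run: fixtures, dose summary, phantom CT study,
# texture statistics, paired-difference ANOVA, histology quantification and
# qPCR, all into one run directory with a JSON summary.

library(riliquant)

cfg <- run_config(list(seed = 1,
                       histo_quant = list(n_fields = 6)))
summary <- run_pipeline(cfg, out_dir = "results/full_run")
str(summary, max.level = 2)
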