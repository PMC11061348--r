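#!/usr/bin/env Rscript
# Stage 1: materialize the synthetic study.
#
# A 600-chemical universe (40 planted structural clusters of 15, 729-bit
# fingerprints) stands in for the screening inventory; half of it plus 150
# structurally related extras form the assay-tested set, whose chemical-assay
# AUC table and full-model reference are drawn from the five activity
# archetypes. Writes the five interchange files plus ground truth.

source("analysis/00_config.R")

make_synthetic(CFG, INPUTS_DIR, uspec = USPEC, aspec = ASPEC,
               n_tested_extra = N_TESTED_EXTRA)

chems <- load_chemicals(file.path(INPUTS_DIR, "chemicals.csv"))
truth <- read.csv(file.path(INPUTS_DIR, "ground_truth.csv"))
cat(sprintf("universe: %d chemicals in %d planted clusters\n",
            sum(chems$in_universe), length(unique(truth$true_cluster))))
cat(sprintf("tested set: %d chemicals (%d inside the universe)\n",
            sum(chems$in_tested_set),
            sum(chems$in_tested_set & chems$in_universe)))
print(table(truth$archetype[nzchar(truth$archetype)]))
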