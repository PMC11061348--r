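#!/usr/bin/env Rscript
# Stage 3: map the tested chemicals into the universe clusters.
#
# Neighbourhood size is chosen by the 80/20 held-out protocol over the
# clustered universe, then every tested chemical (universe members included,
# as an internal consistency check) is assigned by KNN under Tanimoto
# distance.

source("analysis/00_config.R")

fps <- load_fingerprints(file.path(INPUTS_DIR, "fingerprints.csv"))
chems <- load_chemicals(file.path(INPUTS_DIR, "chemicals.csv"))
uni_fps <- fp_subset(fps, chems$chem_id[chems$in_universe])
clusters <- read_assignment(file.path(TABLES_DIR, "universe_clusters.csv"))

ksel <- select_k(uni_fps, clusters, k_candidates = CFG$k_candidates,
                 split_fraction = CFG$split_fraction, seed = CFG$seed)
print(ksel)

tested_fps <- fp_subset(fps, chems$chem_id[chems$in_tested_set])
mapped <- knn_assign(uni_fps, clusters, tested_fps, k = ksel$chosen_k)

in_both <- intersect(names(mapped), names(clusters))
cat(sprintf("%d of %d universe-member tested chemicals map to their own cluster\n",
            sum(unclass(mapped)[in_both] == unclass(clusters)[in_both]),
            length(in_both)))
cov <- cluster_coverage(clusters, mapped)
cat(sprintf("tested set covers %d of %d universe clusters (%.0f%%)\n",
            cov$n_covered_clusters, cov$n_universe_clusters,
            100 * cov$coverage_fraction))

write.csv(data.frame(k = names(ksel$accuracy_by_k),
                     accuracy = unname(ksel$accuracy_by_k),
                     chosen = as.integer(names(ksel$accuracy_by_k)) == ksel$chosen_k),
          file.path(TABLES_DIR, "kselect.csv"), row.names = FALSE)
write.csv(data.frame(chem_id = names(mapped), cluster_id = as.integer(mapped)),
          file.path(TABLES_DIR, "tested_clusters.csv"), row.names = FALSE)
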