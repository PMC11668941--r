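#!/usr/bin/env Rscript
# Stage 4 — spatial permutation network statistics.
#
# Aggregates run contrasts to parcel means, averages them within condition,
# and runs the spatial permutation tests over the parcel-to-network
# assignment: one-sided suppression tests per condition and the two-sided
# therapeutic-vs-non-therapeutic difference test, 10,000 surrogates,
# Bonferroni-corrected over the seven networks.

suppressPackageStartupMessages(library(stimcycle))

config <- read_pipeline_config("results/pipeline_config.yaml")
study_dir <- "results/study"
atlas <- read_atlas(file.path(study_dir, "atlas", "atlas.nii.gz"),
                    file.path(study_dir, "atlas", "parcels.tsv"))
metas <- study_run_metas(study_dir)

pv <- vapply(metas, function(m) {
  stem <- sprintf("%s_run-%02d", m$subject, m$run)
  img <- RNifti::readNifti(file.path("results/contrasts",
                                     paste0(stem, "_contrast.nii.gz")))
  parcel_means(array(as.numeric(img), dim = dim(img)), atlas)
}, numeric(n_parcels(atlas)))
ther <- vapply(metas, `[[`, TRUE, "therapeutic")

v_ther <- rowMeans(pv[, ther, drop = FALSE])
v_non <- rowMeans(pv[, !ther, drop = FALSE])

t_ther <- one_sided_suppression_test(v_ther, atlas$assignment,
                                     config$n_perm, seed = config$seed + 11L,
                                     network_names = atlas$network_names)
t_non <- one_sided_suppression_test(v_non, atlas$assignment,
                                    config$n_perm, seed = config$seed + 12L,
                                    network_names = atlas$network_names)
t_diff <- two_sided_difference_test(v_ther, v_non, atlas$assignment,
                                    config$n_perm, seed = config$seed + 13L,
                                    network_names = atlas$network_names)

tab <- data.frame(network = atlas$network_names,
                  therapeutic_mean = t_ther$table$observed_mean,
                  nontherapeutic_mean = t_non$table$observed_mean,
                  difference = t_diff$table$observed_mean,
                  p_therapeutic = t_ther$table$p_uncorrected,
                  p_therapeutic_bonf = t_ther$table$p_bonferroni,
                  p_difference = t_diff$table$p_uncorrected,
                  p_difference_bonf = t_diff$table$p_bonferroni)
write.csv(tab, "results/network_stats.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nstrongest suppression: %s (therapeutic p = %g, Bonferroni %g)\n",
            tab$network[which.max(-tab$therapeutic_mean)],
            min(tab$p_therapeutic), min(tab$p_therapeutic_bonf)))
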