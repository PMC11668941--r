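#!/usr/bin/env Rscript
# Stage 5 — stimulation-field structural connectivity.
#
# For every stimulation configuration used in the study: paired-sphere VAT
# at the active bipolar contacts, streamline filtering of the subject
# tractogram through the VAT, per-network streamline fractions by distal
# endpoint, and the one-sided (more-connected) and two-sided
# (therapeutic-vs-non-therapeutic) permutation tests on the parcel-level
# streamline counts.

suppressPackageStartupMessages(library(stimcycle))

config <- read_pipeline_config("results/pipeline_config.yaml")
study_dir <- "results/study"
atlas <- read_atlas(file.path(study_dir, "atlas", "atlas.nii.gz"),
                    file.path(study_dir, "atlas", "parcels.tsv"))
metas <- study_run_metas(study_dir)

cfg_rows <- unique(do.call(rbind, lapply(metas, function(m)
  data.frame(subject = m$subject, config_id = m$config_id,
             therapeutic = m$therapeutic,
             amplitude_mA = m$amplitude_mA))))

profiles <- vector("list", nrow(cfg_rows))
for (i in seq_len(nrow(cfg_rows))) {
  row <- cfg_rows[i, ]
  ej <- jsonlite::read_json(file.path(study_dir, row$subject,
                                      "electrodes.json"),
                            simplifyVector = TRUE)
  elec <- electrode_model(ej$contacts, ej$lead_id, ej$hemisphere)
  vat <- estimate_vat(elec, study_stim_config(row$config_id,
                                              row$amplitude_mA))
  streams <- read_tck(file.path(study_dir, row$subject,
                                paste0(row$subject, "_tracks.tck")))
  filt <- streamlines_through_vat(streams, vat)
  profiles[[i]] <- list(row = row,
                        profile = network_streamline_fractions(filt, atlas,
                                                               vat))
  cat(sprintf("%s %-22s: %5d/%5d streamlines through VAT\n", row$subject,
              row$config_id, length(filt), length(streams)))
}

mean_counts <- function(ther) {
  sel <- vapply(profiles, function(p) p$row$therapeutic == ther, logical(1))
  rowMeans(vapply(profiles[sel],
                  function(p) as.numeric(p$profile$parcel_counts),
                  numeric(n_parcels(atlas))))
}
ther_counts <- mean_counts(TRUE)
non_counts <- mean_counts(FALSE)

t_conn <- connectivity_permutation_test(ther_counts, atlas$assignment,
                                        config$n_perm,
                                        seed = config$seed + 21L,
                                        network_names = atlas$network_names)
t_diff <- two_sided_difference_test(ther_counts, non_counts,
                                    atlas$assignment, config$n_perm,
                                    seed = config$seed + 22L,
                                    network_names = atlas$network_names)

tab <- data.frame(
  network = atlas$network_names,
  therapeutic_fraction = as.numeric(rowsum(ther_counts, atlas$assignment)) /
    sum(ther_counts),
  nontherapeutic_fraction = as.numeric(rowsum(non_counts,
                                              atlas$assignment)) /
    sum(non_counts),
  p_connectivity = t_conn$table$p_uncorrected,
  p_connectivity_bonf = t_conn$table$p_bonferroni,
  p_difference = t_diff$table$p_uncorrected,
  p_difference_bonf = t_diff$table$p_bonferroni)
write.csv(tab, "results/connectivity.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nmost connected network (therapeutic): %s, fraction %.2f\n",
            tab$network[which.max(tab$therapeutic_fraction)],
            max(tab$therapeutic_fraction)))
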