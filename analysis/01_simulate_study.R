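#!/usr/bin/env Rscript
# Stage 1 — synthesise the study.
#
# Builds the synthetic DBS cycling study the rest of the workflow analyses:
# 5 subjects (3 responders), 23 six-minute runs (6 therapeutic, 17
# non-therapeutic) with 1-min On/Off cycling and 8-s ramps, a 100-parcel /
# 7-network atlas, per-subject electrodes and tractograms. The volume grid
# and tractogram size are scaled to desk size (16^3 voxels, 4,000
# streamlines per subject); the run structure and timing are not scaled.

suppressPackageStartupMessages(library(stimcycle))

dir.create("results", showWarnings = FALSE)

config <- pipeline_config(
  study = study_config(grid_shape = c(16, 16, 16), n_streamlines = 4000,
                       seed = 11),
  n_perm = 10000,
  cluster = cluster_config(n_iter = 1000),
  smoothness_fwhm = 2,
  seed = 11)
write_pipeline_config(config, "results/pipeline_config.yaml")

study_dir <- "results/study"
if (!file.exists(file.path(study_dir, "manifest.tsv"))) {
  message("generating synthetic study ...")
  manifest <- generate_study(config$study, study_dir)
} else {
  message("study already present; reusing")
  manifest <- read.delim(file.path(study_dir, "manifest.tsv"))
}

report <- validate_inputs(study_dir)
stopifnot(nrow(report) == 0)

runs <- study_run_table(config$study)
cat(sprintf("study: %d subjects, %d runs (%d therapeutic over %d responders)\n",
            length(unique(runs$subject)), nrow(runs), sum(runs$therapeutic),
            length(unique(runs$subject[runs$therapeutic]))))
cat(sprintf("files written: %d (see %s/manifest.tsv)\n", nrow(manifest),
            study_dir))
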