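#!/usr/bin/env Rscript
# Stage 2 — per-run QC and On-Off contrasts.
#
# For every run: motion/DVARS confounds with FD > 0.5 mm / std-DVARS > 1.5
# censoring, per-voxel scaling to a mean of 100, OLS fit of the
# HRF-convolved On and Off regressors plus Legendre drift (orders 0..3)
# with censored rows deleted, and the [On]-[Off] contrast map in
# percent-signal units.

suppressPackageStartupMessages(library(stimcycle))

config <- read_pipeline_config("results/pipeline_config.yaml")
study_dir <- "results/study"
out_dir <- "results/contrasts"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

atlas <- read_atlas(file.path(study_dir, "atlas", "atlas.nii.gz"),
                    file.path(study_dir, "atlas", "parcels.tsv"))
metas <- study_run_metas(study_dir)

censored_total <- 0L
for (m in metas) {
  img <- RNifti::readNifti(m$bold_path)
  bold <- array(as.numeric(img), dim = dim(img))
  motion <- read.delim(m$motion_path)
  design <- cycling_design(m$tr_s, dim(bold)[4], m$cycle_s, m$ramp_s)
  res <- run_contrast_pipeline(bold, motion, design, config$qc,
                               meta = m[c("subject", "run", "therapeutic",
                                          "responder", "config_id")],
                               mask = atlas$labels > 0,
                               drift_order = config$drift_order,
                               ramp_mode = config$ramp_mode)
  stem <- sprintf("%s_run-%02d", m$subject, m$run)
  write_volume_nifti(res$contrast$data, atlas$affine,
                     file.path(out_dir, paste0(stem, "_contrast.nii.gz")))
  write_design_matrix(res$dm, file.path(out_dir, paste0(stem, "_design.tsv")))
  write_confounds(res$confounds,
                  file.path(out_dir, paste0(stem, "_confounds.tsv")))
  censored_total <- censored_total + sum(res$confounds$censor)
}
cat(sprintf("fitted %d runs; %d frames censored in total (%.1f%% of %d)\n",
            length(metas), censored_total,
            100 * censored_total / (length(metas) * 180),
            length(metas) * 180))
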