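#' End-to-end pipeline configuration
#'
#' Bundles the study source (a [study_config()] to synthesise, or an
#' existing study directory), QC thresholds, GLM options, permutation and
#' cluster settings, and the seeds. All randomness derives from explicit
#' seeds; there is no wall-clock seeding. The configuration round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param study A [study_config()], or `NULL` when `study_dir` points at an
#'   existing study.
#' @param study_dir Existing study directory (ignored when `study` given;
#'   then it is where the synthetic study is written).
#' @param qc A [qc_config()].
#' @param drift_order,ramp_mode GLM options.
#' @param n_perm Surrogates for the permutation tests.
#' @param cluster A [cluster_config()] or `NULL` to skip the cluster-extent
#'   stage.
#' @param smoothness_fwhm Noise smoothness (voxels) for the cluster null.
#' @param seed Master analysis seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(), study_dir = NULL,
                            qc = qc_config(), drift_order = 3,
                            ramp_mode = "excluded", n_perm = 10000,
                            cluster = NULL, smoothness_fwhm = 2,
                            seed = 1) {
  stopifnot(n_perm >= 1, seed == as.integer(seed), seed >= 0, seed < 2^20)
  structure(list(study = study, study_dir = study_dir, qc = qc,
                 drift_order = drift_order, ramp_mode = ramp_mode,
                 n_perm = as.integer(n_perm), cluster = cluster,
                 smoothness_fwhm = smoothness_fwhm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(.unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    study = if (is.null(x$study)) NULL else .rebuild_study_config(x$study),
    study_dir = x$study_dir,
    qc = qc_config(x$qc$fd_thresh, x$qc$dvars_thresh, x$qc$head_radius_mm),
    drift_order = x$drift_order, ramp_mode = x$ramp_mode,
    n_perm = x$n_perm,
    cluster = if (is.null(x$cluster)) NULL else
      cluster_config(x$cluster$voxel_p, x$cluster$alpha, x$cluster$nn,
                     x$cluster$n_iter),
    smoothness_fwhm = x$smoothness_fwhm, seed = x$seed)
  cfg
}

.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (is.matrix(x)) {
    x <- apply(x, 1, as.numeric, simplify = FALSE)
  }
  x
}

.rebuild_study_config <- function(s) {
  ep <- s$effect_profile
  study_config(
    n_subjects = s$n_subjects,
    responder_flags = unlist(s$responder_flags),
    therapeutic_runs = unlist(s$therapeutic_runs),
    nontherapeutic_runs = unlist(s$nontherapeutic_runs),
    grid_shape = unlist(s$grid_shape), voxel_size_mm = s$voxel_size_mm,
    tr_s = s$tr_s, run_length_s = s$run_length_s, cycle_s = s$cycle_s,
    ramp_s = s$ramp_s, n_parcels = s$n_parcels,
    network_sizes = unlist(s$network_sizes),
    effect_profile = network_effect_profile(
      network_names = unlist(ep$network_names),
      therapeutic = stats::setNames(unlist(ep$therapeutic),
                                    unlist(ep$network_names)),
      nontherapeutic = stats::setNames(unlist(ep$nontherapeutic),
                                       unlist(ep$network_names)),
      parcel_jitter_sd = ep$parcel_jitter_sd),
    noise = noise_spec(s$noise$sd, s$noise$ar1, unlist(s$noise$drift_coefs),
                       s$noise$spike_prob, s$noise$spike_mm),
    n_streamlines = s$n_streamlines, amplitude_mA = s$amplitude_mA,
    therapeutic_weights = stats::setNames(
      unlist(s$therapeutic_weights), names(s$therapeutic_weights)),
    nontherapeutic_weights = stats::setNames(
      unlist(s$nontherapeutic_weights), names(s$nontherapeutic_weights)),
    seed = s$seed)
}

#' Run the full analysis pipeline
#'
#' Stages, in order, all file-based so any stage can be re-run standalone:
#' 1. **synth** — generate the synthetic study (skipped when `study_dir`
#'    holds an existing one);
#' 2. **qc + glm** — per run: confounds, censoring, mean-100 scaling, OLS
#'    fit, On-Off contrast map (NIfTI + design TSV);
#' 3. **group** — parcel-wise linear mixed-effects therapeutic effect; and,
#'    if a cluster configuration is present, a Monte-Carlo cluster-extent
#'    threshold for the voxel map;
#' 4. **netstats** — network suppression tests for each condition and the
#'    two-sided therapeutic-vs-non-therapeutic difference test (the
#'    bar-plot-ready network table);
#' 5. **connectivity** — per-configuration VAT streamline filtering,
#'    network fractions, and their permutation tests.
#'
#' Outputs are deterministic given the configuration: re-running with the
#' same config yields byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Object of class `results_bundle`: list of tables and file paths
#'   plus a provenance block (config hash, seeds, package version).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(stage, msg) cat(sprintf("[%s] %s\n", stage, msg),
                                   file = log_file, append = TRUE)
  cat("", file = log_file)

  # --- stage: synth -------------------------------------------------------
  study_dir <- config$study_dir
  if (!is.null(config$study)) {
    if (is.null(study_dir)) study_dir <- file.path(out_dir, "study")
    if (!file.exists(file.path(study_dir, "manifest.tsv"))) {
      logf("synth", paste("generating study in", study_dir))
      generate_study(config$study, study_dir)
    } else {
      logf("synth", "existing study found; reusing")
    }
  }
  if (is.null(study_dir) || !dir.exists(study_dir)) {
    stop("stage synth: no study available (study_dir missing)",
         call. = FALSE)
  }
  report <- validate_inputs(study_dir)
  if (nrow(report) > 0) {
    stop("stage synth: study validation failed for ",
         report$file[1], ": ", report$problem[1], call. = FALSE)
  }

  atlas <- read_atlas(file.path(study_dir, "atlas", "atlas.nii.gz"),
                      file.path(study_dir, "atlas", "parcels.tsv"))

  # --- stage: qc + glm ----------------------------------------------------
  con_dir <- file.path(out_dir, "contrasts")
  dir.create(con_dir, showWarnings = FALSE)
  metas <- study_run_metas(study_dir)
  contrasts <- vector("list", length(metas))
  for (i in seq_along(metas)) {
    m <- metas[[i]]
    res <- tryCatch({
      bold <- array(as.numeric(RNifti::readNifti(m$bold_path)),
                    dim = dim(RNifti::readNifti(m$bold_path)))
      motion <- utils::read.delim(m$motion_path)
      design <- cycling_design(m$tr_s, dim(bold)[4], m$cycle_s, m$ramp_s)
      run_contrast_pipeline(bold, motion, design, config$qc,
                            meta = m[c("subject", "run", "therapeutic",
                                       "responder", "config_id")],
                            mask = atlas$labels > 0,
                            drift_order = config$drift_order,
                            ramp_mode = config$ramp_mode)
    }, error = function(e) {
      stop("stage glm failed for ", m$subject, " run ", m$run, ": ",
           conditionMessage(e), call. = FALSE)
    })
    contrasts[[i]] <- res$contrast
    stem <- sprintf("%s_run-%02d", m$subject, m$run)
    write_volume(res$contrast$data, atlas$affine,
                 file.path(con_dir, paste0(stem, "_contrast.nii.gz")))
    write_design_matrix(res$dm,
                        file.path(con_dir, paste0(stem, "_design.tsv")))
    write_confounds(res$confounds,
                    file.path(con_dir, paste0(stem, "_confounds.tsv")))
    logf("glm", sprintf("%s: %d frames censored", stem,
                        sum(res$confounds$censor)))
  }

  # --- stage: group -------------------------------------------------------
  meta_df <- do.call(rbind, lapply(metas, function(m)
    data.frame(subject = m$subject, run = m$run,
               therapeutic = m$therapeutic, responder = m$responder)))
  gdesign <- group_design(meta_df$subject, meta_df$therapeutic,
                          meta_df$responder)
  group_tab <- group_parcel_lme(contrasts, gdesign, atlas)
  if (any(group_tab$method == "ols", na.rm = TRUE)) {
    logf("group", sprintf("OLS fallback in %d parcel(s)",
                          sum(group_tab$method == "ols", na.rm = TRUE)))
  }
  utils::write.csv(group_tab, file.path(out_dir, "group_parcel_lme.csv"),
                   row.names = FALSE)

  cluster_thr <- NULL
  if (!is.null(config$cluster)) {
    cluster_thr <- cluster_size_threshold(dim(atlas$labels),
                                          config$smoothness_fwhm,
                                          config$cluster,
                                          seed = config$seed + 101L)
    jsonlite::write_json(
      list(threshold = as.integer(cluster_thr),
           voxel_p = config$cluster$voxel_p, alpha = config$cluster$alpha,
           nn = config$cluster$nn, n_iter = config$cluster$n_iter,
           smoothness_fwhm = config$smoothness_fwhm,
           null_quantiles = as.list(stats::quantile(
             attr(cluster_thr, "max_sizes"), c(0.5, 0.9, 0.95, 0.99)))),
      file.path(out_dir, "cluster_null.json"), auto_unbox = TRUE)
    logf("group", sprintf("cluster-extent threshold %d voxels",
                          as.integer(cluster_thr)))
  }

  # --- stage: netstats ----------------------------------------------------
  pv <- vapply(contrasts, parcel_means, numeric(n_parcels(atlas)),
               atlas = atlas)
  ther <- rowMeans(pv[, meta_df$therapeutic, drop = FALSE])
  nonther <- rowMeans(pv[, !meta_df$therapeutic, drop = FALSE])
  t_ther <- one_sided_suppression_test(ther, atlas$assignment,
                                       config$n_perm,
                                       seed = config$seed + 11L,
                                       network_names = atlas$network_names)
  t_non <- one_sided_suppression_test(nonther, atlas$assignment,
                                      config$n_perm,
                                      seed = config$seed + 12L,
                                      network_names = atlas$network_names)
  t_diff <- two_sided_difference_test(ther, nonther, atlas$assignment,
                                      config$n_perm,
                                      seed = config$seed + 13L,
                                      network_names = atlas$network_names)
  network_table <- data.frame(
    network = atlas$network_names,
    therapeutic_mean = t_ther$table$observed_mean,
    nontherapeutic_mean = t_non$table$observed_mean,
    difference = t_diff$table$observed_mean,
    p_therapeutic = t_ther$table$p_uncorrected,
    p_therapeutic_bonf = t_ther$table$p_bonferroni,
    p_nontherapeutic = t_non$table$p_uncorrected,
    p_nontherapeutic_bonf = t_non$table$p_bonferroni,
    p_difference = t_diff$table$p_uncorrected,
    p_difference_bonf = t_diff$table$p_bonferroni,
    n_perm = config$n_perm)
  if (config$n_perm < 100) {
    network_table$note <- sprintf(
      "low resolution: p floors at %g", 1 / config$n_perm)
  }
  utils::write.csv(network_table, file.path(out_dir, "network_stats.csv"),
                   row.names = FALSE)

  # --- stage: connectivity ------------------------------------------------
  conn <- .connectivity_stage(study_dir, atlas, config, logf)
  utils::write.csv(conn$table, file.path(out_dir, "connectivity.csv"),
                  row.names = FALSE)

  provenance <- list(
    config_hash = .config_hash(config), seed = config$seed,
    n_perm = config$n_perm,
    package_version = as.character(utils::packageVersion("stimcycle")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)

  structure(list(contrast_dir = con_dir, group_table = group_tab,
                 cluster_threshold = cluster_thr,
                 network_table = network_table,
                 connectivity_table = conn$table,
                 connectivity_tests = conn$tests,
                 netstat_tests = list(therapeutic = t_ther,
                                      nontherapeutic = t_non,
                                      difference = t_diff),
                 provenance = provenance, out_dir = out_dir),
            class = "results_bundle")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_pipeline_config(config, f)
  unname(tools::md5sum(f))
}

#' List the runs of a study directory
#'
#' @param study_dir Directory written by [generate_study()].
#' @return List of run metadata (one element per run) with `bold_path` and
#'   `motion_path` added.
#' @export
study_run_metas <- function(study_dir) {
  meta_files <- sort(list.files(study_dir, pattern = "_meta\\.json$",
                                recursive = TRUE, full.names = TRUE))
  lapply(meta_files, function(f) {
    m <- jsonlite::read_json(f)
    stem <- sub("_meta\\.json$", "", f)
    m$bold_path <- paste0(stem, "_bold.nii.gz")
    m$motion_path <- paste0(stem, "_motion.tsv")
    m
  })
}

.connectivity_stage <- function(study_dir, atlas, config, logf) {
  metas <- study_run_metas(study_dir)
  cfg_rows <- unique(do.call(rbind, lapply(metas, function(m)
    data.frame(subject = m$subject, config_id = m$config_id,
               therapeutic = m$therapeutic,
               amplitude_mA = m$amplitude_mA))))
  profiles <- list()
  for (i in seq_len(nrow(cfg_rows))) {
    row <- cfg_rows[i, ]
    elec_f <- file.path(study_dir, row$subject, "electrodes.json")
    tck_f <- file.path(study_dir, row$subject,
                       paste0(row$subject, "_tracks.tck"))
    if (!file.exists(elec_f) || !file.exists(tck_f)) next
    ej <- jsonlite::read_json(elec_f, simplifyVector = TRUE)
    elec <- electrode_model(ej$contacts, ej$lead_id, ej$hemisphere)
    stim <- study_stim_config(row$config_id, row$amplitude_mA)
    vat <- estimate_vat(elec, stim)
    streams <- read_tck(tck_f)
    filt <- streamlines_through_vat(streams, vat)
    prof <- network_streamline_fractions(filt, atlas, vat)
    logf("connectivity", sprintf("%s %s: %d/%d streamlines through VAT",
                                 row$subject, row$config_id,
                                 length(filt), length(streams)))
    profiles[[i]] <- list(row = row, profile = prof)
  }
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  if (length(profiles) == 0) {
    return(list(table = data.frame(), tests = NULL))
  }
  K <- length(atlas$network_names)
  counts_for <- function(ther) {
    sel <- vapply(profiles, function(p) p$row$therapeutic == ther,
                  logical(1))
    if (!any(sel)) return(NULL)
    rowMeans(vapply(profiles[sel],
                    function(p) as.numeric(p$profile$parcel_counts),
                    numeric(n_parcels(atlas))))
  }
  ther_counts <- counts_for(TRUE)
  non_counts <- counts_for(FALSE)
  tests <- list()
  tab <- data.frame(network = atlas$network_names)
  if (!is.null(ther_counts)) {
    tests$therapeutic <- connectivity_permutation_test(
      ther_counts, atlas$assignment, config$n_perm,
      seed = config$seed + 21L, network_names = atlas$network_names)
    tot <- sum(ther_counts)
    tab$therapeutic_fraction <- if (tot > 0)
      as.numeric(rowsum(ther_counts, atlas$assignment)) / tot else NA
    tab$p_therapeutic <- tests$therapeutic$table$p_uncorrected
    tab$p_therapeutic_bonf <- tests$therapeutic$table$p_bonferroni
  }
  if (!is.null(non_counts)) {
    tot <- sum(non_counts)
    tab$nontherapeutic_fraction <- if (tot > 0)
      as.numeric(rowsum(non_counts, atlas$assignment)) / tot else NA
  }
  if (!is.null(ther_counts) && !is.null(non_counts)) {
    tests$difference <- two_sided_difference_test(
      ther_counts, non_counts, atlas$assignment, config$n_perm,
      seed = config$seed + 22L, network_names = atlas$network_names)
    tab$p_difference <- tests$difference$table$p_uncorrected
    tab$p_difference_bonf <- tests$difference$table$p_bonferroni
  }
  list(table = tab, tests = tests)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>\n  outputs in:", x$out_dir, "\n")
  cat("  network table:\n")
  print(x$network_table, row.names = FALSE)
  invisible(x)
}
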