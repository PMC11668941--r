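#' Configuration of a synthetic DBS cycling study
#'
#' The defaults reproduce the design of the experiment the analysis
#' targets: five subjects (three treatment responders, two non-responders),
#' 6-minute runs at TR 2 s with one-minute On/Off cycling and 8-s ramps
#' starting in Off, six therapeutic runs spread over the responders and 17
#' non-therapeutic runs over all five subjects (23 runs total), stimulation
#' at 5-6 mA on adjacent bipolar contact pairs, and one whole-brain
#' tractogram per subject.
#'
#' @param n_subjects Number of subjects.
#' @param responder_flags Logical per subject.
#' @param therapeutic_runs Integer per subject: number of therapeutic runs
#'   (only allowed in responders).
#' @param nontherapeutic_runs Integer per subject.
#' @param grid_shape,voxel_size_mm Voxel grid of the synthetic volumes.
#' @param tr_s,run_length_s,cycle_s,ramp_s Cycling-paradigm timing,
#'   seconds; `run_length_s` must cover whole On/Off cycles.
#' @param n_parcels,network_sizes Atlas layout.
#' @param effect_profile A [network_effect_profile()].
#' @param noise A [noise_spec()].
#' @param n_streamlines Streamlines per subject tractogram (default the
#'   real-data scale of 200,000; scale down for quick studies).
#' @param amplitude_mA Stimulation amplitude.
#' @param therapeutic_weights,nontherapeutic_weights Named streamline
#'   destination probabilities (see [simulate_streamlines()]) for
#'   therapeutic and non-therapeutic configuration VATs.
#' @param seed Integer master seed; every run/subject seed derives from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 5,
                         responder_flags = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                         therapeutic_runs = c(2, 2, 2, 0, 0),
                         nontherapeutic_runs = c(3, 3, 3, 4, 4),
                         grid_shape = c(24, 24, 24), voxel_size_mm = 4,
                         tr_s = 2, run_length_s = 360, cycle_s = 60,
                         ramp_s = 8, n_parcels = 100,
                         network_sizes = c(17, 13, 12, 13, 12, 13, 20),
                         effect_profile = network_effect_profile(),
                         noise = noise_spec(), n_streamlines = 200000,
                         amplitude_mA = 5,
                         therapeutic_weights = NULL,
                         nontherapeutic_weights = NULL,
                         seed = 1) {
  stopifnot(n_subjects >= 1,
            length(responder_flags) == n_subjects,
            length(therapeutic_runs) == n_subjects,
            length(nontherapeutic_runs) == n_subjects,
            all(therapeutic_runs[!responder_flags] == 0),
            run_length_s %% (2 * cycle_s) == 0,
            seed == as.integer(seed), seed >= 0, seed < 2^20)
  net_names <- effect_profile$network_names
  if (is.null(therapeutic_weights)) {
    # therapeutic stimulation fields connect preferentially to the DMN
    w <- stats::setNames(rep(0.05, length(net_names)), net_names)
    if ("Default" %in% net_names) w["Default"] <- 0.35
    if ("Limbic" %in% net_names) w["Limbic"] <- 0.20
    therapeutic_weights <- c(w, elsewhere = 1 - sum(w))
  }
  if (is.null(nontherapeutic_weights)) {
    w <- stats::setNames(rep(0.08, length(net_names)), net_names)
    nontherapeutic_weights <- c(w, elsewhere = 1 - sum(w))
  }
  structure(list(n_subjects = n_subjects,
                 responder_flags = responder_flags,
                 therapeutic_runs = therapeutic_runs,
                 nontherapeutic_runs = nontherapeutic_runs,
                 grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 tr_s = tr_s, run_length_s = run_length_s,
                 cycle_s = cycle_s, ramp_s = ramp_s,
                 n_parcels = n_parcels, network_sizes = network_sizes,
                 effect_profile = effect_profile, noise = noise,
                 n_streamlines = n_streamlines,
                 amplitude_mA = amplitude_mA,
                 therapeutic_weights = therapeutic_weights,
                 nontherapeutic_weights = nontherapeutic_weights,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Run table of a study configuration
#'
#' @param config A [study_config()].
#' @return Data frame: `subject`, `run`, `therapeutic`, `responder`,
#'   `config_id`, `seed` per run.
#' @export
study_run_table <- function(config) {
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    nt <- config$therapeutic_runs[s]
    nn <- config$nontherapeutic_runs[s]
    ther <- c(rep(TRUE, nt), rep(FALSE, nn))
    if (nt + nn == 0) next
    rows[[s]] <- data.frame(
      subject = sprintf("sub-%02d", s), run = seq_len(nt + nn),
      therapeutic = ther, responder = config$responder_flags[s],
      config_id = ifelse(ther, "therapeutic-pair",
                         paste0("nontherapeutic-pair-",
                                rep_len(1:3, nt + nn))))
  }
  tab <- do.call(rbind, rows)
  # per-run seeds derived from the master seed, kept well below 2^31
  tab$seed <- config$seed * 1000L + seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

# Electrode geometry for one subject: 4 collinear contacts, 2 mm apart,
# running through the grid centre.
.study_electrode <- function(config, subject_idx) {
  ctr <- (config$grid_shape / 2) * config$voxel_size_mm
  z <- (0:3) * 2
  contacts <- cbind(ctr[1] + (subject_idx - 3) * 0.5, ctr[2], ctr[3] + z - 3)
  electrode_model(contacts, lead_id = sprintf("lead-%02d", subject_idx),
                  hemisphere = if (subject_idx %% 2 == 0) "right" else
                    "left")
}

#' Bipolar pair for a synthetic-study configuration id
#'
#' Therapeutic runs stimulate contacts 2-3; non-therapeutic configuration
#' ids cycle over the remaining adjacent pairs.
#'
#' @param config_id Configuration id from the run metadata.
#' @param amplitude_mA Stimulation amplitude.
#' @return A [stimulation_config()].
#' @export
study_stim_config <- function(config_id, amplitude_mA) {
  pair <- switch(config_id,
                 "therapeutic-pair" = c(2, 3),
                 "nontherapeutic-pair-1" = c(1, 2),
                 "nontherapeutic-pair-2" = c(3, 4),
                 "nontherapeutic-pair-3" = c(1, 2))
  stimulation_config("lead", pair[1], pair[2], amplitude_mA,
                     therapeutic = config_id == "therapeutic-pair")
}

#' Generate a complete synthetic study on disk
#'
#' Writes a BIDS-like layout: per-subject/run BOLD NIfTI, confounds-input
#' TSV (motion parameters) and JSON metadata; the atlas NIfTI + lookup TSV;
#' per-subject electrode JSON and a TCK tractogram; and a manifest with MD5
#' checksums. Everything is a pure function of the configuration (and its
#' master seed).
#'
#' @param config A [study_config()].
#' @param out_dir Destination directory (created if missing).
#' @return Invisibly, the manifest as a data frame (`file`, `md5`).
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)

  atlas <- make_atlas(config$n_parcels, config$network_sizes,
                      config$grid_shape, config$voxel_size_mm,
                      seed = config$seed)
  dir.create(file.path(out_dir, "atlas"), showWarnings = FALSE)
  write_atlas(atlas, file.path(out_dir, "atlas", "atlas.nii.gz"),
              file.path(out_dir, "atlas", "parcels.tsv"))

  design <- cycling_design(config$tr_s,
                           config$run_length_s / config$tr_s,
                           config$cycle_s, config$ramp_s)
  runs <- study_run_table(config)

  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    sdir <- file.path(out_dir, r$subject, "func")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_run(design, atlas, config$effect_profile, config$noise,
                        seed = r$seed,
                        condition = if (r$therapeutic) "therapeutic" else
                          "nontherapeutic")
    stem <- sprintf("%s_run-%02d", r$subject, r$run)
    write_volume(sim$bold, atlas$affine,
                 file.path(sdir, paste0(stem, "_bold.nii.gz")))
    utils::write.table(sim$motion,
                       file.path(sdir, paste0(stem, "_motion.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(subject = r$subject, run = r$run, therapeutic = r$therapeutic,
           responder = r$responder, config_id = r$config_id,
           amplitude_mA = config$amplitude_mA, tr_s = config$tr_s,
           cycle_s = config$cycle_s, ramp_s = config$ramp_s,
           seed = r$seed),
      file.path(sdir, paste0(stem, "_meta.json")), auto_unbox = TRUE)
  }

  for (s in seq_len(config$n_subjects)) {
    sub <- sprintf("sub-%02d", s)
    sdir <- file.path(out_dir, sub)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    elec <- .study_electrode(config, s)
    jsonlite::write_json(
      list(lead_id = elec$lead_id, hemisphere = elec$hemisphere,
           contacts = elec$contacts, spacing_mm = 2),
      file.path(sdir, "electrodes.json"), auto_unbox = TRUE, digits = NA)
    streams <- .subject_tractogram(config, atlas, elec, s)
    write_tck(streams, file.path(sdir, paste0(sub, "_tracks.tck")))
  }

  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- files[files != "manifest.tsv"]
  manifest <- data.frame(file = files,
                         md5 = as.character(
                           tools::md5sum(file.path(out_dir, files))))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# One tractogram per subject: streams for each configuration the subject
# uses, drawn around that configuration's VAT with condition-specific
# destination weights.
.subject_tractogram <- function(config, atlas, elec, subject_idx) {
  runs <- study_run_table(config)
  cfg_ids <- unique(runs$config_id[runs$subject ==
                                     sprintf("sub-%02d", subject_idx)])
  if (length(cfg_ids) == 0) cfg_ids <- "nontherapeutic-pair-1"
  n_each <- ceiling(config$n_streamlines / length(cfg_ids))
  sets <- lapply(seq_along(cfg_ids), function(ci) {
    stim <- study_stim_config(cfg_ids[ci], config$amplitude_mA)
    vat <- estimate_vat(elec, stim)
    w <- if (stim$therapeutic) config$therapeutic_weights else
      config$nontherapeutic_weights
    simulate_streamlines(n_each, atlas, vat, w,
                         seed = config$seed * 1000L + subject_idx * 37L +
                           ci)
  })
  streamline_set(do.call(c, lapply(sets, `[[`, "lines")))
}

#' Validate a study directory
#'
#' Checks grid/affine agreement between BOLD runs and the atlas, presence
#' of motion and metadata files, and completeness of the run labels.
#'
#' @param study_dir Directory written by [generate_study()].
#' @return Data frame of failures (`file`, `problem`); empty when intact.
#' @export
validate_inputs <- function(study_dir) {
  fail <- list()
  note <- function(f, p) fail[[length(fail) + 1]] <<-
    data.frame(file = f, problem = p)
  atlas_nii <- file.path(study_dir, "atlas", "atlas.nii.gz")
  atlas_tsv <- file.path(study_dir, "atlas", "parcels.tsv")
  if (!file.exists(atlas_nii)) note(atlas_nii, "missing atlas volume")
  if (!file.exists(atlas_tsv)) note(atlas_tsv, "missing parcel lookup")
  ref_dim <- NULL; ref_aff <- NULL
  if (file.exists(atlas_nii)) {
    img <- RNifti::readNifti(atlas_nii)
    ref_dim <- dim(img)
    ref_aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  }
  bolds <- list.files(study_dir, pattern = "_bold\\.nii(\\.gz)?$",
                      recursive = TRUE, full.names = TRUE)
  for (b in bolds) {
    img <- RNifti::readNifti(b)
    if (!is.null(ref_dim) && !identical(dim(img)[1:3], ref_dim)) {
      note(b, "grid mismatch with atlas")
    }
    if (!is.null(ref_aff)) {
      aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
      if (max(abs(aff - ref_aff)) > 1e-4) note(b, "affine mismatch with atlas")
    }
    stem <- sub("_bold\\.nii(\\.gz)?$", "", b)
    if (!file.exists(paste0(stem, "_motion.tsv"))) {
      note(b, "missing motion parameters")
    }
    meta_f <- paste0(stem, "_meta.json")
    if (!file.exists(meta_f)) {
      note(b, "missing run metadata")
    } else {
      meta <- jsonlite::read_json(meta_f)
      for (key in c("therapeutic", "responder", "subject", "run")) {
        if (is.null(meta[[key]])) note(meta_f, paste("missing", key, "flag"))
      }
    }
  }
  if (length(fail) == 0) {
    data.frame(file = character(0), problem = character(0))
  } else {
    do.call(rbind, fail)
  }
}
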