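#' Configuration for a full cross-modal run
#'
#' Bundles every knob of the study-shaped pipeline: the data source (a
#' `simulate` block or a file manifest), smoothing, permutation and FDR
#' settings, and the output directory. The pipeline is a pure function of
#' this configuration plus the seed.
#'
#' @param simulate list of arguments forwarded to [simulate_study()] (use
#'   `NULL` when supplying files).
#' @param manifest data.frame with columns `subject`, `channel`, `path`
#'   (per-subject 4D NIfTI), or `NULL` when simulating.
#' @param mask_path,parcellation_path,centroids_path file inputs used with a
#'   manifest.
#' @param hp_channels,pet_channels channel names per modality.
#' @param fwhm_mm kernel width applied to the PET-block group maps
#'   (default 14 mm).
#' @param fwhm_grid optional candidate FWHMs; when given, the width is chosen
#'   empirically with [optimize_fwhm()] and `fwhm_mm` is ignored.
#' @param n_perm spin permutations (default 10000).
#' @param alpha FDR level (default 0.05).
#' @param seed master seed.
#' @param out_dir optional output directory; when `NULL` results are only
#'   returned.
#' @param vascular_correct regress CBV out of CMRO2 before use (default
#'   `TRUE`).
#' @param residuals_per_subject compute residual maps per subject and then
#'   take group medians (default `TRUE`); `FALSE` residualizes the group
#'   median maps instead.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(simulate = list(), manifest = NULL,
                       mask_path = NULL, parcellation_path = NULL,
                       centroids_path = NULL,
                       hp_channels = c("pyruvate", "lactate", "bicarbonate"),
                       pet_channels = c("cmrglc", "cbf", "cmro2", "cbv"),
                       fwhm_mm = 14, fwhm_grid = NULL,
                       n_perm = 10000L, alpha = 0.05, seed = 1L,
                       out_dir = NULL, vascular_correct = TRUE,
                       residuals_per_subject = TRUE) {
  if (is.null(simulate) && is.null(manifest))
    stop("either a simulate block or a manifest is required")
  if (!is.null(manifest)) {
    need <- c("subject", "channel", "path")
    if (!all(need %in% names(manifest)))
      stop("manifest needs columns subject, channel, path")
    missing_files <- c(manifest$path, mask_path, parcellation_path,
                       centroids_path)
    missing_files <- missing_files[!file.exists(missing_files)]
    if (length(missing_files))
      stop("missing input files: ", paste(missing_files, collapse = ", "))
  }
  if (fwhm_mm < 0 || n_perm < 100L || alpha <= 0 || alpha >= 1)
    stop("invalid numeric configuration")
  structure(list(simulate = simulate, manifest = manifest,
                 mask_path = mask_path,
                 parcellation_path = parcellation_path,
                 centroids_path = centroids_path,
                 hp_channels = hp_channels, pet_channels = pet_channels,
                 fwhm_mm = fwhm_mm, fwhm_grid = fwhm_grid,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir,
                 vascular_correct = vascular_correct,
                 residuals_per_subject = residuals_per_subject),
            class = "run_config")
}

load_study_inputs <- function(config) {
  if (!is.null(config$manifest)) {
    mask_in <- read_nifti(config$mask_path)
    mask <- mask_in$values > 0
    vox <- mask_in$voxel_size_mm
    lab <- read_nifti(config$parcellation_path)$values
    cent <- read_centroids_csv(config$centroids_path)
    parc <- parcellation(array(as.integer(round(lab)), dim(lab)), cent,
                         parcel_ids = as.integer(rownames(cent)))
    subs <- split(config$manifest, config$manifest$subject)
    subjects <- lapply(subs, function(df) {
      out <- lapply(seq_len(nrow(df)), function(i) {
        nii <- read_nifti(df$path[i])
        d <- dim(nii$values)
        dt <- if (is.finite(nii$frame_interval_s) && nii$frame_interval_s > 0)
          nii$frame_interval_s else 1
        frames <- lapply(seq_len(d[4L]), function(f)
          volume_map(nii$values[, , , f], vox))
        dynamic_series(frames, (seq_len(d[4L]) - 1L) * dt)
      })
      stats::setNames(out, df$channel)
    })
    list(subjects = subjects, mask = mask, parc = parc)
  } else {
    args <- config$simulate
    args <- args[!vapply(args, is.null, logical(1))]   # YAML nulls
    if (!is.null(args$n_subjects)) {                   # CLI convenience
      if (is.null(args$mixing))
        args$mixing <- mixing_spec(n_subjects = args$n_subjects)
      args$n_subjects <- NULL
    }
    args$seed <- config$seed
    study <- do.call(simulate_study, args)
    list(subjects = study$subjects, mask = study$mask, parc = study$parc)
  }
}

derive_residual_set <- function(maps, mask, vascular_correct) {
  out <- maps
  if (vascular_correct && all(c("cmro2", "cbv") %in% names(maps)))
    out$cmro2 <- remove_vascular_component(maps$cmro2, maps$cbv, mask)
  if (all(c("lactate", "bicarbonate") %in% names(maps)))
    out$lbr <- spatial_regress_out(maps$lactate, maps$bicarbonate, mask,
                                   "lactate", "bicarbonate")$map
  if (all(c("lactate", "pyruvate") %in% names(maps)))
    out$lpr <- spatial_regress_out(maps$lactate, maps$pyruvate, mask,
                                   "lactate", "pyruvate")$map
  if (all(c("bicarbonate", "pyruvate") %in% names(maps)))
    out$bpr <- spatial_regress_out(maps$bicarbonate, maps$pyruvate, mask,
                                   "bicarbonate", "pyruvate")$map
  if (all(c("cmrglc", "cmro2") %in% names(maps)))
    out$gi <- compute_gi(out$cmrglc, out$cmro2, mask)$map
  out
}

all_pairs <- function(a, b = NULL) {
  if (is.null(b)) {
    cmb <- utils::combn(a, 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  } else {
    as.matrix(expand.grid(map_a = a, map_b = b, stringsAsFactors = FALSE))
  }
}

#' Run the full study-shaped pipeline
#'
#' Executes, in order: per-subject temporal integration into sum images,
#' whole-brain-mean normalization, per-subject residual maps (LBR, LPR, BPR,
#' GI; CBV regressed out of CMRO2 first when configured), voxelwise group
#' medians, Gaussian smoothing of the PET-block group maps (fixed 14 mm or
#' empirically optimized over `fwhm_grid`), within- and between-modality
#' Spearman correlation matrices with spin-permutation p-values and
#' Benjamini-Hochberg flags (one FDR family per matrix), and a two-component
#' canonical-mode PLS of the two blocks. When `config$out_dir` is set,
#' writes `correlations.csv`, `pls_weights.csv`, `pls_score_correlations.csv`,
#' group map and score NIfTIs, and `provenance.json` (seed, settings, config
#' hash, package version).
#'
#' @param config a [run_config()].
#' @return list with `group_maps`, `correlations` (data.frame with a
#'   `family` column), `fwhm_used`, `pls` (normalized), `score_rho`,
#'   `parc`, `mask`, `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  inputs <- stage("load", load_study_inputs(config))
  mask <- inputs$mask; parc <- inputs$parc

  subject_maps <- stage("sum+normalize", lapply(inputs$subjects, function(ch) {
    lapply(ch, function(ser)
      normalize_global_mean(sum_image(ser), mask))
  }))

  if (config$residuals_per_subject) {
    subject_maps <- stage("derive", lapply(subject_maps, derive_residual_set,
                                           mask = mask,
                                           vascular_correct =
                                             config$vascular_correct))
  }
  channels <- names(subject_maps[[1L]])
  group_maps <- stage("group-median", lapply(
    stats::setNames(channels, channels), function(ch)
      group_median(lapply(subject_maps, `[[`, ch))))
  if (!config$residuals_per_subject)
    group_maps <- stage("derive", derive_residual_set(
      group_maps, mask, config$vascular_correct))

  hp_set <- intersect(c(config$hp_channels, "lbr", "lpr", "bpr"),
                      names(group_maps))
  pet_set <- intersect(c(config$pet_channels, "gi", "oef"),
                       names(group_maps))

  fwhm_used <- config$fwhm_mm
  if (!is.null(config$fwhm_grid)) {
    pr <- all_pairs(hp_set, pet_set)
    fwhm_used <- stage("optimize-fwhm", optimize_fwhm(
      group_maps[pr[, 1L]], group_maps[pr[, 2L]], mask, config$fwhm_grid))
  }
  group_maps[pet_set] <- stage("smooth", lapply(
    group_maps[pet_set], gaussian_smooth, fwhm_mm = fwhm_used, mask = mask))

  fam <- list(hp_hp = all_pairs(hp_set),
              pet_pet = all_pairs(pet_set),
              hp_pet = all_pairs(hp_set, pet_set))
  correlations <- stage("correlate", do.call(rbind, lapply(
    names(fam), function(f) {
      df <- correlate_pairs(group_maps, fam[[f]], mask, parc,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed)
      df$family <- f
      df
    })))

  X <- stack_channels(group_maps, mask, hp_set)
  Y <- stack_channels(group_maps, mask, pet_set)
  pls <- stage("pls", normalize_scores(fit_pls(X, Y, n_components = 2L)))
  score_rho <- score_correlations(pls)

  provenance <- list(
    package = "crossmodal",
    version = as.character(utils::packageVersion("crossmodal")),
    seed = config$seed, n_perm = config$n_perm, alpha = config$alpha,
    fwhm_mm = fwhm_used, hp_channels = hp_set, pet_channels = pet_set,
    n_subjects = length(subject_maps),
    # hash the scientific configuration only: where the outputs land must
    # not change what they contain
    config_hash = digest::digest(unclass(config)[setdiff(names(config),
                                                         "out_dir")]))

  result <- list(group_maps = group_maps, correlations = correlations,
                 fwhm_used = fwhm_used, pls = pls, score_rho = score_rho,
                 parc = parc, mask = mask, provenance = provenance)
  if (!is.null(config$out_dir)) stage("write", write_results(result, config))
  result
}

write_results <- function(result, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cors <- result$correlations
  cors$config_hash <- result$provenance$config_hash
  utils::write.csv(cors, file.path(out, "correlations.csv"),
                   row.names = FALSE)
  pls <- result$pls
  wdf <- rbind(
    data.frame(component = rep(seq_len(pls$n_components),
                               each = nrow(pls$weights_x)),
               block = "hp", channel = rownames(pls$weights_x),
               weight = as.vector(pls$weights_x)),
    data.frame(component = rep(seq_len(pls$n_components),
                               each = nrow(pls$weights_y)),
               block = "pet", channel = rownames(pls$weights_y),
               weight = as.vector(pls$weights_y)))
  wdf$config_hash <- result$provenance$config_hash
  utils::write.csv(wdf, file.path(out, "pls_weights.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(component = seq_along(result$score_rho),
               rho = result$score_rho,
               config_hash = result$provenance$config_hash),
    file.path(out, "pls_score_correlations.csv"), row.names = FALSE)
  vox <- result$group_maps[[1L]]$voxel_size_mm
  for (ch in names(result$group_maps))
    write_nifti(result$group_maps[[ch]]$values,
                file.path(out, sprintf("group_%s.nii.gz", ch)), vox)
  m <- result$mask
  for (k in seq_len(pls$n_components)) {
    for (blk in c("x", "y")) {
      a <- array(0, dim(m))
      a[m] <- pls[[paste0("scores_", blk)]][, k]
      write_nifti(a, file.path(out, sprintf("scores_%s_c%d.nii.gz",
                                            if (blk == "x") "hp" else "pet",
                                            k)), vox)
    }
  }
  jsonlite::write_json(result$provenance,
                       file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
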