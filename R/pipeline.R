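#' Study configuration
#'
#' Bundles everything one variability study needs: the phantom parameters
#' and grid spacing, the degradation applied to emulate clinical image
#' quality, the workflow profiles to compare, the regions of interest, and
#' the metric/statistics settings.
#'
#' @param params a [phantom_params()].
#' @param spacing phantom voxel spacing, mm.
#' @param degrade_psf_fwhm_mm,degrade_noise_sd acquisition degradation:
#'   Gaussian blur FWHM (mm) and additive noise SD (HU).
#' @param profiles list of >= 2 [workflow_profile()]s.
#' @param rois subset of `c("mandible", "tumor", "nerve_right",
#'   "nerve_left")`.
#' @param overlap_pitch voxelization pitch for agreement/disagreement, mm.
#' @param deviation_samples extra surface sample density for deviation
#'   fields, per mm^2.
#' @param tumor_planes number of parallel datum planes through the tumor.
#' @param nerve_planes number of nerve slices for the centroid analysis.
#' @param alpha significance level of the ANOVA/Tukey comparisons.
#' @return A list of class `segqa_config`.
#' @export
study_config <- function(params = phantom_params(),
                         spacing = c(0.5, 0.5, 0.5),
                         degrade_psf_fwhm_mm = 1,
                         degrade_noise_sd = 5,
                         profiles = default_profiles()[1:2],
                         rois = c("mandible", "tumor", "nerve_right"),
                         overlap_pitch = 0.4,
                         deviation_samples = 0.25,
                         tumor_planes = 5,
                         nerve_planes = 7,
                         alpha = 0.05) {
  if (length(profiles) < 2) stop("need at least 2 workflow profiles")
  rois <- match.arg(rois, c("mandible", "tumor", "nerve_right", "nerve_left"),
                    several.ok = TRUE)
  structure(as.list(environment()), class = "segqa_config")
}

#' Read a study configuration from YAML
#'
#' Maps a YAML document onto [study_config()]: top-level keys mirror the
#' `study_config()` arguments; `params` maps onto [phantom_params()] and
#' `profiles` is a list of [workflow_profile()] argument sets.
#'
#' @param path YAML file path.
#' @return A `segqa_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$params)) {
    pp <- y$params
    if (!is.null(pp$hu)) pp$hu <- unlist(pp$hu)
    if (!is.null(pp$tumor_radii)) pp$tumor_radii <- as.numeric(pp$tumor_radii)
    args$params <- do.call(phantom_params, pp)
  }
  if (!is.null(y$profiles))
    args$profiles <- lapply(y$profiles, function(p) do.call(workflow_profile, p))
  for (key in c("spacing", "degrade_psf_fwhm_mm", "degrade_noise_sd", "rois",
                "overlap_pitch", "deviation_samples", "tumor_planes",
                "nerve_planes", "alpha"))
    if (!is.null(y[[key]])) args[[key]] <- unlist(y[[key]])
  do.call(study_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

segment_roi <- function(volume, phantom, profile, roi) {
  if (roi == "mandible") {
    m <- threshold_mask(volume, profile$hu_min, profile$hu_max)
    apply_morphology(m, profile$morphology)
  } else if (roi == "tumor") {
    w <- profile$tumor_window
    m <- if (isTRUE(profile$region_grow$enabled)) {
      cen <- phantom$truth_landmarks["tumor_center", ]
      seed_idx <- round((cen - volume$origin) / volume$spacing) + 1
      region_grow(volume, matrix(seed_idx, ncol = 3), w[1], w[2],
                  profile$region_grow$connectivity %||% 26)
    } else threshold_mask(volume, w[1], w[2])
    apply_morphology(m, list(list(op = "erode", radius = 1), "keep_largest",
                             list(op = "dilate", radius = 1)))
  } else {  # nerves: painted slices + shape-based interpolation
    truth <- phantom$truth_masks[[roi]]
    zs <- which(apply(truth$data, 3, any))
    painted <- zs[seq(1, length(zs), by = profile$nerve_stride)]
    if (painted[length(painted)] != zs[length(zs)])
      painted <- c(painted, zs[length(zs)])
    sparse <- truth$data
    sparse[, , setdiff(seq_len(dim(sparse)[3]), painted)] <- FALSE
    interpolate_slices(binary_mask(sparse, truth$spacing, truth$origin),
                       painted)
  }
}

#' Run the full workflow-variability study
#'
#' Executes the digital pipeline end to end: phantom generation,
#' acquisition degradation, per-profile segmentation of each ROI, surface
#' extraction, the three smoothing levels, and the comparison metrics with
#' ANOVA/Tukey statistics.  Everything is deterministic under a fixed seed.
#'
#' The comparison design mirrors the study setup: each profile contributes
#' three models per ROI (smoothing levels 0/1/2); volume and area are
#' averaged across levels within a profile, the three level values serving
#' as that profile's observations in the ANOVA; overlap matrices are
#' computed across all mandible/tumor models; nerve paths are compared via
#' per-slice centroids of the level-1 models.
#'
#' @param config a [study_config()].
#' @param seed integer seed driving the noise and surface sampling.
#' @param out_dir optional directory; when given, volumes/masks (NRRD),
#'   meshes (STL), tables (CSV), and a JSON manifest are written.  Partial
#'   outputs are retained if a later stage fails.
#' @return A list of class `segqa_study`; see [summary.segqa_study()].
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "segqa_config"))
  seed <- as.integer(seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(writer, x, file) {
    if (!is.null(out_dir)) writer(x, file.path(out_dir, file))
    invisible(NULL)
  }

  phantom <- stage("phantom", {
    grid <- default_phantom_grid(config$params, config$spacing)
    make_mandible_phantom(config$params, grid, seed = seed)
  })
  emit(write_nrrd, phantom$volume, "phantom_volume.nrrd")

  degraded <- stage("degrade",
    degrade(phantom$volume, config$degrade_psf_fwhm_mm,
            config$degrade_noise_sd, seed = seed))
  emit(write_nrrd, degraded, "degraded_volume.nrrd")

  profiles <- config$profiles
  pnames <- vapply(profiles, `[[`, "", "name")
  rois <- config$rois

  masks <- stage("segmentation", {
    res <- list()
    for (p in seq_along(profiles)) for (roi in rois) {
      m <- segment_roi(degraded, phantom, profiles[[p]], roi)
      res[[paste(pnames[p], roi, sep = ".")]] <- m
      emit(write_nrrd, m, sprintf("mask_%s_%s.nrrd", pnames[p], roi))
    }
    res
  })

  meshes <- stage("meshing+refinement", {
    res <- list()
    for (p in seq_along(profiles)) for (roi in rois) {
      base <- extract_surface(masks[[paste(pnames[p], roi, sep = ".")]])
      for (lev in 0:2) {
        mm <- apply_smoothing_level(base, profiles[[p]], lev)
        key <- sprintf("%s.%s.s%d", pnames[p], roi, lev)
        res[[key]] <- mm
        emit(function(x, f) write_stl(x, f), mm,
             sprintf("model_%s_%s_s%d.stl", pnames[p], roi, lev))
      }
    }
    res
  })

  measurements <- stage("global metrics", {
    rows <- list()
    for (key in names(meshes)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      m <- meshes[[key]]
      rows[[key]] <- data.frame(
        profile = parts[1], roi = parts[2],
        level = as.integer(sub("s", "", parts[3])),
        volume_mm3 = mesh_volume(m), area_mm2 = mesh_area(m),
        n_faces = nrow(m$faces))
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  })

  overlaps <- stage("overlap matrices", {
    res <- list()
    for (roi in intersect(rois, c("mandible", "tumor"))) {
      keys <- names(meshes)[grepl(paste0("\\.", roi, "\\.s"), names(meshes))]
      mm <- meshes[keys]
      names(mm) <- sub(paste0(".", roi), "", keys, fixed = TRUE)
      res[[roi]] <- overlap_matrix(mm, pitch = config$overlap_pitch)
    }
    res
  })

  # within-profile (across smoothing levels) vs between-profile disagreement
  profile_of <- function(nm) sub("\\.s[0-2]$", "", nm)
  split_disagreement <- function(mat) {
    nm <- rownames(mat)
    within <- c(); between <- c()
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (j <= i) next
      if (profile_of(nm[i]) == profile_of(nm[j]))
        within <- c(within, mat[i, j])
      else between <- c(between, mat[i, j])
    }
    c(within = mean(within), between = mean(between))
  }
  disagreement_split <- lapply(overlaps, function(o)
    split_disagreement(o$disagreement))

  deviations <- stage("deviation fields", {
    res <- list()
    if ("mandible" %in% rois) {
      lvl1 <- names(meshes)[grepl("\\.mandible\\.s1$", names(meshes))]
      worst <- NULL; worst_pair <- NULL
      for (i in seq_along(lvl1)) for (j in seq_along(lvl1)) {
        if (j <= i) next
        dv <- deviation_field(meshes[[lvl1[i]]], meshes[[lvl1[j]]],
                              samples_per_mm2 = config$deviation_samples,
                              seed = seed)
        res[[paste(lvl1[i], lvl1[j], sep = " vs ")]] <- dv
        if (is.null(worst) || dv$hausdorff > worst$hausdorff) {
          worst <- dv; worst_pair <- c(lvl1[i], lvl1[j])
        }
      }
      if (!is.null(worst) && !is.null(out_dir)) {
        hm <- deviation_heatmap(meshes[[worst_pair[1]]], worst)
        write_ply(hm, file.path(out_dir, "worst_pair_heatmap.ply"))
      }
    }
    res
  })

  stats <- stage("statistics", {
    res <- list()
    for (roi in intersect(rois, c("mandible", "tumor"))) {
      sub <- measurements[measurements$roi == roi, ]
      vol_groups <- split(sub$volume_mm3, sub$profile)
      area_groups <- split(sub$area_mm2, sub$profile)
      res[[paste0(roi, "_volume")]] <-
        tryCatch(tukey_kramer(vol_groups, config$alpha), error = identity)
      res[[paste0(roi, "_area")]] <-
        tryCatch(tukey_kramer(area_groups, config$alpha), error = identity)
    }
    res
  })

  nerve <- stage("nerve path analysis", {
    res <- list()
    for (roi in intersect(rois, c("nerve_right", "nerve_left"))) {
      lvl1 <- names(meshes)[grepl(paste0("\\.", roi, "\\.s1$"), names(meshes))]
      if (length(lvl1) < 2) next
      # coronal planes (normal = y) at shared offsets over the common extent
      ys <- range(do.call(rbind, lapply(meshes[lvl1],
                                        function(m) m$vertices))[, 2])
      offs <- ys[1] + diff(ys) *
        seq_len(config$nerve_planes) / (config$nerve_planes + 1)
      traces <- lapply(lvl1, function(k)
        mesh_path_trace(meshes[[k]], profile_of(k), axis = c(0, 1, 0),
                        offsets = offs, side = roi))
      idx_common <- Reduce(intersect, lapply(traces, `[[`, "slice_index"))
      traces <- lapply(traces, function(tr) {
        keep <- tr$slice_index %in% idx_common
        path_trace(tr$model_id, tr$slice_index[keep],
                   tr$centroids[keep, , drop = FALSE], tr$side)
      })
      cmp <- nerve_path_compare(traces)
      cmp$tukey <- tryCatch(tukey_kramer(cmp$groups, config$alpha),
                            error = identity)
      res[[roi]] <- cmp
    }
    res
  })

  tumor_slices <- stage("tumor datum planes", {
    if (!"tumor" %in% rois) NULL else {
      lvl1 <- names(meshes)[grepl("\\.tumor\\.s1$", names(meshes))]
      zs <- range(do.call(rbind,
                          lapply(meshes[lvl1], function(m) m$vertices))[, 3])
      offs <- zs[1] + diff(zs) *
        seq_len(config$tumor_planes) / (config$tumor_planes + 1)
      rows <- list()
      for (k in lvl1) {
        sl <- slice_mesh(meshes[[k]], axis = c(0, 0, 1), offsets = offs)
        for (i in seq_along(sl)) {
          if (sl[[i]]$empty) next
          ce <- contour_centroid_extents(sl[[i]])
          rows[[paste(k, i)]] <- data.frame(
            profile = profile_of(k), plane = i,
            offset_mm = sl[[i]]$plane$offset,
            area_mm2 = sl[[i]]$total_area_mm2,
            cx = ce$centroid[1], cy = ce$centroid[2],
            ext_pu = ce$ext_pu, ext_mu = ce$ext_mu,
            ext_pv = ce$ext_pv, ext_mv = ce$ext_mv)
        }
      }
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      tab
    }
  })

  landmarks <- landmark_distance(phantom$truth_landmarks,
                                 phantom$caliper_pairs[, c("a", "b")])

  averaged <- stats::aggregate(cbind(volume_mm3, area_mm2) ~ profile + roi,
                               measurements, mean)

  study <- structure(list(
    config = config, seed = seed, phantom = phantom, degraded = degraded,
    masks = masks, meshes = meshes,
    measurements = measurements, averaged = averaged,
    overlaps = overlaps, disagreement_split = disagreement_split,
    deviations = deviations, stats = stats, nerve = nerve,
    tumor_slices = tumor_slices, landmarks = landmarks
  ), class = "segqa_study")

  if (!is.null(out_dir)) stage("reports", write_study_reports(study, out_dir))
  study
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

write_study_reports <- function(study, out_dir) {
  wcsv <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], fmt6)
    write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  wcsv(study$measurements, "measurements.csv")
  wcsv(study$averaged, "averaged_by_profile.csv")
  wcsv(study$landmarks, "landmark_calipers.csv")
  if (!is.null(study$tumor_slices)) wcsv(study$tumor_slices, "tumor_slices.csv")
  for (roi in names(study$overlaps)) {
    # percent tables rounded to the nearest percent; full precision in JSON
    ag <- round(study$overlaps[[roi]]$agreement)
    dg <- round(study$overlaps[[roi]]$disagreement)
    write.csv(ag, file.path(out_dir, sprintf("agreement_%s.csv", roi)))
    write.csv(dg, file.path(out_dir, sprintf("disagreement_%s.csv", roi)))
  }
  for (roi in names(study$nerve))
    wcsv(study$nerve[[roi]]$per_slice, sprintf("nerve_path_%s.csv", roi))
  manifest <- list(
    package = "segqa",
    package_version = as.character(utils::packageVersion("segqa")),
    r_version = R.version.string,
    seed = study$seed,
    spacing = study$config$spacing,
    profiles = lapply(study$config$profiles, function(p)
      p[c("name", "hu_min", "hu_max")]),
    rois = study$config$rois,
    overlap_pitch = study$config$overlap_pitch,
    overlaps = lapply(study$overlaps, function(o)
      list(agreement = fmt6(o$agreement), disagreement = fmt6(o$disagreement))),
    disagreement_split = lapply(study$disagreement_split, fmt6),
    anova = lapply(study$stats, function(s) {
      if (inherits(s, "segqa_tukey"))
        list(F = fmt6(s$anova$F), p = fmt6(s$anova$p), q_crit = fmt6(s$q_crit))
      else list(error = conditionMessage(s))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.segqa_study <- function(x, ...) {
  cat(sprintf(
    "<segqa_study> %d profiles x 3 smoothing levels, ROIs: %s, seed %d\n",
    length(x$config$profiles), paste(x$config$rois, collapse = ", "), x$seed))
  cat(sprintf("  %d models; overlap pitch %g mm\n", length(x$meshes),
              x$config$overlap_pitch))
  invisible(x)
}

#' Summarize a workflow-variability study
#'
#' Prints per-profile averaged dimensions, the within- vs between-profile
#' disagreement split, deviation summaries and the ANOVA/Tukey outcomes.
#'
#' @param object a `segqa_study` from [run_study()].
#' @param ... unused.
#' @return `object`, invisibly.
#' @export
summary.segqa_study <- function(object, ...) {
  print(object)
  cat("\nAveraged across smoothing levels per profile:\n")
  print(fmt6_df(object$averaged))
  for (roi in names(object$disagreement_split)) {
    sp <- object$disagreement_split[[roi]]
    cat(sprintf(
      "\n%s disagreement: within-profile %.2f%%, between-profile %.2f%%\n",
      roi, sp["within"], sp["between"]))
  }
  if (length(object$deviations)) {
    h <- vapply(object$deviations, `[[`, 0, "hausdorff")
    cat(sprintf("\nWorst pairwise Hausdorff deviation: %.3f mm (%s)\n",
                max(h), names(which.max(h))))
  }
  for (nm in names(object$stats)) {
    s <- object$stats[[nm]]
    if (inherits(s, "segqa_tukey"))
      cat(sprintf("%s: F = %.4g, p = %.4g, %d/%d significant pairs\n",
                  nm, s$anova$F, s$anova$p, sum(s$table$significant),
                  nrow(s$table)))
  }
  invisible(object)
}

fmt6_df <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt6)
  df
}

#' Write a phantom case to disk
#'
#' Volume and truth masks as NRRD, landmarks/parameters as JSON, truth
#' meshes as STL.
#'
#' @param phantom a `segqa_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "segqa_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nrrd(phantom$volume, file.path(dir, "volume.nrrd"))
  for (nm in names(phantom$truth_masks)) {
    write_nrrd(phantom$truth_masks[[nm]],
               file.path(dir, sprintf("truth_%s.nrrd", nm)))
    write_stl(extract_surface(phantom$truth_masks[[nm]]),
              file.path(dir, sprintf("truth_%s.stl", nm)))
  }
  jsonlite::write_json(list(
    landmarks = apply(phantom$truth_landmarks, 1, identity, simplify = FALSE),
    caliper_pairs = phantom$caliper_pairs,
    params = phantom$params[!vapply(phantom$params, is.null, TRUE)],
    seed = phantom$seed
  ), file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
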