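# Per-subject pipeline: validate -> classify -> voxel & parcel densities ->
# maps. tdrm() is the in-memory entry point; run_subject()/run_group() are
# the file-based runners used by the command-line interface.

#' Run the per-subject track-density ratio mapping pipeline
#'
#' Validates and classifies a track set against the tissue segmentation,
#' counts terminal densities per 1 mm^3 voxel (all-terminals mode, so the
#' subcortical terminals of projection fibers appear in the maps) and, when
#' a parcellation is supplied, per parcellation piece (cortex-only mode, as
#' in a cortex-restricted quantitative analysis).
#'
#' @param tracks a [track_set()] or path to a `.tck` file.
#' @param tissue a tissue [label_volume()] or path to a NIfTI file.
#' @param parcellation optional parcellation [label_volume()] or path.
#' @param lookup parcel lookup data.frame or TSV path (required with
#'   `parcellation`).
#' @param subject_id identifier carried through summaries.
#' @param length_threshold_mm short/long association split, default 60.
#' @return An object of class `tdrm`: list with `classification`, `summary`,
#'   `density` (a `tdrm_density`), `parcels` (a `tdrm_parcel_density` or
#'   NULL), `tracks`, `tissue`, `parcellation`, `lookup`, `params`.
#' @export
tdrm <- function(tracks, tissue, parcellation = NULL, lookup = NULL,
                 subject_id = "subject", length_threshold_mm = 60) {
  if (is.character(tracks)) tracks <- read_tck(tracks)
  if (is.character(tissue)) tissue <- read_label_volume(tissue, "tissue")
  if (is.character(parcellation))
    parcellation <- read_label_volume(parcellation, "parcellation")
  if (is.character(lookup)) lookup <- read_parcel_lookup(lookup)
  if (!is.null(parcellation) && is.null(lookup))
    stop("`lookup` is required when a parcellation is supplied", call. = FALSE)

  cl <- classify_tracks(tracks, tissue,
                        length_threshold_mm = length_threshold_mm)
  dens <- voxel_density(cl, tracks, tissue)
  parcels <- if (!is.null(parcellation))
    parcel_density(cl, tracks, parcellation, lookup, cortical_only = TRUE)
  structure(list(classification = cl,
                 summary = summary(cl, subject_id = subject_id),
                 density = dens, parcels = parcels,
                 tracks = tracks, tissue = tissue,
                 parcellation = parcellation, lookup = lookup,
                 params = list(length_threshold_mm = length_threshold_mm)),
            class = "tdrm")
}

#' @export
print.tdrm <- function(x, ...) {
  cat("Track-density ratio mapping result\n")
  print(x$summary)
  if (!is.null(x$parcels))
    cat(sprintf("  parcel table: %d parcels, %d cortical terminals assigned\n",
                sum(x$parcels$label > 0L),
                sum(x$parcels$tracks_total[x$parcels$label > 0L])))
  invisible(x)
}

#' @export
summary.tdrm <- function(object, ...) object$summary

#' Plot a track-density ratio map view
#'
#' Composes the voxel RGB map (k = 30) and draws a slice-stacked projection.
#'
#' @param x a `tdrm` object.
#' @param view projection view, default `"superior"`.
#' @param k contrast constant, default 30.
#' @param ... unused.
#' @export
plot.tdrm <- function(x, view = "superior", k = 30, ...) {
  plot(stack_projection(compose_rgb(x$density, k = k), view))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Collects the paths and parameters of a run. Parameter defaults are the
#' published ones: 60 mm association split, k = 30 / 8 / 2 intensity
#' constants for voxel RGB / parcel RGB / grayscale maps.
#'
#' @param tracks,tissue,parcellation,lookup input paths.
#' @param out_dir output directory.
#' @param subject_id subject identifier.
#' @param length_threshold_mm association length split (mm).
#' @param k_voxel,k_parcel,k_gray intensity constants.
#' @param dmax_mode `"global"` or `"per_channel"`.
#' @param cortical_only_maps count only cortical terminals in the voxel maps.
#' @param outlier_k_mad MAD multiplier for the group outlier screen.
#' @param asymmetry_test `"t"` or `"wilcoxon"`.
#' @param seed RNG seed recorded with the run.
#' @return An object of class `tdrm_config` (a named list).
#' @export
tdrm_config <- function(tracks = NULL, tissue = NULL, parcellation = NULL,
                        lookup = NULL, out_dir = "tdrm_out",
                        subject_id = "subject",
                        length_threshold_mm = 60, k_voxel = 30, k_parcel = 8,
                        k_gray = 2, dmax_mode = "global",
                        cortical_only_maps = FALSE, outlier_k_mad = 3.5,
                        asymmetry_test = "t", seed = 1L) {
  structure(list(tracks = tracks, tissue = tissue,
                 parcellation = parcellation, lookup = lookup,
                 out_dir = out_dir, subject_id = subject_id,
                 length_threshold_mm = length_threshold_mm,
                 k_voxel = k_voxel, k_parcel = k_parcel, k_gray = k_gray,
                 dmax_mode = dmax_mode,
                 cortical_only_maps = cortical_only_maps,
                 outlier_k_mad = outlier_k_mad,
                 asymmetry_test = asymmetry_test, seed = as.integer(seed)),
            class = "tdrm_config")
}

#' Read a YAML run configuration
#' @param path YAML file whose keys match [tdrm_config()] arguments.
#' @return A `tdrm_config`.
#' @export
read_tdrm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tdrm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(tdrm_config, vals)
}

write_manifest <- function(dir, config, files) {
  paths <- file.path(dir, files)
  manifest <- list(package = "tdrm",
                   version = as.character(utils::packageVersion("tdrm")),
                   config = unclass(config),
                   files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                                   files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}

#' Run the full per-subject pipeline to disk
#'
#' Writes `classified.tsv`, `summary.json`, `density.nii.gz` (4D, one volume
#' per fiber class), `parcel_density.tsv`, PNG projections for all eight
#' views, and `manifest.json` recording the configuration and the md5 of
#' every artifact. Re-running with identical inputs is bit-identical.
#'
#' @param config a [tdrm_config()] with input paths set.
#' @return The `tdrm` result object, invisibly.
#' @export
run_subject <- function(config) {
  stopifnot(inherits(config, "tdrm_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  fit <- stage("classify", tdrm(config$tracks, config$tissue,
                                config$parcellation, config$lookup,
                                subject_id = config$subject_id,
                                length_threshold_mm = config$length_threshold_mm))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  stage("write-classification", {
    cl <- fit$classification
    utils::write.table(
      data.frame(index = cl$index, label_a = cl$label_a, label_b = cl$label_b,
                 length_mm = sprintf("%.6f", cl$length_mm),
                 class_or_rejection = ifelse(cl$status == "kept",
                                             cl$class, cl$status)),
      out("classified.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    s <- fit$summary
    jsonlite::write_json(list(subject_id = s$subject_id,
                              counts = as.list(s$counts),
                              fractions = as.list(s$fractions),
                              rejections = as.list(s$rejections),
                              total_validated = s$total_validated,
                              total_extracted = s$total_extracted,
                              exclusion_pct = s$exclusion_pct),
                         out("summary.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  dens <- if (config$cortical_only_maps)
    voxel_density(fit$classification, fit$tracks, fit$tissue,
                  cortical_only = TRUE) else fit$density
  stage("write-density", write_density_volume(dens, out("density.nii.gz")))

  files <- c("classified.tsv", "summary.json", "density.nii.gz")
  if (!is.null(fit$parcels)) {
    stage("write-parcels", utils::write.table(fit$parcels,
          out("parcel_density.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE))
    files <- c(files, "parcel_density.tsv")
  }

  rgbv <- stage("compose-rgb", compose_rgb(dens, k = config$k_voxel,
                                           dmax_mode = config$dmax_mode))
  for (v in PROJECTION_VIEWS) {
    f <- sprintf("view_%s.png", gsub("-", "_", v))
    stage(paste0("render-", v),
          write_projection_png(stack_projection(rgbv, v), out(f)))
    files <- c(files, f)
  }
  stage("manifest", write_manifest(config$out_dir, config, files))
  invisible(fit)
}

#' Run the group analysis over subject outputs
#'
#' @param tables list of `tdrm_parcel_density` tables, or paths to
#'   `parcel_density.tsv` files written by [run_subject()].
#' @param summaries optional list of `tdrm_summary` objects for the outlier
#'   screen (skipped when fewer than 3 are given).
#' @param out_dir output directory.
#' @param config a [tdrm_config()] providing `outlier_k_mad` and
#'   `asymmetry_test`.
#' @param density_volumes optional list of `tdrm_density` volumes on a
#'   common grid; their mean is written as `mean_density.nii.gz`.
#' @return list with `group` (a `tdrm_group`), `asymmetry` (per-class
#'   `tdrm_asymmetry` over all homotopic pairs), `outliers` (data.frame or
#'   NULL), invisibly.
#' @export
run_group <- function(tables, summaries = NULL, out_dir = "tdrm_group",
                      config = tdrm_config(), density_volumes = NULL) {
  if (is.character(tables)) tables <- lapply(tables, read_parcel_table)
  grp <- group_parcel_stats(tables)
  asym <- lapply(stats::setNames(nm = c(TDRM_CLASSES, "total_assoc", "total")),
                 function(cl) hemispheric_asymmetry(tables, class = cl,
                                                    test = config$asymmetry_test))
  outliers <- if (!is.null(summaries) && length(summaries) >= 3L)
    flag_outlier_subjects(summaries, k_mad = config$outlier_k_mad)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(grp$per_label, file.path(out_dir, "group_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(hemisphere_means = grp$hemisphere_means,
         asymmetry = lapply(asym, function(a)
           list(class = a$class, n = a$n, statistic = a$statistic,
                p_value = a$p_value, direction = a$direction,
                mean_diff = a$mean_diff, degenerate = a$degenerate,
                test = a$test))),
    file.path(out_dir, "asymmetry.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  if (!is.null(outliers))
    utils::write.table(outliers, file.path(out_dir, "flagged_subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(density_volumes))
    write_density_volume(average_density_volumes(density_volumes),
                         file.path(out_dir, "mean_density.nii.gz"))
  invisible(list(group = grp, asymmetry = asym, outliers = outliers))
}

#' Read back a parcel density TSV written by [run_subject()]
#' @param path path to `parcel_density.tsv`.
#' @return A `tdrm_parcel_density` data.frame.
#' @export
read_parcel_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("tdrm_parcel_density", "data.frame")
  df
}
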