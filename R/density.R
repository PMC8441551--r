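# Terminal counting. The track-density of a fiber class at a voxel is the
# number of that class's streamline terminals whose nearest voxel it is, on a
# 1 mm isotropic grid; per parcel it is tracks_amount / piece_volume.

#' Default 1 mm density grid covering a volume's bounding box
#'
#' If the reference volume is already on a 1 mm isotropic grid its own grid
#' is reused; otherwise a 1 mm axis-aligned grid covering the volume's world
#' bounding box is constructed.
#'
#' @param volume a [label_volume()].
#' @return list with `shape` (3 ints) and `affine` (4x4).
#' @export
density_grid <- function(volume) {
  sp <- voxel_spacing(volume$affine)
  if (all(abs(sp - 1) < 1e-9))
    return(list(shape = dim(volume$labels), affine = volume$affine))
  dm <- dim(volume$labels)
  corners <- as.matrix(expand.grid(c(-0.5, dm[1] - 0.5), c(-0.5, dm[2] - 0.5),
                                   c(-0.5, dm[3] - 0.5)))
  w <- corners %*% t(volume$affine[1:3, 1:3]) +
    matrix(volume$affine[1:3, 4], 8L, 3L, byrow = TRUE)
  lo <- apply(w, 2L, min); hi <- apply(w, 2L, max)
  if (any(hi - lo < 1)) stop("degenerate bounding box for density grid",
                             call. = FALSE)
  shape <- as.integer(ceiling(hi - lo))
  aff <- diag(4)
  aff[1:3, 4] <- lo + 0.5
  list(shape = shape, affine = aff)
}

#' Terminal density per 1 mm^3 voxel, per fiber class
#'
#' Counts, for each validated and classified streamline, its terminals into
#' a 4-channel volume (channel order projection, commissural, short_assoc,
#' long_assoc). By default all terminals are counted, so projection tracks
#' contribute their subcortical terminal too; `cortical_only = TRUE`
#' restricts counting to terminals whose tissue compartment is cortex.
#'
#' @param classified a `tdrm_classification` with classes filled.
#' @param tracks the `tdrm_tracks` the classification came from.
#' @param tissue tissue [label_volume()] (defines the default grid and the
#'   cortical filter).
#' @param grid optional grid from [density_grid()]; non-1 mm spacing draws a
#'   warning since track-density is defined per mm^3.
#' @param cortical_only count only cortex-labelled terminals.
#' @return An object of class `tdrm_density`: list with `counts` (4D array
#'   x,y,z,channel), `affine`, `channels`.
#' @export
voxel_density <- function(classified, tracks, tissue, grid = NULL,
                          cortical_only = FALSE) {
  stopifnot(inherits(classified, "tdrm_classification"),
            inherits(tracks, "tdrm_tracks"))
  if (is.null(grid)) grid <- density_grid(tissue)
  if (any(abs(voxel_spacing(grid$affine) - 1) > 1e-9))
    warning("density grid spacing is not 1 mm; track-density is defined per mm^3")

  kept <- classified$status == "kept" & !is.na(classified$class)
  tp <- terminal_points(tracks)
  pts <- rbind(tp$a[kept, , drop = FALSE], tp$b[kept, , drop = FALSE])
  cls <- factor(rep(classified$class[kept], 2L), levels = TDRM_CLASSES)
  if (cortical_only) {
    term_lab <- c(classified$label_a[kept], classified$label_b[kept])
    ok <- term_lab %in% c(TISSUE_CTX_L, TISSUE_CTX_R)
    pts <- pts[ok, , drop = FALSE]
    cls <- cls[ok]
  }

  counts <- array(0L, dim = c(grid$shape, 4L))
  if (nrow(pts) > 0L) {
    ijk <- voxel_index0(grid$affine, pts)
    dm <- grid$shape
    inside <- ijk[, 1L] >= 0L & ijk[, 1L] < dm[1L] &
              ijk[, 2L] >= 0L & ijk[, 2L] < dm[2L] &
              ijk[, 3L] >= 0L & ijk[, 3L] < dm[3L]
    nvox <- prod(dm)
    lin <- 1L + ijk[inside, 1L] + dm[1L] * (ijk[inside, 2L] + dm[2L] * ijk[inside, 3L]) +
      nvox * (as.integer(cls[inside]) - 1L)
    tab <- tabulate(lin, nbins = nvox * 4L)
    counts <- array(tab, dim = c(dm, 4L))
  }
  structure(list(counts = counts, affine = grid$affine, channels = TDRM_CLASSES),
            class = "tdrm_density")
}

#' @export
print.tdrm_density <- function(x, ...) {
  tot <- apply(x$counts, 4L, sum)
  cat(sprintf("Density volume %s, terminals per class: %s\n",
              paste(dim(x$counts)[1:3], collapse = "x"),
              paste(sprintf("%s=%d", x$channels, tot), collapse = ", ")))
  invisible(x)
}

#' Write a density volume as a 4D NIfTI (4th dimension = fiber class)
#' @param density a `tdrm_density`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_volume <- function(density, path) {
  img <- RNifti::asNifti(density$counts * 1.0)
  RNifti::qform(img) <- structure(density$affine, code = 2L)
  RNifti::sform(img) <- structure(density$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Per-parcel terminal counts and relative densities
#'
#' For every parcellation piece, counts the terminals of each fiber class
#' whose containing voxel carries the parcel label (`tracks_amount`),
#' measures the piece volume in mm^3 from the parcellation affine, and
#' reports the relative density `tracks_amount / piece_volume`. With
#' `cortical_only = TRUE` (the default, matching a cortex-only quantitative
#' analysis) only cortex-labelled terminals are tallied; terminals landing in
#' unlabelled voxels go to an `unassigned` row (label 0).
#'
#' @param classified a `tdrm_classification` with classes filled.
#' @param tracks the corresponding `tdrm_tracks`.
#' @param parcellation parcellation [label_volume()].
#' @param lookup parcel lookup data.frame.
#' @param cortical_only restrict to cortex-labelled terminals.
#' @return An object of class `tdrm_parcel_density`: data.frame with one row
#'   per parcel plus the unassigned row; columns `label`, `name`,
#'   `hemisphere`, `lobe_group`, `piece_volume_mm3`, `tracks_<class>`,
#'   `density_<class>`, `tracks_total`, `density_total`.
#' @export
parcel_density <- function(classified, tracks, parcellation, lookup,
                           cortical_only = TRUE) {
  stopifnot(inherits(classified, "tdrm_classification"),
            inherits(parcellation, "tdrm_labels"))
  lookup <- validate_parcel_lookup(lookup)
  kept <- classified$status == "kept" & !is.na(classified$class)
  tp <- terminal_points(tracks)
  pts <- rbind(tp$a[kept, , drop = FALSE], tp$b[kept, , drop = FALSE])
  cls <- factor(rep(classified$class[kept], 2L), levels = TDRM_CLASSES)
  if (cortical_only) {
    term_lab <- c(classified$label_a[kept], classified$label_b[kept])
    ok <- term_lab %in% c(TISSUE_CTX_L, TISSUE_CTX_R)
    pts <- pts[ok, , drop = FALSE]
    cls <- cls[ok]
  }
  parc_lab <- if (nrow(pts) > 0L) label_at(parcellation, pts) else integer()

  vox_mm3 <- prod(voxel_spacing(parcellation$affine))
  vol_tab <- table(factor(parcellation$labels[parcellation$labels > 0L],
                          levels = lookup$label))
  piece_vol <- as.numeric(vol_tab) * vox_mm3

  labels_all <- c(lookup$label, 0L)
  cnt <- matrix(0L, length(labels_all), 4L,
                dimnames = list(NULL, TDRM_CLASSES))
  if (length(parc_lab)) {
    lab_f <- factor(ifelse(parc_lab %in% lookup$label, parc_lab, 0L),
                    levels = labels_all)
    cnt <- as.matrix(table(lab_f, cls))
  }

  out <- data.frame(label = labels_all,
                    name = c(lookup$name, "unassigned"),
                    hemisphere = c(lookup$hemisphere, NA_character_),
                    lobe_group = c(lookup$lobe_group, NA_character_),
                    piece_volume_mm3 = c(piece_vol, NA_real_),
                    stringsAsFactors = FALSE)
  for (j in seq_along(TDRM_CLASSES)) {
    out[[paste0("tracks_", TDRM_CLASSES[j])]] <- as.integer(cnt[, j])
    out[[paste0("density_", TDRM_CLASSES[j])]] <- cnt[, j] / out$piece_volume_mm3
  }
  out$tracks_total <- as.integer(rowSums(cnt))
  out$density_total <- out$tracks_total / out$piece_volume_mm3
  empty <- !is.na(out$piece_volume_mm3) & out$piece_volume_mm3 == 0
  if (any(empty)) {
    warning("empty parcel(s): ", paste(out$label[empty], collapse = ", "))
    for (col in grep("^density_", names(out), value = TRUE))
      out[[col]][empty] <- NA_real_
  }
  class(out) <- c("tdrm_parcel_density", "data.frame")
  out
}

#' Histogram of per-voxel total terminal counts
#'
#' Tallies the distribution of per-voxel counts (the quantity whose
#' exponential-decay shape motivates the intensity transforms), per class
#' and in total. Zero-count voxels are excluded by default since background
#' dominates any brain volume.
#'
#' @param density a `tdrm_density`.
#' @param n_bins number of equal-width bins over `1..max(count)`; default
#'   one bin per integer count.
#' @param include_zero include the zero-count voxels as their own first bin.
#' @return data.frame with `bin_lo`, `bin_hi` (inclusive integer count
#'   range), one frequency column per class and `total`.
#' @export
density_histogram <- function(density, n_bins = NULL, include_zero = FALSE) {
  stopifnot(inherits(density, "tdrm_density"))
  tot <- apply(density$counts, 1:3, sum)
  mx <- max(tot)
  if (mx == 0L) {
    out <- data.frame(bin_lo = integer(), bin_hi = integer(),
                      total = integer())
    for (cl in density$channels) out[[cl]] <- integer()
    return(out)
  }
  if (is.null(n_bins)) n_bins <- mx
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  width <- ceiling(mx / n_bins)
  edges_lo <- 1L + width * (seq_len(n_bins) - 1L)
  edges_hi <- pmin(edges_lo + width - 1L, mx)
  keep <- edges_lo <= mx
  edges_lo <- edges_lo[keep]; edges_hi <- edges_hi[keep]

  bin_of <- function(v) pmin(((v - 1L) %/% width) + 1L, length(edges_lo))
  out <- data.frame(bin_lo = edges_lo, bin_hi = edges_hi)
  for (j in seq_along(density$channels)) {
    ch <- density$counts[, , , j]
    v <- ch[tot > 0L]
    v <- v[v > 0L]
    out[[density$channels[j]]] <- tabulate(bin_of(v), nbins = length(edges_lo))
  }
  out$total <- tabulate(bin_of(tot[tot > 0L]), nbins = length(edges_lo))
  if (include_zero) {
    zero <- data.frame(bin_lo = 0L, bin_hi = 0L)
    for (j in seq_along(density$channels))
      zero[[density$channels[j]]] <- sum(density$counts[, , , j] == 0L)
    zero$total <- sum(tot == 0L)
    out <- rbind(zero, out)
  }
  out
}
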