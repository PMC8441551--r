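# Rendering: densities become colors through the saturating exponential
# 1 - exp(-k * density / max_density). Presets: k = 30 for voxel RGB maps,
# k = 8 for parcel RGB maps, k = 2 for grayscale total maps. In the default
# fiber mode the channels are R = commissural, G = projection,
# B = short + long association; association mode splits the association
# classes over R = short, G = long.

#' Exponential intensity transform
#'
#' `1 - exp(-k * density / dmax)`: 0 at zero density, `1 - exp(-k)` at
#' `density = dmax`, strictly increasing, invariant under joint rescaling of
#' density and `dmax`.
#'
#' @param density nonnegative density value(s).
#' @param dmax positive normalising maximum density.
#' @param k positive contrast constant (30 voxel RGB, 8 parcel RGB,
#'   2 grayscale).
#' @return Values in `[0, 1)`.
#' @export
intensity_transform <- function(density, dmax, k) {
  if (!is.numeric(dmax) || length(dmax) != 1L || !is.finite(dmax) || dmax <= 0)
    stop("`dmax` must be a positive number (an all-zero map must be handled by the caller)",
         call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be positive", call. = FALSE)
  if (any(density < 0)) stop("densities must be nonnegative", call. = FALSE)
  1 - exp(-k * density / dmax)
}

rgb_assignment <- function(mode) {
  switch(mode,
    fiber = list(R = "commissural", G = "projection",
                 B = c("short_assoc", "long_assoc")),
    association = list(R = "short_assoc", G = "long_assoc", B = character()),
    stop("unknown RGB mode: ", mode, call. = FALSE))
}

channel_density <- function(counts, channels, wanted) {
  if (length(wanted) == 0L) return(array(0, dim(counts)[1:3]))
  idx <- match(wanted, channels)
  out <- counts[, , , idx[1L]]
  for (i in idx[-1L]) out <- out + counts[, , , i]
  out * 1.0
}

new_rgb_volume <- function(rgb, affine, assignment, total) {
  structure(list(rgb = rgb, affine = affine, assignment = assignment,
                 total = total),
            class = "tdrm_rgb")
}

#' @export
print.tdrm_rgb <- function(x, ...) {
  cat(sprintf("RGB volume %s, channels R=%s G=%s B=%s\n",
              paste(dim(x$rgb)[1:3], collapse = "x"),
              paste(x$assignment$R, collapse = "+"),
              paste(x$assignment$G, collapse = "+"),
              if (length(x$assignment$B)) paste(x$assignment$B, collapse = "+")
              else "none"))
  invisible(x)
}

#' Compose an RGB ratio volume from a density volume
#'
#' Each color channel is the intensity transform of its class density.
#' `dmax` is resolved globally over all channels and voxels by default,
#' which preserves cross-class comparability (a denser class is always the
#' brighter channel); `per_channel` normalises each channel by its own
#' maximum. In fiber mode the association channel sums the short and long
#' classes before the transform.
#'
#' @param density a `tdrm_density`.
#' @param k contrast constant; default 30 (voxel-based RGB maps).
#' @param dmax_mode `"global"` or `"per_channel"`.
#' @param mode `"fiber"` (R commissural, G projection, B association) or
#'   `"association"` (R short, G long).
#' @return A `tdrm_rgb` volume with channels in `[0, 1]`, the channel
#'   assignment record, and the pre-transform total density (used as the
#'   stacking exclusion criterion).
#' @export
compose_rgb <- function(density, k = 30, dmax_mode = c("global", "per_channel"),
                        mode = c("fiber", "association")) {
  stopifnot(inherits(density, "tdrm_density"))
  dmax_mode <- match.arg(dmax_mode)
  mode <- match.arg(mode)
  asg <- rgb_assignment(mode)
  dens <- lapply(asg, channel_density, counts = density$counts,
                 channels = density$channels)
  total <- apply(density$counts, 1:3, sum)
  rgb <- array(0, dim = c(dim(density$counts)[1:3], 3L))
  gmax <- max(vapply(dens, max, numeric(1)))
  if (gmax <= 0) {
    warning("all-zero density volume; returning an all-zero RGB volume")
    return(new_rgb_volume(rgb, density$affine, asg, total))
  }
  for (j in 1:3) {
    d <- dens[[j]]
    dmax <- if (dmax_mode == "global") gmax else max(d)
    if (dmax > 0) rgb[, , , j] <- intensity_transform(d, dmax, k)
  }
  new_rgb_volume(rgb, density$affine, asg, total)
}

#' Grayscale total density volume
#'
#' Total terminal count over the four classes pushed through the intensity
#' transform with `k = 2`, written to all three channels equally.
#'
#' @param density a `tdrm_density`.
#' @param k contrast constant, default 2.
#' @return A `tdrm_rgb` volume with R = G = B.
#' @export
grayscale_total <- function(density, k = 2) {
  stopifnot(inherits(density, "tdrm_density"))
  total <- apply(density$counts, 1:3, sum)
  rgb <- array(0, dim = c(dim(total), 3L))
  asg <- list(R = "total", G = "total", B = "total")
  if (max(total) <= 0) {
    warning("all-zero density volume; returning an all-zero RGB volume")
    return(new_rgb_volume(rgb, density$affine, asg, total))
  }
  g <- intensity_transform(total * 1.0, max(total), k)
  for (j in 1:3) rgb[, , , j] <- g
  new_rgb_volume(rgb, density$affine, asg, total)
}

#' Paint parcel-level densities back into the volume
#'
#' Every voxel of a parcel is painted with the parcel's class relative
#' densities pushed through the intensity transform (default `k = 8`,
#' `dmax` = the maximum relative density over parcels, global across
#' channels by default). Parcels present in the table but missing from the
#' volume draw a warning and stay black.
#'
#' @param table a `tdrm_parcel_density`.
#' @param parcellation parcellation [label_volume()].
#' @param k contrast constant, default 8.
#' @param dmax_mode `"global"` or `"per_channel"`.
#' @param mode `"fiber"` or `"association"` (see [compose_rgb()]).
#' @return A `tdrm_rgb` volume; `total` holds the per-voxel total relative
#'   density of its parcel.
#' @export
render_parcel_map <- function(table, parcellation, k = 8,
                              dmax_mode = c("global", "per_channel"),
                              mode = c("fiber", "association")) {
  stopifnot(inherits(table, "tdrm_parcel_density"),
            inherits(parcellation, "tdrm_labels"))
  dmax_mode <- match.arg(dmax_mode)
  mode <- match.arg(mode)
  asg <- rgb_assignment(mode)
  tab <- table[table$label > 0L, , drop = FALSE]
  present <- tab$label %in% parcellation$labels
  if (any(!present))
    warning("parcel label(s) missing from the volume: ",
            paste(tab$label[!present], collapse = ", "))

  dens_parcel <- vapply(asg, function(wanted) {
    if (length(wanted) == 0L) return(rep(0, nrow(tab)))
    d <- rep(0, nrow(tab))
    for (w in wanted) d <- d + tab[[paste0("density_", w)]]
    d
  }, numeric(nrow(tab)))
  dens_parcel <- matrix(dens_parcel, nrow = nrow(tab), ncol = 3L)
  dens_parcel[is.na(dens_parcel)] <- 0

  dm <- dim(parcellation$labels)
  rgb <- array(0, dim = c(dm, 3L))
  total <- array(0, dim = dm)
  pos <- match(as.vector(parcellation$labels), tab$label)  # NA for 0/unknown
  hit <- !is.na(pos)
  tot_parcel <- rowSums(dens_parcel)
  total[hit] <- tot_parcel[pos[hit]]
  gmax <- max(dens_parcel)
  if (gmax <= 0) {
    warning("all-zero parcel densities; returning an all-zero RGB volume")
    return(new_rgb_volume(rgb, parcellation$affine, asg, total))
  }
  nvox <- prod(dm)
  for (j in 1:3) {
    dmax <- if (dmax_mode == "global") gmax else max(dens_parcel[, j])
    if (dmax > 0) {
      ch <- numeric(nvox)
      ch[hit] <- intensity_transform(dens_parcel[pos[hit], j], dmax, k)
      rgb[seq_len(nvox) + (j - 1L) * nvox] <- ch
    }
  }
  new_rgb_volume(rgb, parcellation$affine, asg, total)
}

PROJECTION_VIEWS <- c("superior", "inferior", "anterior", "posterior",
                      "left-lateral", "right-lateral", "medial-L", "medial-R")

# world x coordinate of voxel centres along array axis 1 (used to split
# hemispheres for medial views); assumes an axis-aligned affine
axis1_world_x <- function(affine, dm) {
  ijk <- cbind(seq_len(dm[1]) - 1L, (dm[2] - 1) / 2, (dm[3] - 1) / 2)
  (ijk %*% t(affine[1:3, 1:3]) +
     matrix(affine[1:3, 4], dm[1], 3L, byrow = TRUE))[, 1L]
}

#' Slice-stacked 3D-like projection of an RGB volume
#'
#' Painter's algorithm: slices are traversed from the far side toward the
#' viewer and a pixel takes a voxel's color whenever that voxel's
#' pre-transform total density exceeds the exclusion threshold (default:
#' any nonzero count paints, i.e. only the minimum-density background is
#' excluded). Array axes are taken as left-right, posterior-anterior,
#' inferior-superior; medial views mask one hemisphere by the world-x sign
#' of the voxel centre and stack from the lateral surface toward the
#' midline.
#'
#' @param rgb a `tdrm_rgb` volume.
#' @param view one of `"superior"`, `"inferior"`, `"anterior"`,
#'   `"posterior"`, `"left-lateral"`, `"right-lateral"`, `"medial-L"`,
#'   `"medial-R"`.
#' @param threshold paint a voxel iff its total density is strictly greater
#'   than this; default 0.
#' @return An object of class `tdrm_projection`: list with `image`
#'   (rows x cols x 3 in `[0, 1]`, in array coordinates) and `view`.
#' @export
stack_projection <- function(rgb, view, threshold = 0) {
  stopifnot(inherits(rgb, "tdrm_rgb"))
  if (!view %in% PROJECTION_VIEWS)
    stop("unknown view '", view, "'; expected one of ",
         paste(PROJECTION_VIEWS, collapse = ", "), call. = FALSE)
  dm <- dim(rgb$rgb)[1:3]

  axis <- switch(view,
    superior = 3L, inferior = 3L, anterior = 2L, posterior = 2L,
    `left-lateral` = 1L, `right-lateral` = 1L,
    `medial-L` = 1L, `medial-R` = 1L)
  slices <- switch(view,
    superior = seq_len(dm[3]),            # inferior -> superior
    inferior = rev(seq_len(dm[3])),
    anterior = seq_len(dm[2]),            # posterior -> anterior
    posterior = rev(seq_len(dm[2])),
    `left-lateral` = rev(seq_len(dm[1])), # right -> left (viewer at -x)
    `right-lateral` = seq_len(dm[1]))
  if (is.null(slices)) {                  # medial views
    wx <- axis1_world_x(rgb$affine, dm)
    if (view == "medial-L") slices <- which(wx < 0)          # lateral -> midline
    else slices <- rev(which(wx >= 0))
    if (length(slices) == 0L)
      stop("no voxels on the requested hemisphere side", call. = FALSE)
  }

  img_dims <- switch(axis, `1` = dm[2:3], `2` = dm[c(1, 3)], `3` = dm[1:2])
  img <- array(0, dim = c(img_dims, 3L))
  for (s in slices) {
    sl_tot <- switch(axis,
      `1` = rgb$total[s, , ], `2` = rgb$total[, s, ], `3` = rgb$total[, , s])
    paint <- sl_tot > threshold
    if (!any(paint)) next
    for (j in 1:3) {
      sl <- switch(axis,
        `1` = rgb$rgb[s, , , j], `2` = rgb$rgb[, s, , j], `3` = rgb$rgb[, , s, j])
      ch <- img[, , j]
      ch[paint] <- sl[paint]
      img[, , j] <- ch
    }
  }
  structure(list(image = img, view = view, threshold = threshold),
            class = "tdrm_projection")
}

#' @export
print.tdrm_projection <- function(x, ...) {
  cat(sprintf("Projection image (%s view): %d x %d pixels, %d painted\n",
              x$view, dim(x$image)[1], dim(x$image)[2],
              sum(apply(x$image, 1:2, max) > 0)))
  invisible(x)
}

#' Write a projection image as an 8-bit PNG
#'
#' Pixel values are quantised as `round(255 * v)`. The raster is rotated so
#' that the second array axis points up.
#'
#' @param projection a `tdrm_projection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(projection, path) {
  stopifnot(inherits(projection, "tdrm_projection"))
  img <- projection$image
  raster <- aperm(img, c(2L, 1L, 3L))[rev(seq_len(dim(img)[2])), , , drop = FALSE]
  png::writePNG(round(255 * raster) / 255, path)
  invisible(path)
}

#' Plot a projection image
#' @param x a `tdrm_projection`.
#' @param ... unused.
#' @export
plot.tdrm_projection <- function(x, ...) {
  img <- aperm(x$image, c(2L, 1L, 3L))[rev(seq_len(dim(x$image)[2])), , ,
                                       drop = FALSE]
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = dim(img)[1] / dim(img)[2])
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::title(main = x$view)
  invisible(x)
}
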