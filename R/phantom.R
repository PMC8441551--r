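# Synthetic phantom: a spherical "brain" on a 1 mm grid with two hemispheric
# cortical shells split at the midplane x = 0, a central subcortical blob and
# white matter in between, plus streamlines whose class is encoded purely by
# their terminal compartments and arc length (never by metadata), so the
# classifier can be tested blind against known ground truth.

#' Phantom specification
#'
#' @param grid_shape integer vector of 3 voxel counts (1 mm voxels). Each
#'   axis must be at least 20 voxels; even counts keep the midplane between
#'   voxel columns.
#' @param counts named nonnegative integer vector of streamline counts per
#'   planted category: `projection`, `commissural`, `short_assoc`,
#'   `long_assoc`, `noise_wm`, `ineffective`. The default mix of 10,000
#'   classifiable tracks (18.3% projection, 20.2% commissural, 33.0% short
#'   and 28.5% long association) plus 1,000 noise and 500 ineffective tracks
#'   mirrors the class proportions reported for real whole-brain tractograms.
#' @param n_parcels_per_hemisphere number of cortical parcels per hemisphere.
#' @param seed integer RNG seed; a fixed seed makes the phantom
#'   bit-reproducible.
#' @return An object of class `tdrm_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80L, 80L, 80L),
                         counts = c(projection = 1830L, commissural = 2020L,
                                    short_assoc = 3300L, long_assoc = 2850L,
                                    noise_wm = 1000L, ineffective = 500L),
                         n_parcels_per_hemisphere = 6L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 20L))
    stop("grid_shape must give 3 axes of at least 20 voxels each", call. = FALSE)
  need <- c("projection", "commissural", "short_assoc", "long_assoc",
            "noise_wm", "ineffective")
  full <- stats::setNames(integer(6L), need)
  full[names(counts)] <- as.integer(counts)
  if (!all(names(counts) %in% need))
    stop("unknown count categories: ",
         paste(setdiff(names(counts), need), collapse = ", "), call. = FALSE)
  if (any(full < 0L)) stop("counts must be nonnegative", call. = FALSE)
  structure(list(grid_shape = grid_shape, counts = full,
                 n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
                 seed = as.integer(seed)),
            class = "tdrm_phantom_spec")
}

# geometry parameters shared by tissue construction and track generation
phantom_geometry <- function(spec) {
  n <- spec$grid_shape
  r_brain <- 0.45 * min(n)
  list(r_brain = r_brain,
       shell = if (r_brain >= 15) 3 else 2,     # cortical shell thickness, mm
       r_sub = 0.125 * min(n),                  # subcortical blob radius, mm
       affine = {
         a <- diag(4)
         a[1:3, 4] <- -(n / 2 - 0.5)            # voxel centres at half-integers
         a
       })
}

#' Build the phantom tissue and parcellation volumes
#'
#' The tissue volume holds labels 0 background, 1 white matter, 2 left
#' cortex, 3 right cortex, 4 subcortical. The parcellation tiles each
#' cortical shell into contiguous bands stacked along z, with labels
#' 1..n for the left and n+1..2n for the right hemisphere; homotopic bands
#' share a name, and lobe groups cycle through the six cortical lobes.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `tissue` and `parcellation`
#'   ([label_volume()]s) and `lookup` (parcel lookup data.frame).
#' @export
build_phantom_tissue <- function(spec) {
  stopifnot(inherits(spec, "tdrm_phantom_spec"))
  n <- spec$grid_shape
  g <- phantom_geometry(spec)

  xs <- (seq_len(n[1]) - 1) - n[1] / 2 + 0.5
  ys <- (seq_len(n[2]) - 1) - n[2] / 2 + 0.5
  zs <- (seq_len(n[3]) - 1) - n[3] / 2 + 0.5
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  r <- sqrt(r2)
  xg <- array(xs, dim = n)

  tissue <- array(0L, dim = n)
  in_ctx <- r <= g$r_brain & r > g$r_brain - g$shell
  tissue[in_ctx & xg < 0] <- TISSUE_CTX_L
  tissue[in_ctx & xg >= 0] <- TISSUE_CTX_R
  tissue[r <= g$r_brain - g$shell] <- TISSUE_WM
  tissue[r <= g$r_sub] <- TISSUE_SUB

  npar <- spec$n_parcels_per_hemisphere
  parc <- array(0L, dim = n)
  zg <- array(rep(zs, each = n[1] * n[2]), dim = n)
  for (h in 1:2) {
    lab0 <- if (h == 1L) 0L else npar
    idx <- which(tissue == if (h == 1L) TISSUE_CTX_L else TISSUE_CTX_R)
    ord <- idx[order(zg[idx])]
    band <- ceiling(seq_along(ord) * npar / length(ord))
    parc[ord] <- lab0 + band
  }

  lookup <- data.frame(
    label = seq_len(2L * npar),
    name = rep(sprintf("band_%02d", seq_len(npar)), 2L),
    hemisphere = rep(c("L", "R"), each = npar),
    lobe_group = rep(LOBE_GROUPS[((seq_len(npar) - 1L) %% 6L) + 1L], 2L),
    stringsAsFactors = FALSE)

  list(tissue = label_volume(tissue, g$affine, "tissue"),
       parcellation = label_volume(parc, g$affine, "parcellation"),
       lookup = lookup)
}

# world coordinates of voxel centres for a set of linear indices
voxel_world <- function(volume, lin_idx) {
  ijk <- arrayInd(lin_idx, dim(volume$labels)) - 1L
  ijk %*% t(volume$affine[1:3, 1:3]) +
    matrix(volume$affine[1:3, 4], length(lin_idx), 3L, byrow = TRUE)
}

polyline_len <- function(p) {
  d <- diff(p)
  sum(sqrt(rowSums(d * d)))
}

# resample a polyline at a fixed step along its own segments; first and last
# points are preserved exactly
resample_polyline <- function(p, step = 0.2) {
  d <- sqrt(rowSums(diff(p)^2))
  keep <- c(TRUE, d > 1e-12)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 2L) return(rbind(p, p))
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  L <- s[length(s)]
  t_out <- seq(0, L, by = step)
  if (t_out[length(t_out)] < L) t_out <- c(t_out, L)
  q <- cbind(stats::approx(s, p[, 1], xout = t_out)$y,
             stats::approx(s, p[, 2], xout = t_out)$y,
             stats::approx(s, p[, 3], xout = t_out)$y)
  q[1L, ] <- p[1L, ]
  q[nrow(q), ] <- p[nrow(p), ]
  q
}

# spherical-arc control path from A to B staying near radius r_mid in the
# interior; endpoints exact
arc_path <- function(A, B, r_mid, step_deg = 8) {
  rA <- sqrt(sum(A^2)); rB <- sqrt(sum(B^2))
  uA <- A / rA; uB <- B / rB
  ang <- acos(min(1, max(-1, sum(uA * uB))))
  nseg <- max(2L, ceiling(ang / (step_deg * pi / 180)))
  t <- seq(0, 1, length.out = nseg + 1L)
  if (ang < 1e-6) {
    dirs <- matrix(uA, nseg + 1L, 3L, byrow = TRUE)
  } else {
    dirs <- (sin((1 - t) * ang) %o% uA + sin(t * ang) %o% uB) / sin(ang)
  }
  w <- sqrt(sin(pi * t))               # pull interior quickly off the shell
  rad <- (1 - w) * ((1 - t) * rA + t * rB) + w * r_mid
  p <- dirs * rad
  p[1L, ] <- A
  p[nrow(p), ] <- B
  p
}

# insert radially displaced midpoints until the control path reaches the
# target length; deterministic, no rejection sampling
lengthen_radial <- function(p, target, r_lo, r_hi) {
  for (pass in 1:12) {
    if (polyline_len(p) >= target) break
    np <- nrow(p)
    mids <- (p[-np, , drop = FALSE] + p[-1L, , drop = FALSE]) / 2
    rr <- pmax(sqrt(rowSums(mids^2)), 1e-9)
    rnew <- ifelse(seq_len(np - 1L) %% 2L == 1L, r_lo, r_hi)
    mids <- mids * (rnew / rr)
    q <- matrix(0, 2L * np - 1L, 3L)
    q[seq(1L, 2L * np - 1L, by = 2L), ] <- p
    q[seq(2L, 2L * np - 2L, by = 2L), ] <- mids
    p <- q
  }
  p
}

jitter_interior <- function(p, sd = 0.3) {
  np <- nrow(p)
  if (np > 2L)
    p[2:(np - 1L), ] <- p[2:(np - 1L), ] + matrix(stats::rnorm(3L * (np - 2L), 0, sd),
                                                  np - 2L, 3L)
  p
}

sample_rows <- function(m, k) m[sample.int(nrow(m), k, replace = TRUE), , drop = FALSE]

#' Generate phantom streamlines with known ground truth
#'
#' For each requested category, terminal voxels are sampled in the defining
#' compartments (projection: cortex and subcortical; commissural: left and
#' right cortex; associations: two same-hemisphere cortical terminals with
#' the arc length forced below / at-or-above 60 mm by detour midpoints;
#' noise: a white-matter terminal; ineffective: subcortical on both ends).
#' Interior control points are routed through white matter and jittered, and
#' every polyline is resampled at 0.2 mm steps, the step size typical of
#' fixed-step probabilistic tractography. Terminals are exact voxel centres,
#' so the tissue lookup recovers the intended compartments.
#'
#' @param spec a [phantom_spec()].
#' @param volumes output of [build_phantom_tissue()] for the same spec.
#' @return list with `tracks` (a [track_set()]) and `truth` (data.frame with
#'   `index`, `truth` class/rejection, intended terminal labels).
#' @export
generate_tracks <- function(spec, volumes) {
  stopifnot(inherits(spec, "tdrm_phantom_spec"))
  set.seed(spec$seed)
  tissue <- volumes$tissue
  g <- phantom_geometry(spec)
  lab <- tissue$labels

  ctx_l <- voxel_world(tissue, which(lab == TISSUE_CTX_L))
  ctx_r <- voxel_world(tissue, which(lab == TISSUE_CTX_R))
  sub <- voxel_world(tissue, which(lab == TISSUE_SUB))
  wm_all <- which(lab == TISSUE_WM)
  wm_r <- sqrt(rowSums(voxel_world(tissue, wm_all)^2))
  wm <- voxel_world(tissue, wm_all[wm_r > g$r_sub + 1.5 & wm_r < g$r_brain - g$shell - 1])
  if (nrow(sub) < 2L || nrow(ctx_l) < 10L || nrow(ctx_r) < 10L || nrow(wm) < 10L)
    stop("phantom grid too small: compartments have too few voxels", call. = FALSE)

  r_mid <- 0.55 * g$r_brain
  r_lo <- max(g$r_sub + 3, 0.35 * g$r_brain)
  r_hi <- g$r_brain - g$shell - 1.5
  cnt <- spec$counts
  streamlines <- vector("list", sum(cnt))
  truth <- character(sum(cnt))
  lab_a <- integer(sum(cnt)); lab_b <- integer(sum(cnt))
  k <- 0L

  emit <- function(points, cls, la, lb) {
    k <<- k + 1L
    streamlines[[k]] <<- points
    truth[k] <<- cls
    lab_a[k] <<- la; lab_b[k] <<- lb
  }

  # same-hemisphere terminal pair with Euclidean separation in [d_lo, d_hi]
  pair_in_hemi <- function(ctx, d_lo, d_hi) {
    for (try in 1:50) {
      A <- ctx[sample.int(nrow(ctx), 1L), ]
      cand <- ctx[sample.int(nrow(ctx), min(nrow(ctx), 4000L)), , drop = FALSE]
      d <- sqrt(rowSums((cand - matrix(A, nrow(cand), 3L, byrow = TRUE))^2))
      ok <- which(d >= d_lo & d <= d_hi)
      if (length(ok)) return(list(A = A, B = cand[ok[sample.int(length(ok), 1L)], ]))
    }
    stop("phantom association pair infeasible on this grid (separation ",
         d_lo, "-", d_hi, " mm)", call. = FALSE)
  }

  straight_path <- function(A, B, n_ctrl = 5L) {
    t <- seq(0, 1, length.out = n_ctrl)
    (1 - t) %o% A + t %o% B
  }

  for (i in seq_len(cnt[["projection"]])) {
    ctx <- if (stats::runif(1) < 0.5) ctx_l else ctx_r
    A <- ctx[sample.int(nrow(ctx), 1L), ]
    B <- sub[sample.int(nrow(sub), 1L), ]
    p <- resample_polyline(jitter_interior(straight_path(A, B)), 0.2)
    emit(p, "projection", label_at(tissue, A), TISSUE_SUB)
  }

  for (i in seq_len(cnt[["commissural"]])) {
    A <- ctx_l[sample.int(nrow(ctx_l), 1L), ]
    B <- ctx_r[sample.int(nrow(ctx_r), 1L), ]
    p <- resample_polyline(jitter_interior(arc_path(A, B, r_mid)), 0.2)
    emit(p, "commissural", TISSUE_CTX_L, TISSUE_CTX_R)
  }

  short_hi <- min(35, 0.8 * g$r_brain)
  for (i in seq_len(cnt[["short_assoc"]])) {
    left <- stats::runif(1) < 0.5
    ab <- pair_in_hemi(if (left) ctx_l else ctx_r, 5, short_hi)
    m <- (ab$A + ab$B) / 2
    m <- m * (((sqrt(sum(ab$A^2)) + sqrt(sum(ab$B^2))) / 2 - g$shell - 1.5) /
              max(sqrt(sum(m^2)), 1e-9))
    p <- resample_polyline(jitter_interior(rbind(ab$A, m, ab$B)), 0.2)
    if (polyline_len(p) >= 58)
      stop("phantom short association track exceeded its length budget",
           call. = FALSE)
    emit(p, "short_assoc", if (left) TISSUE_CTX_L else TISSUE_CTX_R,
         if (left) TISSUE_CTX_L else TISSUE_CTX_R)
  }

  long_lo <- min(20, 0.5 * g$r_brain)
  for (i in seq_len(cnt[["long_assoc"]])) {
    left <- stats::runif(1) < 0.5
    ab <- pair_in_hemi(if (left) ctx_l else ctx_r, long_lo, Inf)
    p <- NULL
    for (target in seq(63, 123, by = 10)) {
      ctrl <- lengthen_radial(arc_path(ab$A, ab$B, r_mid), target, r_lo, r_hi)
      q <- resample_polyline(jitter_interior(ctrl), 0.2)
      if (polyline_len(q) >= 60.05) { p <- q; break }
    }
    if (is.null(p))
      stop("phantom long association track could not reach 60 mm", call. = FALSE)
    emit(p, "long_assoc", if (left) TISSUE_CTX_L else TISSUE_CTX_R,
         if (left) TISSUE_CTX_L else TISSUE_CTX_R)
  }

  for (i in seq_len(cnt[["noise_wm"]])) {
    A <- wm[sample.int(nrow(wm), 1L), ]
    if (stats::runif(1) < 0.5) {
      B <- wm[sample.int(nrow(wm), 1L), ]; lb <- TISSUE_WM
    } else {
      ctx <- if (stats::runif(1) < 0.5) ctx_l else ctx_r
      B <- ctx[sample.int(nrow(ctx), 1L), ]; lb <- label_at(tissue, B)
    }
    p <- resample_polyline(jitter_interior(straight_path(A, B, 3L)), 0.2)
    emit(p, "noise_wm", TISSUE_WM, lb)
  }

  for (i in seq_len(cnt[["ineffective"]])) {
    ab <- sub[sample.int(nrow(sub), 2L, replace = FALSE), ]
    p <- resample_polyline(jitter_interior(straight_path(ab[1L, ], ab[2L, ], 3L)), 0.2)
    emit(p, "ineffective", TISSUE_SUB, TISSUE_SUB)
  }

  tracks <- track_set(streamlines, space_id = "phantom-native",
                      source_meta = c(tdrm_phantom = "1",
                                      seed = as.character(spec$seed)))
  truth_df <- data.frame(index = seq_len(k), truth = truth,
                         terminal_a = lab_a, terminal_b = lab_b,
                         stringsAsFactors = FALSE)
  list(tracks = tracks, truth = truth_df)
}

#' Build a complete phantom scene
#'
#' @param spec a [phantom_spec()] (the default spec if omitted).
#' @return An object of class `tdrm_phantom`: list with `spec`, `tissue`,
#'   `parcellation`, `lookup`, `tracks`, `truth`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  vols <- build_phantom_tissue(spec)
  tr <- generate_tracks(spec, vols)
  structure(c(list(spec = spec), vols, tr), class = "tdrm_phantom")
}

#' @export
print.tdrm_phantom <- function(x, ...) {
  cat(sprintf("Phantom scene: %s grid, %d parcels/hemisphere, seed %d\n",
              paste(x$spec$grid_shape, collapse = "x"),
              x$spec$n_parcels_per_hemisphere, x$spec$seed))
  cat("  planted counts:\n")
  for (nm in names(x$spec$counts))
    cat(sprintf("    %-12s %6d\n", nm, x$spec$counts[[nm]]))
  invisible(x)
}

#' Write a phantom scene to disk
#'
#' Writes `tissue.nii.gz`, `parcellation.nii.gz`, `parcels.tsv`,
#' `tracks.tck` and `truth.tsv` into a directory.
#'
#' @param scene a `tdrm_phantom` from [build_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(scene, dir) {
  stopifnot(inherits(scene, "tdrm_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_label_volume(scene$tissue, file.path(dir, "tissue.nii.gz"))
  write_label_volume(scene$parcellation, file.path(dir, "parcellation.nii.gz"))
  write_parcel_lookup(scene$lookup, file.path(dir, "parcels.tsv"))
  write_tck(scene$tracks, file.path(dir, "tracks.tck"))
  utils::write.table(scene$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
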