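# ---- track sets -------------------------------------------------------------

#' Construct a track set
#'
#' A track set holds a list of streamlines (ordered 3D polylines in world
#' millimetres), a free-text coordinate-frame tag, and any header metadata
#' carried over from file.
#'
#' @param streamlines list of numeric matrices, each with 3 columns (x, y, z
#'   in mm) and at least 2 rows of finite coordinates.
#' @param space_id non-empty character tag for the coordinate frame
#'   (e.g. `"native"`, `"MNI"`).
#' @param source_meta named character vector of original header fields.
#' @return An object of class `tdrm_tracks`.
#' @export
track_set <- function(streamlines, space_id = "native",
                      source_meta = character()) {
  if (!is.list(streamlines))
    stop("`streamlines` must be a list of point matrices", call. = FALSE)
  if (!is.character(space_id) || length(space_id) != 1L || !nzchar(space_id))
    stop("`space_id` must be a non-empty string", call. = FALSE)
  for (i in seq_along(streamlines)) {
    p <- streamlines[[i]]
    if (!is.matrix(p) || ncol(p) != 3L || nrow(p) < 2L)
      stop(sprintf("streamline %d is not a matrix with 3 columns and >= 2 rows", i),
           call. = FALSE)
    if (!all(is.finite(p)))
      stop(sprintf("streamline %d contains non-finite coordinates", i),
           call. = FALSE)
  }
  structure(list(streamlines = streamlines, space_id = space_id,
                 source_meta = source_meta),
            class = "tdrm_tracks")
}

#' @export
print.tdrm_tracks <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat(sprintf("Track set: %d streamlines, %d points, space '%s'\n",
              length(x$streamlines), np, x$space_id))
  invisible(x)
}

#' @export
length.tdrm_tracks <- function(x) length(x$streamlines)

# Matrices of first / last points, n x 3.
terminal_points <- function(tracks) {
  sl <- tracks$streamlines
  a <- t(vapply(sl, function(p) p[1L, ], numeric(3)))
  b <- t(vapply(sl, function(p) p[nrow(p), ], numeric(3)))
  list(a = a, b = b)
}

# ---- TCK format -------------------------------------------------------------

# MRtrix track file layout: a text header starting "mrtrix tracks", one
# "key: value" field per line, a "file: . <offset>" self-reference, and a
# terminating "END" line; then little-endian float32 (x,y,z) triplets starting
# at <offset>, with an all-NaN triplet after each streamline and an all-Inf
# triplet closing the stream.

#' Read an MRtrix TCK streamline file
#'
#' @param path path to a `.tck` file.
#' @param space_id coordinate-frame tag to record on the returned set.
#' @return A [track_set()] with coordinates in world mm as stored; all header
#'   fields are preserved in `source_meta`.
#' @export
read_tck <- function(path, space_id = "native") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fsize <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  head_raw <- readBin(con, "raw", n = min(fsize, 65536L))
  magic <- rawToChar(head_raw[seq_len(min(13L, length(head_raw)))])
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic at byte offset 0): ",
         path, call. = FALSE)

  # locate the END line inside the text header
  nl <- which(head_raw == as.raw(10L))
  hdr_end <- NA_integer_
  lines <- character()
  prev <- 0L
  for (pos in nl) {
    line <- rawToChar(head_raw[seq.int(prev + 1L, pos - 1L)])
    if (identical(line, "END")) { hdr_end <- pos; break }
    lines <- c(lines, line)
    prev <- pos
  }
  if (is.na(hdr_end))
    stop(sprintf("malformed TCK header: no END line within the first %d bytes of %s",
                 length(head_raw), path), call. = FALSE)

  lines <- lines[-1L]                     # drop magic line
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", character(1)))
  meta <- stats::setNames(vals, keys)

  if (!"file" %in% keys)
    stop(sprintf("malformed TCK header (no 'file' field before byte offset %d) in %s",
                 hdr_end, path), call. = FALSE)
  fpieces <- strsplit(meta[["file"]], "[[:space:]]+")[[1]]
  offset <- suppressWarnings(as.integer(fpieces[length(fpieces)]))
  if (is.na(offset) || offset < hdr_end)
    stop(sprintf("malformed TCK 'file' field (offset %s) in %s",
                 meta[["file"]], path), call. = FALSE)

  dt <- if ("datatype" %in% keys) meta[["datatype"]] else "Float32LE"
  if (!identical(dt, "Float32LE"))
    stop(sprintf("unsupported TCK datatype '%s' (header ends at byte offset %d); only Float32LE is handled",
                 dt, hdr_end), call. = FALSE)

  nbytes <- fsize - offset
  if (nbytes %% 12L != 0L)
    stop(sprintf("truncated TCK triplet stream: %d bytes after data offset %d is not a multiple of 12 in %s",
                 nbytes, offset, path), call. = FALSE)
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "numeric", n = nbytes / 4L, size = 4L, endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)

  inf_row <- which(rowSums(is.infinite(m)) > 0L)
  if (length(inf_row) == 0L && nrow(m) > 0L)
    stop(sprintf("truncated TCK stream: no Inf terminator (last triplet at byte offset %.0f) in %s",
                 offset + (nrow(m) - 1) * 12, path), call. = FALSE)
  if (length(inf_row) > 0L) m <- m[seq_len(inf_row[1L] - 1L), , drop = FALSE]

  streamlines <- list()
  if (nrow(m) > 0L) {
    sep <- rowSums(is.nan(m)) > 0L
    grp <- cumsum(c(TRUE, sep[-length(sep)]))
    keep <- !sep
    idx <- split(which(keep), grp[keep])
    streamlines <- lapply(idx, function(i) m[i, , drop = FALSE])
    names(streamlines) <- NULL
  }

  if ("count" %in% keys) {
    cnt <- suppressWarnings(as.integer(meta[["count"]]))
    if (!is.na(cnt) && cnt != length(streamlines))
      stop(sprintf("TCK header declares count %d but %d streamlines were read from %s",
                   cnt, length(streamlines), path), call. = FALSE)
  }
  track_set(streamlines = streamlines, space_id = space_id, source_meta = meta)
}

#' Write an MRtrix TCK streamline file
#'
#' Writes a bit-valid TCK file: text header with a `count` field, little-endian
#' float32 triplets, an all-NaN triplet after each streamline and an all-Inf
#' terminator. Coordinates are stored at float32 precision.
#'
#' @param tracks a [track_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tracks, path) {
  stopifnot(inherits(tracks, "tdrm_tracks"))
  sl <- tracks$streamlines
  n <- length(sl)

  meta <- tracks$source_meta
  meta <- meta[!names(meta) %in% c("count", "datatype", "file")]
  body_lines <- c("mrtrix tracks",
                  sprintf("count: %d", n),
                  "datatype: Float32LE",
                  if (length(meta)) sprintf("%s: %s", names(meta), unname(meta)))

  # the data offset depends on the header length, which depends on the number
  # of digits of the offset itself; iterate to a fixed point
  offset <- 0L
  for (i in 1:5) {
    hdr <- paste0(paste0(body_lines, "\n", collapse = ""),
                  sprintf("file: . %d\nEND\n", offset))
    new_offset <- nchar(hdr, type = "bytes")
    if (new_offset == offset) break
    offset <- new_offset
  }

  blocks <- vector("list", 2L * n + 1L)
  nan_row <- matrix(NaN, 1L, 3L)
  for (i in seq_len(n)) {
    blocks[[2L * i - 1L]] <- sl[[i]]
    blocks[[2L * i]] <- nan_row
  }
  blocks[[2L * n + 1L]] <- matrix(Inf, 1L, 3L)
  flat <- as.numeric(t(do.call(rbind, blocks)))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(hdr), con)
  writeBin(flat, con, size = 4L, endian = "little")
  invisible(path)
}

# ---- label volumes ----------------------------------------------------------

#' Construct a label volume
#'
#' @param labels 3D array of nonnegative integer labels.
#' @param affine 4x4 world-from-index transform (mm); maps 0-based voxel
#'   indices to world coordinates of voxel centres.
#' @param role `"tissue"` or `"parcellation"`. Tissue labels must lie in
#'   0 (background), 1 (white matter), 2 (left cortex), 3 (right cortex),
#'   4 (subcortical).
#' @return An object of class `tdrm_labels`.
#' @export
label_volume <- function(labels, affine, role = c("tissue", "parcellation")) {
  role <- match.arg(role)
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L)
    stop("labels must be nonnegative integers", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  if (role == "tissue" && !all(unique(as.vector(labels)) %in% 0:4))
    stop("tissue labels must be a subset of {0,1,2,3,4}", call. = FALSE)
  structure(list(labels = labels, affine = affine, role = role),
            class = "tdrm_labels")
}

#' @export
print.tdrm_labels <- function(x, ...) {
  cat(sprintf("Label volume (%s): %s voxels, %d distinct nonzero labels\n",
              x$role, paste(dim(x$labels), collapse = "x"),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read a NIfTI label volume
#'
#' @param path path to a `.nii` / `.nii.gz` file with integer-valued voxels.
#' @param role passed to [label_volume()].
#' @param tol values further than this from an integer raise an error.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, role = c("tissue", "parcellation"),
                              tol = 1e-6) {
  role <- match.arg(role)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4L] == 1L) a <- a[, , , 1L]
  if (length(dim(a)) != 3L)
    stop("expected a 3D label volume in ", path, call. = FALSE)
  r <- round(a)
  if (max(abs(a - r)) > tol)
    stop("non-integer voxel values (beyond tolerance ", tol, ") in ", path,
         call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  label_volume(array(as.integer(r), dim(a)), aff, role)
}

#' Write a label volume as NIfTI
#'
#' @param volume a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "tdrm_labels"))
  img <- RNifti::asNifti(volume$labels)
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

# ---- world <-> voxel --------------------------------------------------------

# 0-based voxel indices of world points under the nearest-voxel convention
# floor(inv(affine) . p + 0.5). Returns an n x 3 integer matrix.
voxel_index0 <- function(affine, points) {
  points <- as_points(points)
  inv <- solve(affine)
  v <- points %*% t(inv[1:3, 1:3]) +
    matrix(inv[1:3, 4], nrow(points), 3L, byrow = TRUE)
  ijk <- floor(v + 0.5)
  storage.mode(ijk) <- "integer"
  ijk
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 3L) stop("a point must have 3 coordinates", call. = FALSE)
    points <- matrix(points, 1L, 3L)
  }
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix", call. = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Look up labels at world coordinates
#'
#' Maps world-mm points to voxels by rounding the inverse-affine image to the
#' nearest index (NIfTI voxel-centre semantics) and returns the stored label.
#' Points falling outside the array are background (label 0) by contract,
#' never an error.
#'
#' @param volume a [label_volume()].
#' @param points a length-3 vector or n x 3 matrix of world-mm coordinates.
#' @return Integer vector of labels, one per point.
#' @export
label_at <- function(volume, points) {
  stopifnot(inherits(volume, "tdrm_labels"))
  ijk <- voxel_index0(volume$affine, points)
  dm <- dim(volume$labels)
  inside <- ijk[, 1L] >= 0L & ijk[, 1L] < dm[1L] &
            ijk[, 2L] >= 0L & ijk[, 2L] < dm[2L] &
            ijk[, 3L] >= 0L & ijk[, 3L] < dm[3L]
  out <- integer(nrow(ijk))
  if (any(inside)) {
    lin <- 1L + ijk[inside, 1L] + dm[1L] * (ijk[inside, 2L] + dm[2L] * ijk[inside, 3L])
    out[inside] <- volume$labels[lin]
  }
  out
}

# voxel edge lengths (mm) from an affine
voxel_spacing <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# ---- parcel lookup ----------------------------------------------------------

LOBE_GROUPS <- c("frontal", "parietal", "temporal", "limbic", "insular", "occipital")

#' Read a parcel lookup table
#'
#' Tab-separated table with columns `label`, `name`, `hemisphere` (L/R) and
#' `lobe_group` (frontal, parietal, temporal, limbic, insular, occipital).
#' Homotopic parcels share a `name` across hemispheres.
#'
#' @param path path to the TSV.
#' @return A data.frame with validated columns.
#' @export
read_parcel_lookup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_parcel_lookup(df)
}

#' Write a parcel lookup table
#' @param lookup a parcel lookup data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_parcel_lookup <- function(lookup, path) {
  validate_parcel_lookup(lookup)
  utils::write.table(lookup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_parcel_lookup <- function(df) {
  need <- c("label", "name", "hemisphere", "lobe_group")
  if (!all(need %in% names(df)))
    stop("parcel lookup must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$label <- as.integer(df$label)
  if (anyDuplicated(df$label) || any(df$label <= 0L))
    stop("parcel labels must be unique positive integers", call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  if (!all(df$lobe_group %in% LOBE_GROUPS))
    stop("lobe_group must be one of ", paste(LOBE_GROUPS, collapse = ", "),
         call. = FALSE)
  df
}
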