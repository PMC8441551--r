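# Fiber classes and rejection reasons. Classification reads nothing but the
# tissue labels of the two terminals plus the polyline arc length.

#' @rdname classify_tracks
#' @format NULL
#' @export
TDRM_CLASSES <- c("projection", "commissural", "short_assoc", "long_assoc")

#' @rdname classify_tracks
#' @format NULL
#' @export
TDRM_REJECTIONS <- c("noise_wm", "ineffective")

TISSUE_BG   <- 0L
TISSUE_WM   <- 1L
TISSUE_CTX_L <- 2L
TISSUE_CTX_R <- 3L
TISSUE_SUB  <- 4L

#' Arc length of a streamline
#'
#' Sum of Euclidean distances between consecutive points, in mm. No spline
#' smoothing is applied: fixed-step tractography output is already densely
#' sampled and the stored polyline is the track.
#'
#' @param streamline an n x 3 point matrix (n >= 2), or a `tdrm_tracks`
#'   object (then a vector of lengths is returned).
#' @return Arc length(s) in mm.
#' @export
streamline_length <- function(streamline) {
  if (inherits(streamline, "tdrm_tracks"))
    return(vapply(streamline$streamlines, streamline_length, numeric(1)))
  p <- as_points(streamline)
  if (nrow(p) < 2L) stop("a streamline needs at least 2 points", call. = FALSE)
  d <- diff(p)
  sum(sqrt(rowSums(d * d)))
}

#' Tissue compartments of a streamline's two terminals
#'
#' @param tracks a `tdrm_tracks` object (or a single point matrix).
#' @param tissue a tissue [label_volume()].
#' @return An n x 2 integer matrix of tissue labels at the first and last
#'   point of each streamline.
#' @export
terminal_compartments <- function(tracks, tissue) {
  if (is.matrix(tracks)) tracks <- track_set(list(tracks))
  tp <- terminal_points(tracks)
  cbind(label_a = label_at(tissue, tp$a), label_b = label_at(tissue, tp$b))
}

#' Validate streamlines against the tissue segmentation
#'
#' A streamline is rejected as `noise_wm` if either terminal lies in white
#' matter, and as `ineffective` if neither terminal lies in the cerebral
#' cortex (left or right); the white-matter rule takes precedence when both
#' hold. Remaining streamlines are kept for classification.
#'
#' @param tracks a `tdrm_tracks` object.
#' @param tissue a tissue [label_volume()].
#' @return An object of class `tdrm_classification`: a data.frame with one
#'   row per input streamline and columns `index`, `label_a`, `label_b`,
#'   `length_mm`, `status` (`"kept"`, `"noise_wm"` or `"ineffective"`) and
#'   `class` (`NA` until [classify_tracks()] fills it).
#' @export
validate_tracks <- function(tracks, tissue) {
  stopifnot(inherits(tracks, "tdrm_tracks"), inherits(tissue, "tdrm_labels"))
  term <- terminal_compartments(tracks, tissue)
  len <- streamline_length(tracks)
  a <- term[, 1L]; b <- term[, 2L]
  is_wm <- a == TISSUE_WM | b == TISSUE_WM
  has_ctx <- a %in% c(TISSUE_CTX_L, TISSUE_CTX_R) |
             b %in% c(TISSUE_CTX_L, TISSUE_CTX_R)
  status <- rep("kept", length(a))
  status[!has_ctx] <- "ineffective"
  status[is_wm] <- "noise_wm"          # precedence: noise over ineffective
  out <- data.frame(index = seq_along(a), label_a = a, label_b = b,
                    length_mm = len, status = status,
                    class = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("tdrm_classification", "data.frame")
  out
}

#' Classify validated streamlines into the four fiber classes
#'
#' Decision order over the two terminal compartments: any subcortical
#' terminal makes a projection fiber; one terminal in each cortex makes a
#' commissural fiber; two terminals in the same cortex make an association
#' fiber, split by arc length at 6 cm (`< 60` mm short, `>= 60` mm long).
#' A kept streamline whose terminal combination fits none of these (e.g. a
#' background terminal) is reclassified as `ineffective`.
#'
#' @param x a `tdrm_classification` from [validate_tracks()], or a
#'   `tdrm_tracks` object (then `tissue` is required and validation is run
#'   first).
#' @param tissue tissue [label_volume()] (only needed when `x` is a track set).
#' @param length_threshold_mm short/long association split, default 60.
#' @return The `tdrm_classification` with `class` filled for kept rows.
#' @export
classify_tracks <- function(x, tissue = NULL, length_threshold_mm = 60) {
  if (inherits(x, "tdrm_tracks")) {
    if (is.null(tissue)) stop("`tissue` is required to classify a track set",
                              call. = FALSE)
    x <- validate_tracks(x, tissue)
  }
  stopifnot(inherits(x, "tdrm_classification"))
  kept <- x$status == "kept"
  a <- x$label_a[kept]; b <- x$label_b[kept]; len <- x$length_mm[kept]
  cls <- rep(NA_character_, sum(kept))

  proj <- a == TISSUE_SUB | b == TISSUE_SUB
  comm <- !proj & ((a == TISSUE_CTX_L & b == TISSUE_CTX_R) |
                   (a == TISSUE_CTX_R & b == TISSUE_CTX_L))
  assoc <- !proj & !comm & a == b & a %in% c(TISSUE_CTX_L, TISSUE_CTX_R)
  cls[proj] <- "projection"
  cls[comm] <- "commissural"
  cls[assoc & len <  length_threshold_mm] <- "short_assoc"
  cls[assoc & len >= length_threshold_mm] <- "long_assoc"

  x$class[kept] <- cls
  leftover <- kept
  leftover[kept] <- is.na(cls)
  x$status[leftover] <- "ineffective"   # e.g. cortex<->background terminals
  x
}

#' @export
print.tdrm_classification <- function(x, ...) {
  n <- nrow(x)
  kept <- sum(x$status == "kept")
  cat(sprintf("Classified tracks: %d input, %d validated (%.1f%% excluded)\n",
              n, kept, 100 * (n - kept) / max(n, 1L)))
  if (kept > 0L) {
    tab <- table(factor(x$class[x$status == "kept"], levels = TDRM_CLASSES))
    for (cl in TDRM_CLASSES)
      cat(sprintf("  %-12s %8d (%.1f%%)\n", cl, tab[[cl]], 100 * tab[[cl]] / kept))
  }
  rej <- table(factor(x$status[x$status != "kept"], levels = TDRM_REJECTIONS))
  cat(sprintf("  rejected: %d noise (white-matter terminal), %d ineffective\n",
              rej[["noise_wm"]], rej[["ineffective"]]))
  invisible(x)
}

#' Per-subject classification summary
#'
#' @param object a `tdrm_classification`.
#' @param subject_id identifier recorded on the summary.
#' @param ... unused.
#' @return An object of class `tdrm_summary`: list with per-class counts,
#'   fractions of total validated (NA when nothing validated), rejection
#'   counts, totals and the exclusion percentage.
#' @export
summary.tdrm_classification <- function(object, subject_id = "subject", ...) {
  kept <- object$status == "kept"
  n_val <- sum(kept)
  n_tot <- nrow(object)
  counts <- table(factor(object$class[kept], levels = TDRM_CLASSES))
  counts <- stats::setNames(as.integer(counts), TDRM_CLASSES)
  fractions <- if (n_val > 0L) counts / n_val
               else stats::setNames(rep(NA_real_, 4L), TDRM_CLASSES)
  rej <- table(factor(object$status[!kept], levels = TDRM_REJECTIONS))
  structure(list(subject_id = subject_id,
                 counts = counts,
                 fractions = fractions,
                 rejections = stats::setNames(as.integer(rej), TDRM_REJECTIONS),
                 total_validated = n_val,
                 total_extracted = n_tot,
                 exclusion_pct = if (n_tot > 0L) 100 * (n_tot - n_val) / n_tot
                                 else NA_real_),
            class = "tdrm_summary")
}

#' @export
print.tdrm_summary <- function(x, ...) {
  cat(sprintf("Subject %s: %d / %d tracks validated (%.1f%% excluded)\n",
              x$subject_id, x$total_validated, x$total_extracted,
              x$exclusion_pct))
  for (cl in TDRM_CLASSES)
    cat(sprintf("  %-12s %8d  fraction %s\n", cl, x$counts[[cl]],
                formatC(x$fractions[[cl]], digits = 4, format = "f")))
  invisible(x)
}

#' Flag outlier subjects by validated-track count and commissural fraction
#'
#' Screens a group of classification summaries for subjects whose total
#' validated-track count or commissural fraction falls outside
#' median +/- k * MAD of the group. Flags are advisory: they are reported,
#' never auto-excluded.
#'
#' @param summaries list of `tdrm_summary` objects (>= 3).
#' @param k_mad robust threshold in MAD units, default 3.5.
#' @return data.frame with one row per subject: `subject_id`,
#'   `total_validated`, `commissural_fraction`, per-criterion flags and an
#'   overall `flagged`.
#' @export
flag_outlier_subjects <- function(summaries, k_mad = 3.5) {
  if (length(summaries) < 3L)
    stop("outlier screening needs at least 3 subjects", call. = FALSE)
  tot <- vapply(summaries, function(s) as.numeric(s$total_validated), numeric(1))
  cf <- vapply(summaries, function(s) s$fractions[["commissural"]], numeric(1))
  ids <- vapply(summaries, function(s) s$subject_id, character(1))
  outside <- function(v) {
    med <- stats::median(v)
    m <- stats::mad(v)           # constant 1.4826 for normal consistency
    if (m == 0) v != med else abs(v - med) > k_mad * m
  }
  f_tot <- outside(tot)
  f_cf <- outside(cf)
  data.frame(subject_id = ids, total_validated = tot,
             commissural_fraction = cf,
             flag_total = f_tot, flag_commissural = f_cf,
             flagged = f_tot | f_cf,
             stringsAsFactors = FALSE)
}
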