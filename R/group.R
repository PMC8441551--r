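# Group analysis over subjects already in a common (template) space:
# voxel-wise averaging of density volumes, per-parcel mean/SD tables, and
# paired hemispheric-asymmetry tests over homotopic parcels.

#' Voxel-wise mean of density volumes
#'
#' All volumes must share grid shape and affine (i.e. be in a common
#' template space; spatial normalisation itself is out of scope here).
#' Intensity transforms are meant to be applied to the averaged densities,
#' not before averaging.
#'
#' @param volumes list of `tdrm_density` objects.
#' @return A `tdrm_density` whose `counts` are the per-voxel, per-channel
#'   arithmetic means (floating point).
#' @export
average_density_volumes <- function(volumes) {
  if (length(volumes) < 1L) stop("need at least one volume", call. = FALSE)
  ref <- volumes[[1L]]
  acc <- ref$counts * 1.0
  for (i in seq_along(volumes)[-1L]) {
    v <- volumes[[i]]
    if (!identical(dim(v$counts), dim(ref$counts)) ||
        max(abs(v$affine - ref$affine)) > 1e-6)
      stop("density volume ", i, " is not on the common grid", call. = FALSE)
    acc <- acc + v$counts
  }
  structure(list(counts = acc / length(volumes), affine = ref$affine,
                 channels = ref$channels),
            class = "tdrm_density")
}

parcel_density_matrix <- function(tab) {
  cols <- paste0("density_", TDRM_CLASSES)
  m <- as.matrix(tab[tab$label > 0L, cols])
  rownames(m) <- tab$label[tab$label > 0L]
  m
}

check_common_labels <- function(tables) {
  ref <- tables[[1L]]$label
  for (i in seq_along(tables)[-1L])
    if (!identical(tables[[i]]$label, ref))
      stop("parcel table ", i, " has a different label set", call. = FALSE)
  invisible(ref)
}

#' Group mean and SD of relative parcel densities
#'
#' Per parcel label and fiber class, the across-subject mean and sample
#' standard deviation (n - 1 denominator) of the relative density
#' `tracks_amount / piece_volume`; plus per-class hemisphere means, computed
#' as unweighted means over the labels of each hemisphere.
#'
#' @param tables list of `tdrm_parcel_density` tables (>= 2 subjects,
#'   identical label sets).
#' @return An object of class `tdrm_group`: list with `per_label`
#'   (data.frame of mean/SD per label x class), `hemisphere_means`
#'   (data.frame hemisphere x class), `n_subjects`.
#' @export
group_parcel_stats <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 subjects", call. = FALSE)
  check_common_labels(tables)
  mats <- lapply(tables, parcel_density_matrix)
  arr <- simplify2array(mats)                     # label x class x subject
  mean_m <- apply(arr, 1:2, mean)
  sd_m <- apply(arr, 1:2, stats::sd)
  meta <- tables[[1L]][tables[[1L]]$label > 0L,
                       c("label", "name", "hemisphere", "lobe_group")]
  per_label <- cbind(meta,
                     stats::setNames(as.data.frame(mean_m),
                                     paste0("mean_", TDRM_CLASSES)),
                     stats::setNames(as.data.frame(sd_m),
                                     paste0("sd_", TDRM_CLASSES)))
  rownames(per_label) <- NULL

  hemis <- lapply(c(L = "L", R = "R"), function(h) {
    colMeans(mean_m[meta$hemisphere == h, , drop = FALSE])
  })
  hemisphere_means <- data.frame(hemisphere = c("L", "R"),
                                 do.call(rbind, hemis),
                                 row.names = NULL)
  names(hemisphere_means)[-1L] <- TDRM_CLASSES
  hemisphere_means$total_assoc <- hemisphere_means$short_assoc +
    hemisphere_means$long_assoc
  hemisphere_means$total <- rowSums(hemisphere_means[, TDRM_CLASSES])

  structure(list(per_label = per_label, hemisphere_means = hemisphere_means,
                 n_subjects = length(tables)),
            class = "tdrm_group")
}

#' @export
print.tdrm_group <- function(x, ...) {
  cat(sprintf("Group parcel statistics over %d subjects, %d parcels\n",
              x$n_subjects, nrow(x$per_label)))
  cat("Hemisphere means (relative density, unweighted over labels):\n")
  print(format(x$hemisphere_means, digits = 4), row.names = FALSE)
  invisible(x)
}

# paired two-sided t statistic and p via the t distribution; the reference
# implementation stats::t.test is used as a cross-check in the tests, never
# here
paired_t <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0))
      return(list(statistic = NA_real_, p = 1, degenerate = FALSE))
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(statistic = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       degenerate = FALSE)
}

#' Hemispheric asymmetry test over homotopic parcels
#'
#' For one fiber class and a set of homotopic parcels (paired across
#' hemispheres by shared `name`), each subject contributes one pair: the
#' unweighted mean relative density over the set's labels per hemisphere.
#' The left-minus-right differences are tested two-sided, by a paired t-test
#' (default) or a Wilcoxon signed-rank test.
#'
#' @param tables list of `tdrm_parcel_density` tables (>= 3 subjects).
#' @param class one of `"projection"`, `"commissural"`, `"short_assoc"`,
#'   `"long_assoc"`, `"total_assoc"`, `"total"`.
#' @param names parcel names to pool (default: all homotopic pairs).
#' @param test `"t"` or `"wilcoxon"`.
#' @return An object of class `tdrm_asymmetry`: list with `class`, `names`,
#'   `n`, `statistic`, `p_value`, `direction` (`"LH>RH"`, `"RH>LH"` or
#'   `"none"`), `mean_diff`, `degenerate`, `test`.
#' @export
hemispheric_asymmetry <- function(tables, class = "long_assoc", names = NULL,
                                  test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(tables) < 3L) stop("need at least 3 subjects", call. = FALSE)
  check_common_labels(tables)
  if (!class %in% c(TDRM_CLASSES, "total_assoc", "total"))
    stop("unknown fiber class: ", class, call. = FALSE)
  col <- switch(class,
                total_assoc = c("density_short_assoc", "density_long_assoc"),
                total = paste0("density_", TDRM_CLASSES),
                paste0("density_", class))

  ref <- tables[[1L]]
  parc <- ref[ref$label > 0L, ]
  if (is.null(names)) names <- unique(parc$name)
  sel <- parc$name %in% names
  if (!any(sel)) stop("no parcels match the requested names", call. = FALSE)
  by_name <- split(parc$label[sel], parc$name[sel])
  paired <- vapply(by_name, function(l) {
    h <- parc$hemisphere[match(l, parc$label)]
    length(l) == 2L && setequal(h, c("L", "R"))
  }, logical(1))
  if (!all(paired))
    stop("unpaired parcels (need one L and one R label per name): ",
         paste(names(by_name)[!paired], collapse = ", "), call. = FALSE)
  lab_L <- vapply(by_name, function(l) l[parc$hemisphere[match(l, parc$label)] == "L"],
                  integer(1))
  lab_R <- vapply(by_name, function(l) l[parc$hemisphere[match(l, parc$label)] == "R"],
                  integer(1))

  subj_means <- function(tab, labels) {
    rows <- match(labels, tab$label)
    mean(rowSums(as.matrix(tab[rows, col, drop = FALSE])))
  }
  lh <- vapply(tables, subj_means, numeric(1), labels = lab_L)
  rh <- vapply(tables, subj_means, numeric(1), labels = lab_R)
  d <- lh - rh

  if (test == "t") {
    r <- paired_t(d)
  } else {
    if (all(d == 0)) {
      r <- list(statistic = NA_real_, p = 1, degenerate = FALSE)
    } else {
      w <- suppressWarnings(stats::wilcox.test(d, alternative = "two.sided"))
      r <- list(statistic = unname(w$statistic), p = w$p.value,
                degenerate = FALSE)
    }
  }
  direction <- if (all(d == 0) || mean(d) == 0) "none"
               else if (mean(d) > 0) "LH>RH" else "RH>LH"
  structure(list(class = class, names = names, n = length(d),
                 statistic = r$statistic, p_value = r$p,
                 direction = direction, mean_diff = mean(d),
                 degenerate = r$degenerate, test = test),
            class = "tdrm_asymmetry")
}

#' @export
print.tdrm_asymmetry <- function(x, ...) {
  cat(sprintf("Hemispheric asymmetry (%s, %s test, n = %d pairs)\n",
              x$class, x$test, x$n))
  if (x$degenerate) {
    cat(sprintf("  degenerate: constant nonzero difference %.4g, p undefined\n",
                x$mean_diff))
  } else {
    cat(sprintf("  direction %s, mean LH-RH difference %.4g, p = %.4g\n",
                x$direction, x$mean_diff, x$p_value))
  }
  invisible(x)
}

LOBE_COLORS <- c(frontal = "red", parietal = "blue", temporal = "green",
                 limbic = "magenta", insular = "cyan", occipital = "yellow")

#' Plot-ready per-label table with LH/RH values and lobe color keys
#'
#' Emits one row per homotopic parcel name, ordered by atlas label, with the
#' left and right hemisphere group means and SDs side by side and the lobe
#' color key (frontal red, parietal blue, temporal green, limbic magenta,
#' insular cyan, occipital yellow).
#'
#' @param group a `tdrm_group` from [group_parcel_stats()].
#' @param class fiber class column to extract (as in
#'   [hemispheric_asymmetry()], excluding the totals).
#' @return data.frame with columns `name`, `label_L`, `label_R`,
#'   `lobe_group`, `lobe_color`, `mean_L`, `sd_L`, `mean_R`, `sd_R`.
#' @export
lobe_grouped_bars <- function(group, class = "projection") {
  stopifnot(inherits(group, "tdrm_group"))
  if (!class %in% TDRM_CLASSES) stop("unknown fiber class: ", class, call. = FALSE)
  pl <- group$per_label
  lh <- pl[pl$hemisphere == "L", ]
  rh <- pl[pl$hemisphere == "R", ]
  lh <- lh[order(lh$label), ]
  rh <- rh[match(lh$name, rh$name), ]
  if (anyNA(rh$label)) stop("unpaired parcels in group result", call. = FALSE)
  data.frame(name = lh$name, label_L = lh$label, label_R = rh$label,
             lobe_group = lh$lobe_group,
             lobe_color = unname(LOBE_COLORS[lh$lobe_group]),
             mean_L = lh[[paste0("mean_", class)]],
             sd_L = lh[[paste0("sd_", class)]],
             mean_R = rh[[paste0("mean_", class)]],
             sd_R = rh[[paste0("sd_", class)]],
             stringsAsFactors = FALSE)
}
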