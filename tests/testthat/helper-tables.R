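# Build a parcel-density table directly from a density matrix
# (rows = parcel labels in lookup order, cols = the four classes),
# for group-level tests that do not need a full phantom run.

make_lookup <- function(n_per_hemi) {
  data.frame(label = seq_len(2L * n_per_hemi),
             name = rep(sprintf("pair_%02d", seq_len(n_per_hemi)), 2L),
             hemisphere = rep(c("L", "R"), each = n_per_hemi),
             lobe_group = rep(rep(c("frontal", "parietal", "temporal",
                                    "limbic", "insular", "occipital"),
                                  length.out = n_per_hemi), 2L),
             stringsAsFactors = FALSE)
}

make_parcel_table <- function(lookup, dens, piece_volume = 1000) {
  stopifnot(nrow(dens) == nrow(lookup), ncol(dens) == 4L)
  out <- data.frame(label = c(lookup$label, 0L),
                    name = c(lookup$name, "unassigned"),
                    hemisphere = c(lookup$hemisphere, NA),
                    lobe_group = c(lookup$lobe_group, NA),
                    piece_volume_mm3 = c(rep(piece_volume, nrow(lookup)), NA),
                    stringsAsFactors = FALSE)
  classes <- c("projection", "commissural", "short_assoc", "long_assoc")
  for (j in 1:4) {
    out[[paste0("tracks_", classes[j])]] <-
      c(as.integer(round(dens[, j] * piece_volume)), 0L)
    out[[paste0("density_", classes[j])]] <- c(dens[, j], NA)
  }
  out$tracks_total <- c(as.integer(round(rowSums(dens) * piece_volume)), 0L)
  out$density_total <- c(rowSums(dens), NA)
  class(out) <- c("tdrm_parcel_density", "data.frame")
  out
}

# a random density volume for group-averaging tests
rand_density <- function(seed, shape = c(6, 6, 6)) {
  set.seed(seed)
  structure(list(counts = array(rpois(prod(shape) * 4, 1.5), c(shape, 4L)),
                 affine = diag(4), channels = TDRM_CLASSES),
            class = "tdrm_density")
}

# classification data.frame built directly (for density-module tests where
# the terminal compartments are dictated, not looked up)
make_classification <- function(label_a, label_b, length_mm, class,
                                status = "kept") {
  out <- data.frame(index = seq_along(label_a), label_a = label_a,
                    label_b = label_b, length_mm = length_mm,
                    status = status, class = class, stringsAsFactors = FALSE)
  class(out) <- c("tdrm_classification", "data.frame")
  out
}
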