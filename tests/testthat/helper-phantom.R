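# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# modest phantom reused across module tests
small_phantom <- function() {
  cached("small", function() build_phantom(phantom_spec(
    grid_shape = c(50L, 50L, 50L),
    counts = c(projection = 80L, commissural = 90L, short_assoc = 140L,
               long_assoc = 120L, noise_wm = 40L, ineffective = 20L),
    n_parcels_per_hemisphere = 4L, seed = 42L)))
}

small_classified <- function() {
  cached("small_cl", function() {
    ph <- small_phantom()
    classify_tracks(ph$tracks, ph$tissue)
  })
}

# full-size phantom at the study mix (10,000 classifiable + 1,500 rejects)
study_phantom <- function() {
  cached("study", function() build_phantom(phantom_spec(seed = 1L)))
}

# a hand-laid tissue volume, identity affine: one voxel of each compartment
# at a known index, everything else background
unit_tissue <- function() {
  lab <- array(0L, c(12L, 12L, 12L))
  lab[2, 2, 2] <- 1L   # white matter at world (1,1,1)
  lab[4, 2, 2] <- 2L   # left cortex at (3,1,1)
  lab[6, 2, 2] <- 3L   # right cortex at (5,1,1)
  lab[8, 2, 2] <- 4L   # subcortical at (7,1,1)
  label_volume(lab, diag(4), "tissue")
}

# two-point streamline between two world points
seg <- function(a, b) rbind(a, b)

# world coordinates of the compartment voxels in unit_tissue()
UT <- list(bg = c(0, 0, 0), wm = c(1, 1, 1), ctxL = c(3, 1, 1),
           ctxR = c(5, 1, 1), sub = c(7, 1, 1))
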