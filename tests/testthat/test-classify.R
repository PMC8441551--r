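test_that("streamline arc length is the polyline sum of segment lengths", {
  expect_equal(streamline_length(seg(c(0, 0, 0), c(0, 0, 10))), 10)
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))), 17)
  expect_error(streamline_length(matrix(0, 1, 3)), "at least 2")
})

test_that("vectorised length matches a naive per-segment loop on 1,000 random polylines", {
  set.seed(21)
  rel_err <- replicate(1000, {
    n <- sample(2:30, 1)
    p <- matrix(runif(3 * n, -100, 100), n, 3)
    naive <- 0
    for (i in 2:n) naive <- naive + sqrt(sum((p[i, ] - p[i - 1, ])^2))
    abs(streamline_length(p) - naive) / naive
  })
  expect_lt(max(rel_err), 1e-9)
})

test_that("validation rejects white-matter and non-cortical terminals with the right precedence", {
  tis <- unit_tissue()
  ts <- track_set(list(
    seg(UT$wm, UT$ctxR),    # (1,3): noise despite cortical terminal
    seg(UT$sub, UT$sub),    # (4,4): ineffective
    seg(UT$ctxL, UT$sub),   # (2,4): kept
    seg(UT$wm, UT$wm),      # (1,1): noise takes precedence over ineffective
    seg(UT$bg, UT$bg),      # (0,0): ineffective
    seg(UT$ctxL, UT$ctxR))) # (2,3): kept
  v <- validate_tracks(ts, tis)
  expect_identical(v$status, c("noise_wm", "ineffective", "kept",
                               "noise_wm", "ineffective", "kept"))
  expect_identical(v$label_a, c(1L, 4L, 2L, 1L, 0L, 2L))
})

test_that("classification follows the terminal-compartment decision order", {
  tis <- unit_tissue()
  far <- c(3, 1, 130)                  # off-volume: background, 129 mm away
  ts <- track_set(list(
    seg(UT$ctxL, UT$sub),                       # projection
    rbind(UT$ctxL, c(3, 1, 119), UT$ctxR),      # commissural, length >> 60
    seg(UT$ctxR, UT$ctxR + c(0, 0.2, 0)),       # short association
    rbind(UT$ctxR, c(5, 1, 40), UT$ctxR + c(0.2, 0, 0)),  # long association
    seg(UT$ctxL, UT$bg)))                       # cortex<->background
  cl <- classify_tracks(ts, tis)
  expect_identical(cl$class[1:4], c("projection", "commissural",
                                    "short_assoc", "long_assoc"))
  # commissural regardless of length
  expect_gt(cl$length_mm[2], 60)
  # background-terminal combination is reclassified, not invented
  expect_identical(cl$status[5], "ineffective")
  expect_true(is.na(cl$class[5]))
})

test_that("the 6 cm split is half-open: 60.000 mm is long, just under is short", {
  # straight tracks inside one cortical slab, lengths set exactly
  lab <- array(2L, c(70L, 3L, 3L))
  tis <- label_volume(lab, diag(4), "tissue")
  mk <- function(len) seg(c(1, 1, 1), c(1 + len, 1, 1))
  ts <- track_set(list(mk(59.9), mk(60.1), mk(59.999), mk(60.0)))
  cl <- classify_tracks(ts, tis)
  expect_identical(cl$class, c("short_assoc", "long_assoc",
                               "short_assoc", "long_assoc"))
})

test_that("classification is invariant to point-order reversal", {
  ph <- small_phantom()
  cl <- small_classified()
  rev_tracks <- track_set(lapply(ph$tracks$streamlines,
                                 function(p) p[nrow(p):1, , drop = FALSE]),
                          space_id = ph$tracks$space_id)
  cl_rev <- classify_tracks(rev_tracks, ph$tissue)
  expect_identical(cl_rev$class, cl$class)
  expect_identical(cl_rev$status, cl$status)
})

test_that("lengthening a same-hemisphere track across 60 mm flips short to long only", {
  lab <- array(2L, c(100L, 3L, 3L))          # left-cortex slab
  tis <- label_volume(lab, diag(4), "tissue")
  lens <- c(20, 40, 59, 61, 80, 120)
  cls <- vapply(lens, function(L) {
    # scale the detour until the polyline length is exactly L
    f <- function(s) streamline_length(rbind(c(1, 1, 1), c(1 + s, 1.5, 1), c(1, 1.2, 1.4))) - L
    s <- uniroot(f, c(0.1, 200))$root
    ts <- track_set(list(rbind(c(1, 1, 1), c(1 + s, 1.5, 1), c(1, 1.2, 1.4))))
    classify_tracks(ts, tis)$class
  }, character(1))
  expect_identical(cls, ifelse(lens < 60, "short_assoc", "long_assoc"))
  # projection/commissural labels never depend on length
  tisu <- unit_tissue()
  for (L in c(10, 200)) {
    p <- rbind(UT$ctxL, c(3, 1, L / 2), UT$sub)
    expect_identical(classify_tracks(track_set(list(p)), tisu)$class, "projection")
  }
})

test_that("classes partition the validated tracks and recover phantom truth exactly", {
  ph <- small_phantom()
  cl <- small_classified()
  kept <- cl$status == "kept"
  expect_true(all(!is.na(cl$class[kept])))
  expect_true(all(is.na(cl$class[!kept])))
  expect_true(all(cl$class[kept] %in% TDRM_CLASSES))
  pred <- ifelse(kept, cl$class, cl$status)
  expect_identical(pred, ph$truth$truth)
})

test_that("summaries report counts, fractions and exclusion percentage", {
  cl <- small_classified()
  s <- summary(cl, subject_id = "ph42")
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(s$counts),
               c(80L, 90L, 140L, 120L))
  expect_equal(s$total_validated, 430L)
  expect_equal(s$exclusion_pct, 100 * 60 / 490)

  # degenerate: nothing validated
  empty <- make_classification(label_a = c(1L, 1L), label_b = c(1L, 1L),
                               length_mm = c(5, 5), class = NA_character_,
                               status = "noise_wm")
  s0 <- summary(empty)
  expect_true(all(is.na(s0$fractions)))
  expect_equal(s0$total_validated, 0L)

  # 5,000 tracks of which 4,500 rejected -> 90.0% excluded
  big <- make_classification(label_a = rep(1L, 5000), label_b = rep(1L, 5000),
                             length_mm = rep(10, 5000), class = NA_character_,
                             status = c(rep("kept", 500), rep("noise_wm", 4500)))
  big$class[big$status == "kept"] <- "projection"
  expect_equal(summary(big)$exclusion_pct, 90.0)
})

test_that("outlier screening flags gross deviants in count or commissural fraction", {
  mk <- function(id, total, frac_comm) {
    counts <- c(projection = round(total * 0.2), commissural = round(total * frac_comm),
                short_assoc = round(total * 0.3),
                long_assoc = 0L)
    counts["long_assoc"] <- total - sum(counts[1:3])
    structure(list(subject_id = id, counts = counts,
                   fractions = counts / total, total_validated = total,
                   total_extracted = total * 10L,
                   rejections = c(noise_wm = 0L, ineffective = 0L),
                   exclusion_pct = 90), class = "tdrm_summary")
  }
  grp <- c(lapply(1:15, function(i) mk(paste0("S", i), 400000L, 0.2)),
           list(mk("S16", 4000000L, 0.2)))
  fl <- flag_outlier_subjects(grp)
  expect_identical(fl$subject_id[fl$flagged], "S16")

  none <- flag_outlier_subjects(lapply(1:6, function(i) mk(paste0("S", i), 400000L, 0.2)))
  expect_false(any(none$flagged))

  # planted 2-sigma and 6-sigma deviants around a spread group
  base <- 400000L + seq(-7L, 8L) * 1000L
  sdv <- stats::mad(base)
  grp2 <- lapply(seq_along(base), function(i) mk(paste0("T", i), base[i], 0.2))
  grp2[[17]] <- mk("dev2", as.integer(stats::median(base) + 2 * sdv), 0.2)
  grp2[[18]] <- mk("dev6", as.integer(stats::median(base) + 6 * sdv), 0.2)
  fl2 <- flag_outlier_subjects(grp2, k_mad = 3.5)
  med <- stats::median(fl2$total_validated)
  md <- stats::mad(fl2$total_validated)
  expect_identical(fl2$subject_id[fl2$flagged],
                   fl2$subject_id[abs(fl2$total_validated - med) > 3.5 * md])
  expect_true("dev6" %in% fl2$subject_id[fl2$flagged])
  expect_false("dev2" %in% fl2$subject_id[fl2$flagged])

  expect_error(flag_outlier_subjects(grp[1:2]), "at least 3")
})
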