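make_lm <- function(y_head, y_t1, y_t12, y_foot, x = 0) {
  body_landmarks(c(x, y_head), c(x, y_t1), c(x, y_t12), c(x, y_foot))
}

test_that("subject height and ratios follow the landmark arithmetic", {
  lm <- make_lm(1000, 880, 560, 0)
  expect_equal(subject_height(lm), 1000)
  expect_equal(subject_ratios(lm), c(r1 = 0.12, r2 = 0.32, r3 = 0.56))

  lm2 <- make_lm(900, 600, 300, 0)
  expect_equal(unname(subject_ratios(lm2)), rep(1 / 3, 3))

  expect_equal(subject_height(make_lm(5, 4.6, 4.2, 4)), 1)
  expect_error(make_lm(100, 100, 50, 0), "ordering")
  expect_error(make_lm(100, 50, 50, 0), "ordering")
})

test_that("ratios telescope to one for arbitrary valid landmarks", {
  set.seed(1)
  for (i in 1:50) {
    ys <- sort(runif(4, 0, 1000), decreasing = TRUE)
    lm <- make_lm(ys[1], ys[2], ys[3], ys[4])
    expect_equal(sum(subject_ratios(lm)), 1, tolerance = 1e-12)
  }
})

test_that("cohort averaging is the component-wise mean and preserves the sum", {
  a <- make_lm(1000, 900, 600, 0)     # (0.10, 0.30, 0.60)
  b <- make_lm(1000, 860, 600, 0)     # (0.14, 0.26, 0.60)
  avg <- average_ratios(list(a, b))
  expect_equal(as.numeric(avg), c(0.12, 0.28, 0.60), tolerance = 1e-12)
  expect_equal(sum(avg), 1, tolerance = 1e-12)
  # N = 1 identity
  expect_equal(as.numeric(average_ratios(list(a))),
               unname(subject_ratios(a)))
  expect_error(average_ratios(list()), "at least one")
})

test_that("ratio constructor validates its invariants", {
  expect_error(landmark_ratios(c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(landmark_ratios(c(0, 0.4, 0.6)), "strictly")
  expect_silent(landmark_ratios(c(0.12, 0.28, 0.60)))
})

test_that("landmark localization hits the generator's ground-truth rows", {
  sp <- synth_spec(rows = 600, cols = 400, height_px = 500, theta = 25,
                   ratios = c(0.12, 0.28, 0.60))
  s <- generate_subject(sp)
  lm <- locate_landmarks(s$mask, s$ratios)
  n_rows <- nrow(s$mask)
  expect_equal(y_to_row(lm$head[2], n_rows), s$rows[["head"]])
  expect_equal(y_to_row(lm$foot[2], n_rows), s$rows[["foot"]])
  expect_lte(abs(y_to_row(lm$t1[2], n_rows) - s$rows[["t1"]]), 1)
  expect_lte(abs(y_to_row(lm$t12[2], n_rows) - s$rows[["t12"]]), 1)
})

test_that("single-column mask with equal thirds puts T1 at H/3 from the top", {
  mask <- matrix(0L, 90, 5)
  mask[10:70, 3] <- 1L
  thirds <- rep(1, 3) / 3
  lm <- locate_landmarks(mask, landmark_ratios(thirds), facing = "left")
  expect_equal(y_to_row(lm$t1[2], 90), 30)   # head row 10 + 60/3
  expect_equal(y_to_row(lm$t12[2], 90), 50)
})

test_that("localization is invariant to translation and mirrors with facing", {
  s <- generate_subject(synth_spec(rows = 700, cols = 450, height_px = 600,
                                   theta = 30))
  r <- s$ratios
  lm <- locate_landmarks(s$mask, r)
  # vertical translation: pad 40 empty rows on top, drop 40 at the bottom
  shifted <- rbind(matrix(0L, 40, ncol(s$mask)),
                   s$mask[1:(nrow(s$mask) - 40), ])
  lm_s <- locate_landmarks(shifted, r)
  expect_equal(y_to_row(lm_s$t1[2], nrow(shifted)),
               y_to_row(lm$t1[2], nrow(s$mask)) + 40)
  # horizontal mirror with flipped facing: same rows, mirrored columns
  mirrored <- s$mask[, rev(seq_len(ncol(s$mask)))]
  lm_m <- locate_landmarks(mirrored, r)
  expect_equal(lm_m$t1[2], lm$t1[2])
  expect_equal(lm_m$t12[2], lm$t12[2])
  expect_equal(lm_m$t1[1], ncol(s$mask) + 1 - lm$t1[1])
})

test_that("empty or broken masks raise localization errors", {
  expect_error(locate_landmarks(matrix(0L, 10, 10),
                                landmark_ratios(c(0.12, 0.28, 0.6))),
               "empty mask")
  s <- generate_subject(synth_spec(rows = 600, cols = 400, height_px = 500))
  lm <- locate_landmarks(s$mask, s$ratios)
  broken <- s$mask
  broken[s$rows[["t1"]] + 5, ] <- 0L
  expect_error(dorsal_contour(broken, lm), "broken silhouette")
})

test_that("dorsal contour is flat on a rectangular torso and smoothing is a no-op on clean masks", {
  mask <- matrix(0L, 200, 100)
  mask[20:180, 30:70] <- 1L
  lm <- locate_landmarks(mask, landmark_ratios(c(0.12, 0.28, 0.60)),
                         facing = "right")
  c1 <- dorsal_contour(mask, lm, smooth = 1)
  c5 <- dorsal_contour(mask, lm, smooth = 5)
  expect_equal(c1, c5)
  expect_true(all(c1[, "x"] == c1[1, "x"]))
  cd <- chord_depth_from_contour(c1, lm$t1, lm$t12)
  expect_equal(cd$d, 0)
})

test_that("dorsal contour of a generated arc recovers the sagitta within a pixel", {
  sp <- synth_spec(rows = 900, cols = 520, height_px = 800, theta = 35)
  s <- generate_subject(sp)
  lm <- locate_landmarks(s$mask, s$ratios)
  contour <- dorsal_contour(s$mask, lm)
  cd <- chord_depth_from_contour(contour, lm$t1, lm$t12)
  expect_lte(abs(cd$d - s$d_px), 1)
  expect_equal(cd$L, s$L_px)
})

test_that("annotation round-trip: CSV in image-row convention calibrates correctly", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  # one subject, image of 1000 rows, head row 99, T1 219, T12 499, foot 999
  write.csv(data.frame(subject_id = "A", x_head = 50, y_head_row = 99,
                       x_t1 = 60, y_t1_row = 219, x_t12 = 60, y_t12_row = 499,
                       x_foot = 55, y_foot_row = 999),
            tmp, row.names = FALSE)
  lms <- read_landmark_annotations(tmp, n_rows = 1000)
  expect_equal(unname(subject_ratios(lms[["A"]])),
               c(120, 280, 500) / 900, tolerance = 1e-12)
})
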