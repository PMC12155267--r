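#' Calibrate proportion ratios from an annotation file
#'
#' Reads a landmark annotation CSV (see [read_landmark_annotations()]),
#' averages the per-subject proportion ratios, and optionally persists the
#' result as JSON with provenance (cohort size, input file hash).
#'
#' @param annotations path to the annotation CSV, or a list of
#'   [body_landmarks()] objects.
#' @param n_rows image height in rows (needed to flip CSV row indices).
#' @param out optional path of a JSON file to write the ratios to.
#' @return a [landmark_ratios()] object.
#' @export
calibrate <- function(annotations, n_rows = NULL, out = NULL) {
  if (is.character(annotations)) {
    if (is.null(n_rows))
      stop("`n_rows` is required when calibrating from a CSV", call. = FALSE)
    lms <- read_landmark_annotations(annotations, n_rows)
  } else {
    lms <- annotations
  }
  ratios <- average_ratios(lms)
  if (!is.null(out)) {
    payload <- list(r1 = ratios[["r1"]], r2 = ratios[["r2"]],
                    r3 = ratios[["r3"]], n = attr(ratios, "n"))
    if (is.character(annotations))
      payload$input_md5 <- unname(tools::md5sum(annotations))
    jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
  }
  ratios
}

#' Load calibrated ratios from JSON
#'
#' @param path JSON file written by [calibrate()].
#' @return a [landmark_ratios()] object.
#' @export
read_ratios <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_ratios(c(j$r1, j$r2, j$r3), n = if (is.null(j$n)) NA else j$n)
}

#' Measure the kyphosis angle of one subject
#'
#' Runs the full measurement chain: segmentation (skipped when a binary
#' mask is supplied directly), mask cleanup, landmark localization from the
#' calibrated ratios, dorsal-contour extraction between the T1 and T12
#' rows, chord/depth measurement, and the angle formula. All lengths are
#' in pixels; the angle is scale invariant, so no pixel-to-cm conversion
#' is needed.
#'
#' @param input an RGB image array, a 0/1 mask matrix, or a path to a
#'   PNG/JPEG file (read as a mask if single-channel binary, as an image
#'   otherwise).
#' @param ratios a [landmark_ratios()] object (or length-3 vector).
#' @param is_mask force treating `input` as a binary mask.
#' @param backend segmentation backend id (used only for images).
#' @param facing facing side (`"auto"`, `"left"`, `"right"`).
#' @param smooth dorsal-contour running-median window (odd, rows).
#' @param subject_id identifier recorded in the result.
#' @return object of class `kyphosis_measurement`: list with `subject_id`,
#'   `theta` (degrees), `L_px`, `d_px`, `landmarks`, `backend`, `dorsal`.
#' @export
measure_kyphosis <- function(input, ratios, is_mask = NA, backend = "threshold",
                             facing = "auto", smooth = 5L,
                             subject_id = NA_character_) {
  if (!inherits(ratios, "landmark_ratios")) ratios <- landmark_ratios(ratios)
  if (is.character(input)) {
    img <- read_rgb(input)
    flat <- img[, , 1]
    is_binary <- all(abs(img[, , 1] - img[, , 2]) < 1e-9) &&
      length(unique(round(as.vector(flat), 6))) <= 2L
    input <- if (isTRUE(is_mask) || (is.na(is_mask) && is_binary)) {
      .as_mask(flat)
    } else img
  }
  used_backend <- NA_character_
  if (is.matrix(input) && (isTRUE(is_mask) || is.na(is_mask))) {
    mask <- postprocess_mask(.as_mask(input))
  } else {
    mask <- segment_person(input, backend = backend)
    used_backend <- backend
  }
  if (sum(mask) == 0L) stop("empty mask", call. = FALSE)
  lm <- locate_landmarks(mask, ratios, facing = facing)
  contour <- dorsal_contour(mask, lm, smooth = smooth)
  cd <- chord_depth_from_contour(contour, lm$t1, lm$t12)
  theta <- kyphosis_angle(cd$L, cd$d)
  structure(list(subject_id = subject_id, theta = theta,
                 L_px = cd$L, d_px = cd$d, landmarks = lm,
                 backend = used_backend, dorsal = attr(lm, "dorsal")),
            class = "kyphosis_measurement")
}

#' @export
print.kyphosis_measurement <- function(x, ...) {
  id <- if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]")
  cat(sprintf("Kyphosis measurement%s: theta = %.3f deg (L = %.1f px, d = %.2f px, back: %s)\n",
              id, x$theta, x$L_px, x$d_px, x$dorsal))
  invisible(x)
}

#' Measure a batch of subjects
#'
#' Applies [measure_kyphosis()] to a list of inputs (masks, images or
#' paths), collecting one row per subject. Per-subject failures are caught
#' and recorded as a warning string; the batch continues.
#'
#' @param inputs named list (or vector of paths); names become subject ids.
#' @param ratios calibrated [landmark_ratios()].
#' @param ... passed to [measure_kyphosis()].
#' @return data frame with columns `subject_id`, `theta_deg`, `L_px`,
#'   `d_px`, `warning` (angles reported to 3 decimals in the CSV writer;
#'   full precision here).
#' @export
measure_batch <- function(inputs, ratios, ...) {
  ids <- names(inputs)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(inputs))
  rows <- lapply(seq_along(inputs), function(i) {
    rec <- tryCatch(measure_kyphosis(inputs[[i]], ratios,
                                     subject_id = ids[i], ...),
                    error = function(e) e)
    if (inherits(rec, "error"))
      data.frame(subject_id = ids[i], theta_deg = NA_real_, L_px = NA_real_,
                 d_px = NA_real_, warning = conditionMessage(rec))
    else
      data.frame(subject_id = ids[i], theta_deg = rec$theta, L_px = rec$L_px,
                 d_px = rec$d_px, warning = NA_character_)
  })
  do.call(rbind, rows)
}

#' Write measurement records to CSV
#'
#' Angles are written to 3 decimal places.
#'
#' @param records data frame from [measure_batch()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  out <- records
  num <- intersect(c("theta_deg", "L_px", "d_px"), names(out))
  for (cl in num) out[[cl]] <- round(out[[cl]], 3)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate predicted angles against a reference
#'
#' Joins predicted measurements with reference (gold standard) angles by
#' subject id and computes the method-agreement report: Spearman rho, ICC
#' with 95% CI, Cronbach's alpha and per-method descriptives.
#'
#' @param records data frame with `subject_id` and `theta_deg` (predicted).
#' @param reference data frame with `subject_id` and a reference angle
#'   column.
#' @param ref_col name of the reference angle column.
#' @param icc_form passed to [icc()].
#' @return a [reliability_report()].
#' @export
validate_measurements <- function(records, reference,
                                  ref_col = "actual_angle_deg",
                                  icc_form = "agreement") {
  if (!all(c("subject_id", "theta_deg") %in% names(records)))
    stop("`records` needs subject_id and theta_deg columns", call. = FALSE)
  if (!ref_col %in% names(reference))
    stop("reference column `", ref_col, "` not found", call. = FALSE)
  merged <- merge(records, reference, by = "subject_id")
  missing <- setdiff(union(records$subject_id, reference$subject_id),
                     merged$subject_id)
  if (nrow(merged) == 0L)
    stop("no common subject ids; offenders: ",
         paste(missing, collapse = ", "), call. = FALSE)
  reliability_report(merged[[ref_col]], merged$theta_deg,
                     icc_form = icc_form)
}

#' Flexicurve measurement table of ten clinical subjects
#'
#' Loads the bundled table of ten subjects measured both by an expert with
#' a physical flexicurve (chord `L_cm`, depth `d_cm`, and the resulting
#' `actual_angle_deg`) and by an automated silhouette pipeline
#' (`predicted_angle_deg`). Useful as a worked example for the angle
#' formula and the agreement statistics.
#'
#' @return data frame with columns `patient`, `gender`, `age`,
#'   `body_length_cm`, `weight_kg`, `L_cm`, `d_cm`, `actual_angle_deg`,
#'   `predicted_angle_deg`.
#' @export
flexicurve_table <- function() {
  utils::read.csv(system.file("extdata", "table3.csv", package = "kyphoscan",
                              mustWork = TRUE))
}
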