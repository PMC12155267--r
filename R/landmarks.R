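#' @title Body landmarks and proportion ratios
#' @description Helpers that calibrate the body-proportion ratios
#'   (r1, r2, r3) from annotated subjects and localize T1/T12 rows on a new
#'   binary silhouette. All landmark arithmetic uses a y-up convention
#'   (larger y = higher on the body) so that body height is simply
#'   `y_head - y_foot`; [row_to_y()] / [y_to_row()] convert between image
#'   row indices (row 1 = top) and this convention.
#' @name landmarks
NULL

#' Convert between image rows and y-up coordinates
#'
#' Image arrays index rows from the top (`row = 1` is the top of the
#' image); the landmark equations use y increasing upward. For an image
#' with `n_rows` rows, `y = n_rows - row` maps row 1 to the largest y.
#'
#' @param row image row index (1-based, top = 1)
#' @param y y-up coordinate
#' @param n_rows number of image rows
#' @return the converted coordinate
#' @export
row_to_y <- function(row, n_rows) n_rows - row

#' @rdname row_to_y
#' @export
y_to_row <- function(y, n_rows) n_rows - y

#' Construct a set of body landmarks
#'
#' Bundles the four sagittal landmark points -- top of head, T1, T12,
#' bottom of foot -- in y-up coordinates and checks the upright ordering
#' `y_head > y_t1 > y_t12 > y_foot`.
#'
#' @param p_head,p_t1,p_t12,p_foot numeric `(x, y)` pairs, y increasing
#'   upward.
#' @return object of class `body_landmarks`.
#' @export
body_landmarks <- function(p_head, p_t1, p_t12, p_foot) {
  pts <- list(head = p_head, t1 = p_t1, t12 = p_t12, foot = p_foot)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
      stop("landmark `", nm, "` must be a finite (x, y) pair", call. = FALSE)
  }
  ys <- vapply(pts, `[`, numeric(1), 2L)
  if (!(ys["head"] > ys["t1"] && ys["t1"] > ys["t12"] &&
        ys["t12"] > ys["foot"]))
    stop("landmarks violate upright ordering y_head > y_T1 > y_T12 > y_foot",
         call. = FALSE)
  structure(pts, class = "body_landmarks")
}

#' @export
print.body_landmarks <- function(x, ...) {
  cat("Body landmarks (y-up):\n")
  for (nm in c("head", "t1", "t12", "foot"))
    cat(sprintf("  %-5s x = %8.2f  y = %8.2f\n", nm, x[[nm]][1], x[[nm]][2]))
  cat(sprintf("  height = %.2f\n", subject_height(x)))
  invisible(x)
}

#' Body height of a landmarked subject
#'
#' Height in pixels: vertical distance from the top of the head to the
#' bottom of the foot, `y_head - y_foot`.
#'
#' @param lm a [body_landmarks()] object.
#' @return height (same unit as the coordinates), always > 0.
#' @export
subject_height <- function(lm) {
  stopifnot(inherits(lm, "body_landmarks"))
  lm$head[2] - lm$foot[2]
}

#' Body-proportion ratios of one subject
#'
#' The three segment fractions of body height: head-top to T1 (`r1`), T1 to
#' T12 (`r2`) and T12 to foot (`r3`). They telescope, so the components
#' always sum to exactly 1.
#'
#' @param lm a [body_landmarks()] object.
#' @return named numeric vector `c(r1, r2, r3)`.
#' @export
subject_ratios <- function(lm) {
  stopifnot(inherits(lm, "body_landmarks"))
  h <- subject_height(lm)
  if (h <= 0) stop("zero body height", call. = FALSE)
  c(r1 = (lm$head[2] - lm$t1[2]) / h,
    r2 = (lm$t1[2] - lm$t12[2]) / h,
    r3 = (lm$t12[2] - lm$foot[2]) / h)
}

#' Calibrate average proportion ratios over a training cohort
#'
#' Component-wise arithmetic mean of [subject_ratios()] over all annotated
#' training subjects. The averaged components still sum to 1 (the mean is
#' linear), so the three ratios partition body height.
#'
#' @param training list of [body_landmarks()] objects (one per subject).
#' @return object of class `landmark_ratios`: named numeric vector
#'   `c(r1, r2, r3)` with attribute `n` (cohort size).
#' @export
average_ratios <- function(training) {
  if (inherits(training, "body_landmarks")) training <- list(training)
  if (!is.list(training) || length(training) == 0L)
    stop("calibration needs at least one annotated subject", call. = FALSE)
  per <- vapply(training, subject_ratios, numeric(3))
  landmark_ratios(rowMeans(per), n = length(training))
}

#' Construct a ratio set
#'
#' @param r numeric length-3 vector `(r1, r2, r3)`; each component in
#'   (0, 1), summing to 1 within `1e-12`.
#' @param n optional cohort size the ratios were averaged over.
#' @return object of class `landmark_ratios`.
#' @export
landmark_ratios <- function(r, n = NA_integer_) {
  r <- as.numeric(r)
  if (length(r) != 3L || !all(is.finite(r)))
    stop("ratios must be three finite numbers", call. = FALSE)
  if (any(r <= 0) || any(r >= 1))
    stop("each ratio must lie strictly in (0, 1)", call. = FALSE)
  if (abs(sum(r) - 1) > 1e-12)
    stop("ratios must sum to 1 (got ", format(sum(r), digits = 15), ")",
         call. = FALSE)
  structure(stats::setNames(r, c("r1", "r2", "r3")),
            n = as.integer(n), class = "landmark_ratios")
}

#' @export
print.landmark_ratios <- function(x, ...) {
  cat(sprintf("Landmark ratios: r1 = %.4f  r2 = %.4f  r3 = %.4f",
              x[1], x[2], x[3]))
  n <- attr(x, "n")
  if (!is.na(n)) cat(sprintf("  (averaged over %d subjects)", n))
  cat("\n")
  invisible(x)
}

# nearest-row rounding with ties resolved toward the head (smaller offset)
.round_toward_head <- function(x) ceiling(x - 0.5)

#' Localize landmarks on a binary silhouette
#'
#' Finds the head-top and foot-bottom rows as the extreme rows containing
#' person pixels, then places the T1 and T12 rows at the calibrated
#' fractions `r1` and `r1 + r2` of body height below the head. Row
#' positions are rounded to the nearest grid row (ties toward the head).
#' The x coordinate of head and foot is the centroid column of the extreme
#' row; the x of T1/T12 is the dorsal-most person column of their row,
#' where the dorsal side is resolved by `facing` (see [dorsal_side()]).
#'
#' @param mask binary person mask: 0/1 matrix, row 1 = image top.
#' @param ratios a [landmark_ratios()] object.
#' @param facing `"left"`, `"right"`, or `"auto"`: the direction the
#'   subject faces; the dorsal (back) side is the opposite image side.
#'   `"auto"` picks the side whose T1--T12 edge bows outward more.
#' @return a [body_landmarks()] object in y-up coordinates (use
#'   [y_to_row()] to recover image rows).
#' @export
locate_landmarks <- function(mask, ratios, facing = c("auto", "left", "right")) {
  facing <- match.arg(facing)
  mask <- .as_mask(mask)
  if (!inherits(ratios, "landmark_ratios")) ratios <- landmark_ratios(ratios)
  rows_with <- which(rowSums(mask) > 0)
  if (length(rows_with) == 0L) stop("empty mask: no person pixels", call. = FALSE)
  n_rows <- nrow(mask)
  row_head <- rows_with[1]
  row_foot <- rows_with[length(rows_with)]
  H <- row_foot - row_head
  if (H <= 0) stop("degenerate silhouette: zero body height", call. = FALSE)
  row_t1  <- .round_toward_head(row_head + ratios[["r1"]] * H)
  row_t12 <- .round_toward_head(row_head + (ratios[["r1"]] + ratios[["r2"]]) * H)
  if (row_t1 <= row_head || row_t12 >= row_foot || row_t12 <= row_t1)
    stop("T1/T12 rows fall outside the silhouette's vertical span",
         call. = FALSE)
  dorsal <- dorsal_side(mask, row_t1, row_t12, facing)
  x_of <- function(row) {
    cols <- which(mask[row, ] > 0)
    if (length(cols) == 0L)
      stop("broken silhouette: empty row at landmark level", call. = FALSE)
    if (dorsal == "left") min(cols) else max(cols)
  }
  centroid_of <- function(row) mean(which(mask[row, ] > 0))
  lm <- body_landmarks(
    p_head = c(centroid_of(row_head), row_to_y(row_head, n_rows)),
    p_t1   = c(x_of(row_t1),  row_to_y(row_t1, n_rows)),
    p_t12  = c(x_of(row_t12), row_to_y(row_t12, n_rows)),
    p_foot = c(centroid_of(row_foot), row_to_y(row_foot, n_rows)))
  attr(lm, "dorsal") <- dorsal
  lm
}

#' Resolve which image side is the subject's back
#'
#' For `facing = "left"` the back is the right image side and vice versa.
#' With `"auto"`, both candidate edges between the T1 and T12 rows are
#' extracted and the side with the larger outward bow (maximum deviation of
#' the edge from its own endpoint chord, in the outward direction) is
#' declared dorsal; the thoracic back is convex outward while the ventral
#' chest-abdomen profile bows the other way.
#'
#' @param mask 0/1 mask matrix.
#' @param row_t1,row_t12 image rows bracketing the thoracic segment.
#' @param facing `"left"`, `"right"` or `"auto"`.
#' @return `"left"` or `"right"`: the dorsal image side.
#' @export
dorsal_side <- function(mask, row_t1, row_t12, facing = "auto") {
  if (facing == "left") return("right")
  if (facing == "right") return("left")
  rows <- row_t1:row_t12
  bow <- function(side) {
    edge <- vapply(rows, function(r) {
      cols <- which(mask[r, ] > 0)
      if (length(cols) == 0L) return(NA_real_)
      if (side == "left") min(cols) else max(cols)
    }, numeric(1))
    edge <- edge[is.finite(edge)]
    if (length(edge) < 3L) return(0)
    chord <- seq(edge[1], edge[length(edge)], length.out = length(edge))
    dev <- edge - chord
    # outward = toward smaller columns on the left, larger on the right
    if (side == "left") max(-dev, 0) else max(dev, 0)
  }
  if (bow("left") >= bow("right")) "left" else "right"
}

#' Extract the dorsal contour between the T1 and T12 rows
#'
#' One point per image row from the T1 row down to the T12 row: the
#' dorsal-most person column of that row, optionally smoothed with an
#' odd-window running median (robust to single-row mask noise without
#' flattening the arc apex). Points are returned in y-up coordinates,
#' ordered from T1 (top) to T12 (bottom).
#'
#' @param mask 0/1 mask matrix, row 1 = image top.
#' @param lm a [body_landmarks()] object located on `mask`.
#' @param facing facing side passed through to [dorsal_side()]; when `lm`
#'   carries a resolved `dorsal` attribute (as produced by
#'   [locate_landmarks()]) that side is reused.
#' @param smooth odd running-median window in rows; `1` disables smoothing.
#' @return two-column matrix of `(x, y)` contour points.
#' @export
dorsal_contour <- function(mask, lm, facing = "auto", smooth = 5L) {
  mask <- .as_mask(mask)
  stopifnot(inherits(lm, "body_landmarks"))
  smooth <- as.integer(smooth)
  if (smooth < 1L || smooth %% 2L == 0L)
    stop("`smooth` must be an odd positive window size", call. = FALSE)
  n_rows <- nrow(mask)
  row_t1  <- y_to_row(lm$t1[2], n_rows)
  row_t12 <- y_to_row(lm$t12[2], n_rows)
  if (row_t12 <= row_t1)
    stop("T12 must lie below T1 on the image", call. = FALSE)
  dorsal <- attr(lm, "dorsal")
  if (is.null(dorsal)) dorsal <- dorsal_side(mask, row_t1, row_t12, facing)
  rows <- row_t1:row_t12
  xs <- vapply(rows, function(r) {
    cols <- which(mask[r, ] > 0)
    if (length(cols) == 0L)
      stop("broken silhouette: no person pixels in row ", r, call. = FALSE)
    if (dorsal == "left") min(cols) else max(cols)
  }, numeric(1))
  if (smooth > 1L && length(xs) > smooth)
    xs <- stats::runmed(xs, smooth, endrule = "median")
  cbind(x = as.numeric(xs), y = row_to_y(rows, n_rows))
}

#' Read a landmark annotation table
#'
#' Reads a CSV of manually annotated landmark coordinates (image-row
#' convention, 0-based rows as exported by annotation tools) and converts
#' each subject to a y-up [body_landmarks()] object. Expected columns:
#' `subject_id, x_head, y_head_row, x_t1, y_t1_row, x_t12, y_t12_row,
#' x_foot, y_foot_row`, plus the image height in rows via `n_rows`.
#'
#' @param path CSV file path.
#' @param n_rows image height in rows used to flip row indices to y-up.
#' @return named list of [body_landmarks()] objects keyed by subject id.
#' @export
read_landmark_annotations <- function(path, n_rows) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "x_head", "y_head_row", "x_t1", "y_t1_row",
            "x_t12", "y_t12_row", "x_foot", "y_foot_row")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("annotation file has no subjects", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    # 0-based row index -> y-up: y = (n_rows - 1) - row
    flip <- function(r) (n_rows - 1) - r
    body_landmarks(
      p_head = c(df$x_head[i], flip(df$y_head_row[i])),
      p_t1   = c(df$x_t1[i],   flip(df$y_t1_row[i])),
      p_t12  = c(df$x_t12[i],  flip(df$y_t12_row[i])),
      p_foot = c(df$x_foot[i], flip(df$y_foot_row[i])))
  })
  names(out) <- df$subject_id
  out
}
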