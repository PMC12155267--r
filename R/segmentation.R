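#' @importFrom EBImage bwlabel fillHull distmap otsu Image readImage writeImage imageData
NULL

# coerce assorted mask-like inputs (logical/numeric matrix, EBImage Image,
# 0/255 PNG values) to a 0/1 integer matrix, row 1 = image top
.as_mask <- function(mask) {
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  if (is.logical(mask)) mask <- mask * 1L
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix", call. = FALSE)
  u <- unique(as.vector(mask))
  if (length(u) > 2L)
    stop("mask must carry exactly two label values", call. = FALSE)
  thr <- if (max(u) > 1) max(u) / 2 else 0.5
  m <- (mask > thr) * 1L
  dim(m) <- dim(mask)
  m
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass over the label image
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) union2(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(k), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' Clean up a binary person mask
#'
#' Postprocessing applied after any segmentation backend: keeps only the
#' largest 8-connected person component (removing speckles and detached
#' false positives) and fills background holes fully enclosed by the body.
#' Idempotent; an empty mask passes through unchanged.
#'
#' @param mask 0/1 matrix (or anything [as_binary_mask()] accepts).
#' @return cleaned 0/1 integer matrix of the same shape.
#' @export
postprocess_mask <- function(mask) {
  mask <- .as_mask(mask)
  if (sum(mask) == 0L) return(mask)
  lab <- .label8(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  m <- (lab == keep) * 1L
  dim(m) <- dim(mask)
  m <- EBImage::imageData(EBImage::fillHull(m))
  storage.mode(m) <- "integer"
  m
}

#' Coerce an object to a binary mask
#'
#' Accepts logical or numeric matrices (any two-level coding, e.g. 0/255
#' PNG values) and `EBImage` images; returns a plain 0/1 integer matrix
#' with row 1 at the image top.
#'
#' @param mask mask-like object.
#' @return 0/1 integer matrix.
#' @export
as_binary_mask <- function(mask) .as_mask(mask)

# --- backend registry -------------------------------------------------------

.backends <- new.env(parent = emptyenv())

#' Register or list segmentation backends
#'
#' The segmentation stage is a pluggable contract: a backend is a function
#' `(image, ...) -> 0/1 mask` operating on an `rows x cols x 3` RGB array
#' in `[0, 1]`. The package ships the deterministic `"threshold"` backend
#' ([segment_threshold()]); a learned model can be registered under its own
#' id and dropped into the same pipeline.
#'
#' @param id backend identifier string.
#' @param fun backend function `(image, ...) -> mask`.
#' @return `register_backend` invisibly returns `id`; `list_backends`
#'   returns the registered ids.
#' @export
register_backend <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  assign(id, fun, envir = .backends)
  invisible(id)
}

#' @rdname register_backend
#' @export
list_backends <- function() ls(.backends)

#' Segment the person silhouette from an RGB image
#'
#' Runs the selected backend and then [postprocess_mask()]. The default
#' `"threshold"` backend models the background color from the image border
#' and classifies pixels by their distance to that model (see
#' [segment_threshold()]).
#'
#' @param image `rows x cols x 3` RGB array in `[0, 1]` (a grayscale
#'   matrix is accepted and replicated across channels).
#' @param backend registered backend id.
#' @param postprocess apply [postprocess_mask()] to the backend output.
#' @param ... passed to the backend.
#' @return 0/1 integer mask matrix.
#' @export
segment_person <- function(image, backend = "threshold", postprocess = TRUE,
                           ...) {
  if (!exists(backend, envir = .backends))
    stop("unregistered segmentation backend: `", backend, "`", call. = FALSE)
  fun <- get(backend, envir = .backends)
  mask <- fun(image, ...)
  mask <- .as_mask(mask)
  if (postprocess) mask <- postprocess_mask(mask)
  if (sum(mask) == 0L)
    stop("segmentation found no foreground (empty mask)", call. = FALSE)
  mask
}

#' Border-color threshold segmentation backend
#'
#' Deterministic reference backend: the background color is estimated as
#' the per-channel median of the image border (the subject stands centered,
#' so the border is background by protocol); each pixel is scored by its
#' Euclidean distance in RGB space to that color, and the score map is
#' binarized with Otsu's threshold (or a fixed cut if `threshold` is
#' given). Works on any scene whose background is approximately uniform or
#' smoothly varying relative to the person/background contrast.
#'
#' @param image RGB array in `[0, 1]` or grayscale matrix.
#' @param border_px border width in pixels used for the background color
#'   model (default 5).
#' @param threshold optional fixed threshold on the distance map in
#'   `[0, sqrt(3)]`; `NULL` (default) selects it by Otsu's method.
#' @return 0/1 integer mask (un-postprocessed).
#' @export
segment_threshold <- function(image, border_px = 5L, threshold = NULL) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be rows x cols x 3 (RGB) or a grayscale matrix",
         call. = FALSE)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (nr == 0L || nc == 0L) stop("empty image", call. = FALSE)
  b <- min(border_px, floor(min(nr, nc) / 2))
  border_idx <- matrix(FALSE, nr, nc)
  border_idx[c(seq_len(b), nr - seq_len(b) + 1L), ] <- TRUE
  border_idx[, c(seq_len(b), nc - seq_len(b) + 1L)] <- TRUE
  bg <- vapply(1:3, function(ch) stats::median(image[, , ch][border_idx]),
               numeric(1))
  dist2 <- (image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
    (image[, , 3] - bg[3])^2
  score <- sqrt(dist2) / sqrt(3)   # normalized to [0, 1]
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(score), range = c(0, 1))
  } else {
    threshold <- threshold / sqrt(3)
  }
  (score > threshold) * 1L
}

register_backend("threshold", segment_threshold)

# --- mask I/O ---------------------------------------------------------------

#' Read or write a binary mask PNG
#'
#' Masks are stored as single-channel PNG files with values 0 (background)
#' and 255 (person). `read_mask` returns a 0/1 integer matrix with row 1 at
#' the image top.
#'
#' @param path PNG file path.
#' @param mask 0/1 matrix to write.
#' @return `read_mask`: 0/1 integer matrix; `write_mask`: `path`,
#'   invisibly.
#' @export
read_mask <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- dat[, , 1]
  .as_mask(t(dat))   # EBImage stores x = columns first; transpose to row-major
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  mask <- .as_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask)), path)
  invisible(path)
}

#' Read or write an RGB image
#'
#' Thin wrappers over `EBImage` returning/accepting `rows x cols x 3`
#' arrays in `[0, 1]` with row 1 at the image top.
#'
#' @param path image file path (PNG or JPEG).
#' @param image RGB array to write.
#' @return `read_rgb`: RGB array; `write_rgb`: `path`, invisibly.
#' @export
read_rgb <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3]
  aperm(dat, c(2, 1, 3))
}

#' @rdname read_rgb
#' @export
write_rgb <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  EBImage::writeImage(EBImage::Image(aperm(image, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}
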