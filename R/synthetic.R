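#' Specification of a synthetic sagittal silhouette
#'
#' Describes one synthetic standing subject: image size, body height in
#' pixels, the true kyphosis angle, the proportion ratios placing the
#' head-top/T1/T12/foot rows, simple body-shape parameters, and an
#' optional boundary-noise rate. The dorsal edge between the T1 and T12
#' rows is a circular arc whose chord and sagitta realize the prescribed
#' angle exactly (the angle formula is exactly the chord-sagitta relation
#' of an arc, so "true theta" is well defined); elsewhere the back is
#' straight.
#'
#' @param rows,cols image size in pixels.
#' @param height_px body height (head-top row to foot-bottom row).
#' @param theta true kyphosis angle in degrees, in `[0, 60]`.
#' @param ratios length-3 proportion vector `(r1, r2, r3)`, summing to 1:
#'   head-to-T1, T1-to-T12, T12-to-foot fractions of body height. The
#'   default (0.12, 0.28, 0.60) is a plausible standing-adult proportion
#'   set; calibration never assumes it.
#' @param torso_halfwidth_px torso half-width in pixels.
#' @param head_radius_px head disc radius in pixels.
#' @param facing `"left"` or `"right"`: direction the subject faces; the
#'   dorsal arc bulges toward the opposite side.
#' @param noise_rate fraction of mask boundary pixels to flip (0 = clean).
#' @param seed integer seed for the subject's pseudo-random stream.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(rows = 900L, cols = 520L, height_px = 800L,
                       theta = 32, ratios = c(0.12, 0.28, 0.60),
                       torso_halfwidth_px = round(0.09 * height_px),
                       head_radius_px = round(0.04 * height_px),
                       facing = c("left", "right"),
                       noise_rate = 0, seed = 1L) {
  facing <- match.arg(facing)
  ratios <- landmark_ratios(ratios)
  if (theta < 0 || theta > 60)
    stop("`theta` must lie in [0, 60] degrees", call. = FALSE)
  if (height_px >= rows)
    stop("body height must fit inside the image", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1)
    stop("`noise_rate` must be a fraction", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 height_px = as.integer(height_px), theta = theta,
                 ratios = ratios,
                 torso_halfwidth_px = as.integer(torso_halfwidth_px),
                 head_radius_px = as.integer(head_radius_px),
                 facing = facing, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# run expr with a private RNG stream, leaving the caller's stream untouched
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic subject with ground truth
#'
#' Rasterizes the silhouette described by a [synth_spec()]: a head disc,
#' neck, torso whose dorsal edge carries the kyphotic arc between the T1
#' and T12 rows, and a leg block down to the foot row. Returns the binary
#' mask together with the exact ground truth: landmark rows, the true
#' chord length `L` (the T1-T12 row distance, both endpoints on the arc
#' baseline), the true sagitta `d = flexicurve_depth(theta, L)`, and the
#' prescribed angle. Deterministic given the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return object of class `synth_subject`: list with `mask` (0/1 matrix),
#'   `landmarks` ([body_landmarks()]), `rows` (named landmark image rows),
#'   `L_px`, `d_px`, `theta`, `ratios`, `facing`, `spec`.
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nr <- spec$rows; nc <- spec$cols
  H <- spec$height_px
  r <- spec$ratios
  row_head <- (nr - H) %/% 2L + 1L
  row_foot <- row_head + H
  row_t1  <- .round_toward_head(row_head + r[["r1"]] * H)
  row_t12 <- .round_toward_head(row_head + (r[["r1"]] + r[["r2"]]) * H)
  L <- row_t12 - row_t1
  d <- flexicurve_depth(spec$theta, L)
  hw <- spec$torso_halfwidth_px
  hr <- spec$head_radius_px
  # dorsal baseline column: leave room for the arc bulge
  pad <- ceiling(d) + 6L
  x0 <- if (spec$facing == "left") nc - pad else pad + 1L
  sgn <- if (spec$facing == "left") 1L else -1L   # outward dorsal direction
  ventral_x <- x0 - sgn * 2L * hw
  if (min(x0, ventral_x) < 1L || max(x0, ventral_x) > nc ||
      x0 + sgn * ceiling(d) < 1L || x0 + sgn * ceiling(d) > nc)
    stop("silhouette (arc bulge or torso) exceeds image bounds", call. = FALSE)

  mask <- matrix(0L, nr, nc)
  fill_span <- function(row, xa, xb) {
    cols <- max(1L, min(xa, xb)):min(nc, max(xa, xb))
    mask[row, cols] <<- 1L
  }
  # dorsal arc offset per row (0 at the T1/T12 rows, d at mid-chord)
  arc_dx <- function(rowv) {
    if (d == 0) return(rep(0, length(rowv)))
    R <- L^2 / (8 * d) + d / 2
    mid <- (row_t1 + row_t12) / 2
    sqrt(pmax(R^2 - (rowv - mid)^2, 0)) - (R - d)
  }
  # torso: from the shoulder line (just above T1) to the hip
  row_shoulder <- row_head + round(0.75 * r[["r1"]] * H)
  if (row_head + 2L * hr >= row_shoulder)
    stop("head radius too large for the head-to-T1 segment", call. = FALSE)
  row_hip <- min(row_t12 + round(0.1 * H), row_foot - 1L)
  for (row in row_shoulder:row_hip) {
    dx <- if (row >= row_t1 && row <= row_t12) arc_dx(row) else 0
    fill_span(row, ventral_x, x0 + sgn * as.integer(round(dx)))
  }
  # head disc (kept clear of the dorsal baseline) and neck
  cx <- x0 - sgn * (hr + 3L)
  cy <- row_head + hr
  rr <- (row_head):(row_head + 2L * hr)
  for (row in rr) {
    half <- sqrt(max(hr^2 - (row - cy)^2, 0))
    if (half >= 0.5 || row == row_head || row == row_head + 2L * hr)
      fill_span(row, floor(cx - half), ceiling(cx + half))
    else fill_span(row, cx, cx)
  }
  for (row in (row_head + 2L * hr):row_shoulder)
    fill_span(row, cx - hr %/% 2L, cx + hr %/% 2L)
  # legs: block from hip to the foot row, inset from the dorsal baseline
  leg_a <- ventral_x + sgn * hw %/% 2L
  leg_b <- x0 - sgn * hw %/% 2L
  for (row in row_hip:row_foot) fill_span(row, leg_a, leg_b)

  if (spec$noise_rate > 0)
    mask <- .with_seed(spec$seed,
                       .flip_boundary(mask, spec$noise_rate))

  # ground-truth annotation keeps the exact (sub-pixel) T1/T12 positions;
  # the `rows` field carries the rasterized grid rows used for the arc
  lm <- body_landmarks(
    p_head = c(cx, row_to_y(row_head, nr)),
    p_t1   = c(x0, row_to_y(row_head + r[["r1"]] * H, nr)),
    p_t12  = c(x0, row_to_y(row_head + (r[["r1"]] + r[["r2"]]) * H, nr)),
    p_foot = c(mean(c(leg_a, leg_b)), row_to_y(row_foot, nr)))
  attr(lm, "dorsal") <- if (spec$facing == "left") "right" else "left"
  structure(list(mask = mask, landmarks = lm,
                 rows = c(head = row_head, t1 = row_t1, t12 = row_t12,
                          foot = row_foot),
                 L_px = as.numeric(L), d_px = d, theta = spec$theta,
                 ratios = r, facing = spec$facing, spec = spec),
            class = "synth_subject")
}

#' @export
print.synth_subject <- function(x, ...) {
  cat(sprintf(
    "Synthetic subject: %d x %d mask, height %d px, theta %.2f deg (L = %.0f, d = %.2f px)\n",
    nrow(x$mask), ncol(x$mask), x$spec$height_px, x$theta, x$L_px, x$d_px))
  invisible(x)
}

# flip a fraction of the mask's boundary pixels (both person-side and
# background-side boundary), emulating segmentation edge noise
.flip_boundary <- function(mask, rate) {
  person_b <- which(.boundary(mask, 1L))
  bg_adj <- which(.boundary(mask, 0L) &
                    EBImage::imageData(EBImage::distmap(1 - mask)) <= 1.5)
  cand <- c(person_b, bg_adj)
  n_flip <- round(rate * length(cand))
  if (n_flip > 0) {
    idx <- sample(cand, n_flip)
    mask[idx] <- 1L - mask[idx]
  }
  mask
}

#' Render a synthetic subject into an RGB scene
#'
#' Fills the silhouette with a body color and composites it over one of
#' the registered synthetic backgrounds -- `"uniform"` (flat light gray),
#' `"gradient"` (vertical luminance ramp), or `"textured"` (smooth seeded
#' low-frequency texture) -- then adds i.i.d. Gaussian pixel noise. The
#' subject's ground-truth mask is untouched, so one subject rendered over
#' several backgrounds emulates background-modification dataset
#' augmentation with a shared ground truth.
#'
#' @param subject a [generate_subject()] result.
#' @param background background id.
#' @param noise_sd additive Gaussian noise SD (image scale `[0, 1]`).
#' @param seed seed for texture and noise.
#' @param body_color RGB triplet of the silhouette fill.
#' @return `rows x cols x 3` RGB array in `[0, 1]`.
#' @export
render_scene <- function(subject,
                         background = c("uniform", "gradient", "textured"),
                         noise_sd = 0, seed = 1L,
                         body_color = c(0.18, 0.18, 0.22)) {
  background <- match.arg(background)
  mask <- subject$mask
  nr <- nrow(mask); nc <- ncol(mask)
  .with_seed(seed, {
    bg <- switch(background,
      uniform = array(rep(c(0.85, 0.86, 0.88), each = nr * nc), c(nr, nc, 3)),
      gradient = {
        ramp <- matrix(seq(0.70, 0.95, length.out = nr), nr, nc)
        array(c(ramp, ramp * 0.99, ramp * 1.02), c(nr, nc, 3))
      },
      textured = {
        rowi <- matrix(seq_len(nr), nr, nc)
        coli <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        tex <- 0.82
        for (j in 1:4) {
          fr <- stats::runif(1, 0.005, 0.03); fc <- stats::runif(1, 0.005, 0.03)
          ph <- stats::runif(2, 0, 2 * pi)
          tex <- tex + 0.035 * sin(2 * pi * fr * rowi + ph[1]) *
            cos(2 * pi * fc * coli + ph[2])
        }
        array(c(tex, tex * 0.98, tex * 1.01), c(nr, nc, 3))
      })
    img <- bg
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask == 1L] <- body_color[ch]
      img[, , ch] <- plane
    }
    if (noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    pmin(pmax(img, 0), 1)
  })
}

# truncated-normal sampler by rejection (bounds well within ±3 sd here)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort
#'
#' Draws `n` independent subjects with true angles from a truncated normal
#' distribution and optional per-subject jitter of the proportion ratios
#' around the cohort means. Per-subject seeds are derived from the cohort
#' seed by counter offset, so subjects are reproducible individually and
#' in parallel.
#'
#' @param n cohort size.
#' @param theta_mean,theta_sd,theta_range truncated-normal parameters of
#'   the true angle distribution (degrees).
#' @param ratio_jitter SD of multiplicative jitter applied to the ratios
#'   (renormalized to sum 1); `0` gives every subject identical ratios.
#' @param seed cohort seed.
#' @param ... further arguments passed to [synth_spec()] (image size,
#'   noise rate, ...).
#' @return object of class `synth_cohort`: list with `subjects` (list of
#'   `synth_subject`) and `manifest` (data frame of ground truth per
#'   subject).
#' @export
generate_cohort <- function(n, theta_mean = 32, theta_sd = 10,
                            theta_range = c(15, 55), ratio_jitter = 0,
                            seed = 1L, ...) {
  if (n < 1L) stop("cohort size must be >= 1", call. = FALSE)
  if (theta_range[1] >= theta_range[2])
    stop("invalid truncation bounds", call. = FALSE)
  base <- synth_spec(...)
  draws <- .with_seed(seed, {
    thetas <- .rtruncnorm(n, theta_mean, theta_sd,
                          theta_range[1], theta_range[2])
    ratio_list <- lapply(seq_len(n), function(i) {
      if (ratio_jitter == 0) return(as.numeric(base$ratios))
      r <- as.numeric(base$ratios) *
        exp(stats::rnorm(3, 0, ratio_jitter))
      r / sum(r)
    })
    list(thetas = thetas, ratios = ratio_list)
  })
  subjects <- lapply(seq_len(n), function(i) {
    sp <- base
    sp$theta <- draws$thetas[i]
    sp$ratios <- landmark_ratios(draws$ratios[[i]])
    sp$seed <- base$seed + i
    generate_subject(sp)
  })
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- subjects[[i]]
    data.frame(subject_id = sprintf("S%03d", i),
               true_theta_deg = s$theta, L_px = s$L_px, d_px = s$d_px,
               r1 = s$ratios[["r1"]], r2 = s$ratios[["r2"]],
               r3 = s$ratios[["r3"]],
               row_head = s$rows[["head"]], row_t1 = s$rows[["t1"]],
               row_t12 = s$rows[["t12"]], row_foot = s$rows[["foot"]])
  }))
  structure(list(subjects = subjects, manifest = manifest,
                 seed = as.integer(seed)),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort of %d subjects (theta %.1f-%.1f deg)\n",
              nrow(x$manifest), min(x$manifest$true_theta_deg),
              max(x$manifest$true_theta_deg)))
  invisible(x)
}
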