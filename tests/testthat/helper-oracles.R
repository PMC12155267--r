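# Brute-force oracles, written independently of the package internals:
# explicit pixel loops and direct arithmetic only.

oracle_global_accuracy <- function(pred, gt) {
  correct <- 0L
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt)))
    if (pred[i, j] == gt[i, j]) correct <- correct + 1L
  correct / length(gt)
}

oracle_class_recall <- function(pred, gt, cl) {
  hit <- 0L; tot <- 0L
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt)))
    if (gt[i, j] == cl) {
      tot <- tot + 1L
      if (pred[i, j] == cl) hit <- hit + 1L
    }
  if (tot == 0L) NA_real_ else hit / tot
}

oracle_iou <- function(pred, gt, cl) {
  inter <- 0L; uni <- 0L
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    p <- pred[i, j] == cl; g <- gt[i, j] == cl
    if (p && g) inter <- inter + 1L
    if (p || g) uni <- uni + 1L
  }
  if (uni == 0L) 1 else inter / uni
}

oracle_weighted_iou <- function(pred, gt) {
  w0 <- sum(gt == 0); w1 <- sum(gt == 1)
  (w0 * oracle_iou(pred, gt, 0) + w1 * oracle_iou(pred, gt, 1)) / (w0 + w1)
}

# boundary pixels of class cl: 4-neighbour of another class, or frame edge
oracle_boundary_pixels <- function(mask, cl) {
  out <- NULL
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j] != cl) next
    edge <- i == 1L || i == nr || j == 1L || j == nc
    if (!edge) {
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
        if (mask[nb[1], nb[2]] != cl) { edge <- TRUE; break }
    }
    if (edge) out <- rbind(out, c(i, j))
  }
  out
}

oracle_boundary_f1 <- function(pred, gt, cl, tol) {
  bp <- oracle_boundary_pixels(pred, cl)
  bg <- oracle_boundary_pixels(gt, cl)
  if (is.null(bp) && is.null(bg)) return(1)
  if (is.null(bp) || is.null(bg)) return(0)
  near <- function(p, set) {
    for (k in seq_len(nrow(set)))
      if (sqrt(sum((p - set[k, ])^2)) <= tol) return(TRUE)
    FALSE
  }
  prec <- mean(vapply(seq_len(nrow(bp)), function(k) near(bp[k, ], bg),
                      logical(1)))
  rec <- mean(vapply(seq_len(nrow(bg)), function(k) near(bg[k, ], bp),
                     logical(1)))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# ICC(A,1) from aov mean squares: an independent two-way ANOVA route
oracle_icc_agreement <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  long <- data.frame(y = as.vector(tab),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = long))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

random_mask_pair <- function(nr = 10, nc = 10) {
  # random but correlated pair so that intersections are non-trivial
  gt <- matrix(rbinom(nr * nc, 1, 0.5), nr, nc)
  flip <- matrix(rbinom(nr * nc, 1, 0.2), nr, nc)
  pred <- ifelse(flip == 1, 1 - gt, gt)
  list(pred = pred, gt = gt)
}
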