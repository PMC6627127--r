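#' Relative mean signal and coefficient of variation
#'
#' The relative fat-suppressed T2 mean signal is the ROI-mean tumor
#' intensity divided by the ROI-mean intensity of the healthy-side medial
#' pterygoid muscle; the coefficient of variation is SD/mean within the
#' tumor ROI.
#'
#' @param t2 T2-weighted `image_volume`.
#' @param tumor,muscle `roi_mask`s aligned to `t2`.
#' @param exclude Optional exclusion `roi_mask` applied to the tumor ROI.
#' @return List with `rel_mean_signal` and `cv`.
#' @export
relative_mean_and_cv <- function(t2, tumor, muscle, exclude = NULL) {
  tv <- mask_values(t2, tumor, exclude)
  mv <- mask_values(t2, muscle)
  mu_m <- mean(mv)
  if (mu_m == 0) stop("muscle ROI has zero mean signal")
  mu_t <- mean(tv)
  cv <- if (mu_t == 0) 0 else stats::sd(tv) / mu_t
  if (length(tv) == 1L) cv <- 0
  list(rel_mean_signal = mu_t / mu_m, cv = cv)
}

#' Gray-level co-occurrence texture features
#'
#' Haralick contrast, correlation, energy and homogeneity from a
#' symmetric, normalised GLCM. Intensities are min-max quantized to
#' `levels` gray levels within the ROI (making the features invariant to
#' affine intensity rescaling); co-occurrences are accumulated slice-wise
#' in 2D over the four distance-`distance` offsets (0, 45, 90, 135
#' degrees), counting only voxel pairs that both lie inside the ROI, and
#' the matrices are summed over slices and offsets before normalisation.
#'
#' A constant ROI is degenerate: contrast 0, energy 1, homogeneity 1 and
#' correlation reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param vol `image_volume` (typically fat-suppressed T2).
#' @param mask Tumor `roi_mask`.
#' @param levels Number of gray levels G (default 64).
#' @param distance Offset distance in voxels (default 1).
#' @param exclude Optional exclusion `roi_mask`.
#' @return Named numeric vector `contrast`, `correlation`, `energy`,
#'   `homogeneity` (attribute `degenerate` flags a constant ROI).
#' @export
glcm_features <- function(vol, mask, levels = 64L, distance = 1L,
                          exclude = NULL) {
  check_same_geometry(vol, mask, "volume and mask")
  keep <- mask$data
  if (!is.null(exclude)) keep <- keep & !exclude$data
  if (!any(keep)) stop("mask is empty (after exclusions)")
  x <- vol$data
  rng <- range(x[keep])
  if (rng[1] == rng[2]) {
    out <- c(contrast = 0, correlation = 0, energy = 1, homogeneity = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  q <- array(NA_integer_, dim(x))
  qq <- floor((x[keep] - rng[1]) / (rng[2] - rng[1]) * levels)
  qq[qq >= levels] <- levels - 1L
  q[keep] <- as.integer(qq)

  offsets <- distance * rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  d <- dim(x)
  counts <- numeric(levels * levels)
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    xs <- seq_len(d[1] - abs(dx)); ys <- seq_len(d[2] - abs(dy))
    x1 <- if (dx >= 0) xs else xs + abs(dx)
    y1 <- if (dy >= 0) ys else ys + abs(dy)
    x2 <- x1 + dx; y2 <- y1 + dy
    qa <- q[x1, y1, , drop = FALSE]
    qb <- q[x2, y2, , drop = FALSE]
    ok <- !is.na(qa) & !is.na(qb)
    if (!any(ok)) next
    code <- qa[ok] * levels + qb[ok] + 1L
    tab <- tabulate(code, nbins = levels * levels)
    counts <- counts + tab
    # symmetric matrix: add the transposed pairing
    code_t <- qb[ok] * levels + qa[ok] + 1L
    counts <- counts + tabulate(code_t, nbins = levels * levels)
  }
  if (sum(counts) == 0) stop("no in-mask voxel pairs for any offset")
  P <- matrix(counts / sum(counts), levels, levels)
  i <- row(P) - 1; j <- col(P) - 1
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sd_i == 0 || sd_j == 0) 0 else
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  out <- c(contrast = contrast, correlation = correlation,
           energy = sum(P^2), homogeneity = sum(P / (1 + abs(i - j))))
  attr(out, "degenerate") <- FALSE
  out
}
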