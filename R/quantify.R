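#' Interpretable feature quantification and image metrics
#'
#' The second step of the two-step analysis: after super-resolution, simple
#' handcrafted measurements quantify the phenotype directly on the images.
#' \itemize{
#'   \item [translocation_ratio()]: nucleocytoplasmic reporter ratio — mean
#'     reporter fluorescence inside the segmented nucleus over the mean in a
#'     cytoplasmic ring; above 1 indicates nuclear translocation.
#'   \item [mean_spot_area()]: mean area of the segmented reporter spots —
#'     large for a compact Golgi, small when the Golgi scatters into stacks.
#'   \item [psnr()], [ms_ssim()], [l1_distance()]: reference image metrics.
#'   \item [threshold_classify()]: midpoint-of-medians threshold rule with
#'     balanced accuracy, an interpretable stand-in for a learned two-class
#'     classifier.
#' }
#' Feature extractors take file-range (`[0, 1]`) images with channel 1 = DNA,
#' channel 2 = reporter, channel 3 = cell body.
#'
#' @name latsr-quantify
NULL

# 8-connected labelling of a logical matrix (two-pass BFS; images are small)
label_components8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  idx <- which(mask)
  for (p0 in idx) {
    if (lab[p0] != 0L) next
    cur <- cur + 1L
    queue <- p0
    lab[p0] <- cur
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      r <- (p - 1L) %% n + 1L
      c <- (p - 1L) %/% n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1L && r2 <= n && c2 >= 1L && c2 <= m) {
          q <- r2 + (c2 - 1L) * n
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

otsu_threshold <- function(x, levels = 256L) {
  x <- pmin(pmax(as.numeric(x), 0), 1)
  EBImage::otsu(EBImage::Image(matrix(x, length(x), 1L)), levels = levels)
}

segment_nucleus <- function(dna, smooth_sigma = 1) {
  sm <- gaussian_blur(array(dna, c(1L, dim(dna))), smooth_sigma)[1L, , ]
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  if (!any(mask)) stop("no nucleus detected", call. = FALSE)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  mask <- lab == big
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  matrix(as.logical(mask), nrow(dna), ncol(dna))
}

#' Nucleocytoplasmic translocation ratio
#'
#' Segments the nucleus from the smoothed DNA channel (Otsu threshold,
#' largest 8-connected component, holes filled), builds a cytoplasmic ring by
#' morphological dilation, and returns the ratio of mean reporter intensity
#' inside the nucleus to the ring (both regularized by `eps`).
#'
#' @param img 3-channel file-range image (DNA, reporter, cell body).
#' @param smooth_sigma Gaussian smoothing of the DNA channel before
#'   thresholding (pixels).
#' @param ring_width cytoplasmic ring width in pixels (default 4).
#' @param eps ratio regularizer (default 1e-6).
#' @return list of class `latsr_feature`: `value`, `n_objects`,
#'   `masks_used` (nucleus and cytoplasm ring).
#' @export
translocation_ratio <- function(img, smooth_sigma = 1, ring_width = 4L,
                                eps = 1e-6) {
  check_image(img)
  stopifnot(dim(img)[1L] >= 2L)
  nucleus <- segment_nucleus(img[1L, , ], smooth_sigma)
  brush <- EBImage::makeBrush(2L * as.integer(ring_width) + 1L,
                              shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(nucleus * 1), brush) > 0.5
  ring <- matrix(as.logical(dil), nrow(nucleus)) & !nucleus
  rep_ch <- img[2L, , ]
  value <- (mean(rep_ch[nucleus]) + eps) / (mean(rep_ch[ring]) + eps)
  structure(list(value = value, n_objects = 1L,
                 masks_used = list(nucleus = nucleus, cytoplasm = ring)),
            class = "latsr_feature")
}

#' Mean reporter spot area
#'
#' Thresholds the reporter channel at its Otsu level within the cell mask
#' (from the cell-body channel), labels 8-connected components, discards
#' components below `min_area`, and returns the mean component area in
#' pixels. Zero components give value 0 (not an error).
#'
#' @param img 3-channel file-range image.
#' @param min_area minimum component area kept (default 2 px).
#' @return list of class `latsr_feature`: `value`, `n_objects`,
#'   `masks_used` (the spot label image).
#' @export
mean_spot_area <- function(img, min_area = 2L) {
  check_image(img)
  stopifnot(dim(img)[1L] >= 3L)
  cellmask <- tryCatch(segment_nucleus(img[3L, , ], smooth_sigma = 1),
                       error = function(e) matrix(TRUE, dim(img)[2L],
                                                  dim(img)[3L]))
  rep_ch <- img[2L, , ]
  vals <- rep_ch[cellmask]
  thr <- otsu_threshold(vals)
  mask <- rep_ch > thr & cellmask
  lab <- label_components8(mask)
  if (max(lab) == 0L)
    return(structure(list(value = 0, n_objects = 0L,
                          masks_used = list(labels = lab)),
                     class = "latsr_feature"))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (!length(keep))
    return(structure(list(value = 0, n_objects = 0L,
                          masks_used = list(labels = lab)),
                     class = "latsr_feature"))
  lab[!(lab %in% keep)] <- 0L
  structure(list(value = mean(sizes[keep]), n_objects = length(keep),
                 masks_used = list(labels = lab)),
            class = "latsr_feature")
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(1 / MSE)` for file-range images, capped at 100 dB for
#' (near-)identical inputs.
#'
#' @param a,b images of identical shape, values in `[0, 1]`.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse < 1e-10) return(100)
  10 * log10(1 / mse)
}

#' Mean absolute (L1) distance between two images
#' @param a,b images of identical shape.
#' @return mean absolute difference.
#' @export
l1_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  mean(abs(a - b))
}

# 2-D 'valid' correlation with a separable kernel
filter_valid <- function(M, k) {
  r <- (length(k) - 1L) / 2
  n <- nrow(M); m <- ncol(M)
  K1 <- function(nn) {
    B <- matrix(0, nn - 2L * r, nn)
    for (j in seq_len(nn - 2L * r)) B[j, j:(j + 2L * r)] <- k
    B
  }
  K1(n) %*% M %*% t(K1(m))
}

ssim_maps <- function(a, b, L = 1) {
  k <- stats::dnorm(seq(-5, 5), sd = 1.5)
  k <- k / sum(k)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mu_a <- filter_valid(a, k); mu_b <- filter_valid(b, k)
  saa <- filter_valid(a * a, k) - mu_a^2
  sbb <- filter_valid(b * b, k) - mu_b^2
  sab <- filter_valid(a * b, k) - mu_a * mu_b
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  cs <- (2 * sab + C2) / (saa + sbb + C2)
  list(l = mean(l), cs = mean(cs))
}

downsample2 <- function(M) {
  n <- 2L * (nrow(M) %/% 2L); m <- 2L * (ncol(M) %/% 2L)
  M <- M[seq_len(n), seq_len(m), drop = FALSE]
  0.25 * (M[seq(1L, n, 2L), seq(1L, m, 2L), drop = FALSE] +
          M[seq(2L, n, 2L), seq(1L, m, 2L), drop = FALSE] +
          M[seq(1L, n, 2L), seq(2L, m, 2L), drop = FALSE] +
          M[seq(2L, n, 2L), seq(2L, m, 2L), drop = FALSE])
}

#' Multi-scale structural similarity
#'
#' Standard 5-scale construction: per-scale SSIM with an 11 x 11 Gaussian
#' window (sigma 1.5), stability constants `(0.01 L)^2`, `(0.03 L)^2`, scale
#' weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333) and dyadic 2 x 2 mean
#' downsampling. The contrast-structure terms of the coarser scales multiply
#' the full SSIM of the last scale, each raised to its weight (signs are
#' preserved). For small images the number of scales is reduced so the
#' window always fits, with the weights renormalized. Multi-channel images
#' are averaged over channels.
#'
#' @param a,b images of identical shape, values in `[0, 1]`.
#' @param max_scales cap on the number of scales (default 5).
#' @return similarity in `[-1, 1]`; 1 iff the inputs are identical.
#' @export
ms_ssim <- function(a, b, max_scales = 5L) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  if (length(dim(a)) == 2L) {
    a <- array(a, c(1L, dim(a)))
    b <- array(b, c(1L, dim(b)))
  }
  d <- dim(a)
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  n_scales <- min(max_scales, floor(log2(min(d[2L], d[3L]) / 11)) + 1L)
  if (n_scales < 1L) stop("image too small for an 11x11 SSIM window",
                          call. = FALSE)
  w <- weights[seq_len(n_scales)]
  w <- w / sum(w)
  per_channel <- vapply(seq_len(d[1L]), function(ch) {
    A <- a[ch, , ]; B <- b[ch, , ]
    val <- 1
    for (s in seq_len(n_scales)) {
      sm <- ssim_maps(A, B)
      term <- if (s < n_scales) sm$cs else sm$l * sm$cs
      val <- val * sign(term) * abs(term)^w[s]
      if (s < n_scales) {
        A <- downsample2(A); B <- downsample2(B)
      }
    }
    val
  }, 0)
  mean(per_channel)
}

#' Midpoint-of-medians threshold classifier
#'
#' Places the decision threshold midway between the class medians, assigns
#' the side of each class by its median, and reports the balanced accuracy
#' of that rule on the given samples. An interpretable stand-in for a
#' learned two-condition classifier.
#'
#' @param values_a,values_b feature values of the two classes (nonempty).
#' @return list with `threshold`, `accuracy` (balanced), and `direction`
#'   (+1 when class b lies above the threshold).
#' @export
threshold_classify <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both classes must be nonempty", call. = FALSE)
  ma <- stats::median(values_a)
  mb <- stats::median(values_b)
  thr <- (ma + mb) / 2
  dir <- if (mb >= ma) 1 else -1
  acc_a <- if (dir > 0) mean(values_a < thr) else mean(values_a >= thr)
  acc_b <- if (dir > 0) mean(values_b >= thr) else mean(values_b < thr)
  list(threshold = thr, accuracy = (acc_a + acc_b) / 2, direction = dir)
}

#' Compute assay features for a set of images
#'
#' @param imgs list of file-range images.
#' @param assay `"translocation"` or `"golgi"`.
#' @param ... extractor options.
#' @return numeric vector of feature values (NA where extraction failed).
#' @export
extract_features <- function(imgs, assay = c("translocation", "golgi"),
                             ...) {
  assay <- match.arg(assay)
  f <- if (assay == "translocation") translocation_ratio else mean_spot_area
  vapply(imgs, function(im)
    tryCatch(f(im, ...)$value, error = function(e) NA_real_), 0)
}
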