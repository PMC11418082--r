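#' Forward (degradation) operators
#'
#' The forward operator D relates the high-resolution image to its
#' low-resolution observation. The core step is an antialiased, differentiable
#' bicubic downscale (Keys kernel, a = -0.5, kernel support stretched by the
#' scale factor, reflect boundary). Optional corruption steps — Gaussian noise,
#' salt-and-pepper and Gaussian blur — model robustness scenarios; the
#' robustness protocol applies them to the already-downscaled image.
#'
#' All operators act on channels-first images in the internal `[-1, 1]` range.
#' The downscale and blur are linear in the image, so their adjoints (used for
#' gradient propagation) are the matrix transposes of the row/column filters.
#'
#' @name latsr-degradation
NULL

# Keys bicubic kernel, a = -0.5 (Catmull-Rom)
bicubic_kernel <- function(t, a = -0.5) {
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# reflect an 0-based index into [0, n-1] ('symmetric' boundary)
reflect_index <- function(i, n) {
  i[i < 0] <- -1L - i[i < 0]
  i[i >= n] <- 2L * n - 1L - i[i >= n]
  if (any(i < 0 | i >= n)) i <- reflect_index(i, n)
  i
}

# n_out x n_in row-stochastic matrix for an antialiased 1-D bicubic downscale
bicubic_matrix <- function(n_in, factor) {
  n_out <- n_in %/% factor
  D <- matrix(0, n_out, n_in)
  half <- 2 * factor
  for (j in seq_len(n_out)) {
    src <- (j - 0.5) * factor - 0.5            # 0-based input coordinate
    i <- seq.int(floor(src) - half + 1L, floor(src) + half)
    w <- bicubic_kernel((i - src) / factor)
    ii <- reflect_index(as.integer(i), n_in) + 1L
    for (k in seq_along(ii)) D[j, ii[k]] <- D[j, ii[k]] + w[k]
  }
  D / rowSums(D)
}

.op_cache <- new.env(parent = emptyenv())

cached_bicubic <- function(n_in, factor) {
  key <- paste0("bc_", n_in, "_", factor)
  if (is.null(.op_cache[[key]]))
    .op_cache[[key]] <- bicubic_matrix(n_in, factor)
  .op_cache[[key]]
}

#' Antialiased bicubic downscale
#'
#' Separable Keys (a = -0.5) bicubic resampling with the kernel support
#' stretched by the factor (antialiasing) and reflect boundary handling.
#' Linear and differentiable in the image; `factor = 1` is the identity.
#'
#' @param img C x H x W array.
#' @param factor integer power of 2 dividing H and W (1 allowed).
#' @return C x (H/factor) x (W/factor) array.
#' @export
bicubic_downscale <- function(img, factor) {
  check_image(img)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) return(img)
  if (bitwAnd(factor, factor - 1L) != 0L)
    stop("factor must be a power of 2", call. = FALSE)
  d <- dim(img)
  if (d[2L] %% factor != 0L || d[3L] %% factor != 0L)
    stop("factor must divide image height and width", call. = FALSE)
  Dh <- cached_bicubic(d[2L], factor)
  Dw <- cached_bicubic(d[3L], factor)
  out <- array(0, c(d[1L], nrow(Dh), nrow(Dw)))
  for (c in seq_len(d[1L]))
    out[c, , ] <- Dh %*% img[c, , ] %*% t(Dw)
  out
}

# adjoint of bicubic_downscale, for backpropagation
bicubic_downscale_adjoint <- function(grad_lr, hr_dim, factor) {
  if (factor == 1L) return(grad_lr)
  Dh <- cached_bicubic(hr_dim[2L], factor)
  Dw <- cached_bicubic(hr_dim[3L], factor)
  out <- array(0, hr_dim)
  for (c in seq_len(hr_dim[1L]))
    out[c, , ] <- t(Dh) %*% grad_lr[c, , ] %*% Dw
  out
}

#' Bicubic upscale (baseline interpolation)
#'
#' Plain (non-antialiased) Keys bicubic interpolation used as the naive
#' upsampling baseline that super-resolution results are compared against.
#'
#' @param img C x H x W array.
#' @param factor integer upscale factor (power of 2).
#' @return C x (H*factor) x (W*factor) array.
#' @export
bicubic_upscale <- function(img, factor) {
  check_image(img)
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  d <- dim(img)
  up1 <- function(n_in) {
    n_out <- n_in * factor
    U <- matrix(0, n_out, n_in)
    for (j in seq_len(n_out)) {
      src <- (j - 0.5) / factor - 0.5
      i <- seq.int(floor(src) - 1L, floor(src) + 2L)
      w <- bicubic_kernel(i - src)
      ii <- reflect_index(as.integer(i), n_in) + 1L
      for (k in seq_along(ii)) U[j, ii[k]] <- U[j, ii[k]] + w[k]
    }
    U / rowSums(U)
  }
  key <- paste0("up_", d[2L], "_", d[3L], "_", factor)
  if (is.null(.op_cache[[key]]))
    .op_cache[[key]] <- list(up1(d[2L]), up1(d[3L]))
  UhUw <- .op_cache[[key]]
  out <- array(0, c(d[1L], d[2L] * factor, d[3L] * factor))
  for (c in seq_len(d[1L]))
    out[c, , ] <- UhUw[[1L]] %*% img[c, , ] %*% t(UhUw[[2L]])
  out
}

#' Additive Gaussian pixel noise
#'
#' @param img C x H x W array in `[-1, 1]`.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed; the draw is reproducible.
#' @param clip clip the result back to `[-1, 1]` (default TRUE).
#' @return corrupted image.
#' @export
add_gaussian_noise <- function(img, sigma, seed, clip = TRUE) {
  check_image(img)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  out <- img + array(with_seed(seed, stats::rnorm(length(img), 0, sigma)),
                     dim(img))
  if (clip) out <- pmin(pmax(out, -1), 1)
  out
}

#' Salt-and-pepper noise
#'
#' Each pixel is independently replaced by -1 or +1 (equal odds) with
#' probability `p`.
#'
#' @param img C x H x W array in `[-1, 1]`.
#' @param p corruption probability in `[0, 1]`.
#' @param seed integer seed.
#' @return corrupted image.
#' @export
add_salt_pepper <- function(img, p, seed) {
  check_image(img)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (p == 0) return(img)
  n <- length(img)
  draw <- with_seed(seed, {
    list(hit = stats::runif(n) < p, salt = stats::runif(n) < 0.5)
  })
  out <- as.numeric(img)
  out[draw$hit] <- ifelse(draw$salt[draw$hit], 1, -1)
  array(out, dim(img))
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with kernel radius `ceiling(3*sigma)` and
#' reflect padding. `sigma = 0` is the identity.
#'
#' @param img C x H x W array.
#' @param sigma blur standard deviation in pixels (>= 0).
#' @return blurred image.
#' @export
gaussian_blur <- function(img, sigma) {
  check_image(img)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(img)
  B1 <- function(n) {
    B <- matrix(0, n, n)
    for (j in seq_len(n)) {
      ii <- reflect_index(seq.int(j - 1L - r, j - 1L + r), n) + 1L
      for (m in seq_along(ii)) B[j, ii[m]] <- B[j, ii[m]] + k[m]
    }
    B
  }
  Bh <- B1(d[2L]); Bw <- if (d[3L] == d[2L]) Bh else B1(d[3L])
  out <- array(0, d)
  for (c in seq_len(d[1L]))
    out[c, , ] <- Bh %*% img[c, , ] %*% t(Bw)
  out
}

#' Compose a forward operator
#'
#' A forward operator is an ordered list of steps. Step kinds:
#' `bicubic_downscale` (params: `factor`), `gaussian_noise` (`sigma`, `seed`),
#' `salt_pepper` (`p`, `seed`), `gaussian_blur` (`sigma`). At most one
#' downscale step is allowed; the robustness protocol places corruptions after
#' it.
#'
#' @param ... steps created with [op_step()], or a single list of steps.
#' @return object of class `latsr_operator`.
#' @export
forward_operator <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1L]], "latsr_op_step") &&
      is.list(steps[[1L]]))
    steps <- steps[[1L]]
  kinds <- vapply(steps, function(s) s$kind, "")
  if (sum(kinds == "bicubic_downscale") > 1L)
    stop("at most one downscale step is allowed", call. = FALSE)
  structure(list(steps = steps), class = "latsr_operator")
}

#' @rdname forward_operator
#' @param kind step kind.
#' @param ... for `op_step()`: step parameters.
#' @export
op_step <- function(kind = c("bicubic_downscale", "gaussian_noise",
                             "salt_pepper", "gaussian_blur"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...)), class = "latsr_op_step")
}

#' Apply a forward operator to an image
#'
#' @param op `latsr_operator`.
#' @param img C x H x W array in `[-1, 1]`.
#' @return degraded image.
#' @export
apply_operator <- function(op, img) {
  stopifnot(inherits(op, "latsr_operator"))
  for (s in op$steps) {
    p <- s$params
    img <- switch(s$kind,
      bicubic_downscale = bicubic_downscale(img, p$factor),
      gaussian_noise = add_gaussian_noise(img, p$sigma, p$seed,
                                          clip = p$clip %||% TRUE),
      salt_pepper = add_salt_pepper(img, p$p, p$seed),
      gaussian_blur = gaussian_blur(img, p$sigma),
      stop("unknown step kind: ", s$kind, call. = FALSE))
  }
  img
}

# deterministic (noise-free) linear part used inside the optimization loop:
# the downscale, with any stochastic corruption steps ignored
operator_factor <- function(op) {
  f <- 1L
  for (s in op$steps)
    if (s$kind == "bicubic_downscale") f <- as.integer(s$params$factor)
  f
}

#' Parse a compact degradation description
#'
#' Accepts strings such as `"bicubic:16,gauss:0.05,sp:0.02,blur:1"` (used by
#' the command line) and returns the corresponding [forward_operator()].
#'
#' @param text degradation description.
#' @param seed integer seed assigned to stochastic steps.
#' @return `latsr_operator`.
#' @export
parse_operator <- function(text, seed = 1L) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1L]]
  steps <- lapply(seq_along(parts), function(i) {
    kv <- strsplit(trimws(parts[i]), ":", fixed = TRUE)[[1L]]
    val <- if (length(kv) > 1L) as.numeric(kv[2L]) else NA_real_
    switch(kv[1L],
      bicubic = op_step("bicubic_downscale", factor = as.integer(val)),
      gauss = op_step("gaussian_noise", sigma = val, seed = seed + i),
      sp = op_step("salt_pepper", p = val, seed = seed + i),
      blur = op_step("gaussian_blur", sigma = val),
      stop("unknown degradation: ", kv[1L], call. = FALSE))
  })
  forward_operator(steps)
}
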