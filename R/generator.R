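#' Style-based generators and the latent-space contract
#'
#' A generator pairs a mapping network `F : Z -> W` (noise to style vector)
#' with a synthesis network `G : W+ -> image`. The extended latent space W+
#' holds one d-dimensional style vector per synthesis layer (an L x d matrix),
#' which is the variable the regularized latent search optimizes.
#'
#' Two desk-scale instances are provided:
#' \itemize{
#'   \item `style_mini` ([make_style_mini()]): a 3-layer mapping MLP plus a
#'     modulated-convolution synthesis stack (constant 4x4 input, nearest
#'     upsampling, 3x3 modulated convolutions, leaky-ReLU, tanh-bounded RGB
#'     head). Weights are drawn once from a seed and frozen — the method under
#'     study is the latent search, not generator training. The path-length
#'     penalty used when training full-scale style generators is not
#'     implemented here; the synthesis Jacobian is simply treated as constant,
#'     which is the assumption under which the image prior reduces to a prior
#'     on the style vectors.
#'   \item `linear_oracle` ([make_linear_oracle()]): `G(w) = reshape(A w) +
#'     offset` with full-column-rank `A`, giving closed-form least-squares
#'     solutions for oracle tests. Outputs are unbounded (flagged by
#'     `bounded = FALSE`). [fit_pca_generator()] builds a linear generator
#'     whose columns are principal components of an image collection, so its
#'     range contains realistic reconstructions of that collection.
#' }
#'
#' All operations are deterministic given their inputs and seeds, and
#' `synthesize()` has an analytic gradient with respect to the latent
#' ([synthesize_grad()]), verified against finite differences in the tests.
#'
#' @name latsr-generators
NULL

# ---- index plumbing for the convolutional stack ------------------------

# 3x3 im2col source indices at resolution n x n (column-major pixel index
# p = row + (col-1)*n); entry n*n+1 denotes the zero-padding row
conv_idx9 <- function(n) {
  P <- n * n
  rows <- rep(seq_len(n), n)
  cols <- rep(seq_len(n), each = n)
  idx <- matrix(P + 1L, P, 9L)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= n
    idx[ok, j] <- r2[ok] + (c2[ok] - 1L) * n
  }
  idx
}

# nearest-neighbour 2x upsample source indices (length (2n)^2)
up_idx2 <- function(n) {
  n2 <- 2L * n
  rows <- rep(seq_len(n2), n2)
  cols <- rep(seq_len(n2), each = n2)
  ((rows + 1L) %/% 2L) + (((cols + 1L) %/% 2L) - 1L) * n
}

.gen_idx_cache <- new.env(parent = emptyenv())

gen_indices <- function(n) {
  key <- as.character(n)
  if (is.null(.gen_idx_cache[[key]]))
    .gen_idx_cache[[key]] <- list(idx9 = conv_idx9(n), up = up_idx2(n))
  .gen_idx_cache[[key]]
}

im2col <- function(M, idx9) {
  P <- nrow(M); C <- ncol(M)
  Mz <- rbind(M, 0)
  X <- matrix(0, P, 9L * C)
  for (j in 1:9)
    X[, (j - 1L) * C + seq_len(C)] <- Mz[idx9[, j], , drop = FALSE]
  X
}

col2im <- function(Gcol, idx9, P, C) {
  G <- matrix(0, P, C)
  for (j in 1:9) {
    v <- idx9[, j]
    ok <- v <= P
    G[v[ok], ] <- G[v[ok], ] + Gcol[ok, (j - 1L) * C + seq_len(C),
                                    drop = FALSE]
  }
  G
}

# ---- constructors ------------------------------------------------------

#' Build the miniature style-based generator
#'
#' @param d style dimension (test default 16; full-scale models use 512).
#' @param size output side length, a power of 2 at least 8 (default 64,
#'   giving L = 8 style inputs).
#' @param n_channels output image channels (default 3).
#' @param seed seed from which all frozen weights are drawn.
#' @return object of class `latsr_generator`, kind `"style_mini"`.
#' @export
make_style_mini <- function(d = 16L, size = 64L, n_channels = 3L, seed = 1L) {
  stopifnot(size >= 8L, bitwAnd(as.integer(size), as.integer(size) - 1L) == 0L)
  d <- as.integer(d)
  n_blocks <- as.integer(log2(size / 4))
  L <- 2L * n_blocks
  ch <- pmax(8L, round(16 * 0.85^(0:n_blocks)))
  params <- with_seed(seed, {
    # orthogonal mapping layers (gain-corrected for the leaky ReLU) keep the
    # style covariance well conditioned, as in a trained mapping network,
    # while the activations still make the style distribution non-Gaussian
    map_slope <- 0.3
    gain <- sqrt(2 / (1 + map_slope^2))
    mapping <- lapply(1:3, function(i)
      list(W = qr.Q(qr(matrix(stats::rnorm(d * d), d, d))) * gain,
           b = stats::rnorm(d, 0, 0.1)))
    const <- matrix(stats::rnorm(16L * ch[1L]), 16L, ch[1L])
    layers <- vector("list", L)
    for (b in seq_len(n_blocks)) for (k in 1:2) {
      cin <- if (k == 1L) ch[b] else ch[b + 1L]
      cout <- ch[b + 1L]
      layers[[2L * (b - 1L) + k]] <- list(
        W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                   9L * cin, cout),
        b = stats::rnorm(cout, 0, 0.1),
        A = matrix(stats::rnorm(cin * d, 0, 0.25 / sqrt(d)), cin, d))
    }
    rgb <- list(W = matrix(stats::rnorm(ch[n_blocks + 1L] * n_channels, 0,
                                        1.5 / sqrt(ch[n_blocks + 1L])),
                           ch[n_blocks + 1L], n_channels),
                b = stats::rnorm(n_channels, 0, 0.2))
    list(mapping = mapping, const = const, layers = layers, rgb = rgb)
  })
  structure(list(kind = "style_mini", d = d, L = L,
                 output_shape = c(n_channels, size, size),
                 n_blocks = n_blocks, channels = ch, bounded = TRUE,
                 map_slope = 0.3, params = params),
            class = "latsr_generator")
}

#' Build the linear oracle generator
#'
#' `G(w) = reshape(A w)` with `A` full column rank; the mapping network is the
#' identity. `A` is exposed as `gen$params$A` for closed-form computations.
#'
#' @param d latent dimension (must not exceed the pixel count).
#' @param output_shape integer c(C, H, W).
#' @param seed seed for drawing `A`.
#' @param L number of style copies (default 1).
#' @return object of class `latsr_generator`, kind `"linear_oracle"`.
#' @export
make_linear_oracle <- function(d, output_shape, seed = 1L, L = 1L) {
  m <- prod(output_shape)
  if (d > m) stop("d must not exceed the number of pixels", call. = FALSE)
  A <- NULL
  for (try in 1:10) {
    A <- with_seed(seed + (try - 1L) * 1000L,
                   matrix(stats::rnorm(m * d), m, d))
    if (qr(A)$rank == d) break
    A <- NULL
  }
  if (is.null(A)) stop("could not draw a full-column-rank A", call. = FALSE)
  structure(list(kind = "linear_oracle", d = as.integer(d), L = as.integer(L),
                 output_shape = as.integer(output_shape), bounded = FALSE,
                 params = list(A = A, offset = numeric(m))),
            class = "latsr_generator")
}

#' Fit a linear generator to an image collection by PCA
#'
#' The generator range is the affine span of the first `d` principal
#' components of the (internal-range) images, scaled so that the latent codes
#' of the fitted collection have approximately unit variance per coordinate.
#' Latent codes of new images are recovered with [project_latent()].
#'
#' @param imgs list of C x H x W arrays in `[-1, 1]`.
#' @param d number of components.
#' @param L number of style copies (default 1).
#' @return `latsr_generator` of kind `"linear_oracle"` with a mean-image
#'   offset.
#' @export
fit_pca_generator <- function(imgs, d, L = 1L) {
  X <- vapply(imgs, as.numeric, numeric(length(imgs[[1L]])))
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc, nu = d, nv = 0)
  scale <- sv$d[seq_len(d)] / sqrt(max(1L, ncol(X) - 1L))
  if (any(scale <= 1e-12))
    stop("image collection has rank below d", call. = FALSE)
  A <- sv$u %*% diag(scale, d)
  structure(list(kind = "linear_oracle", d = as.integer(d), L = as.integer(L),
                 output_shape = dim(imgs[[1L]]), bounded = FALSE,
                 params = list(A = A, offset = mu)),
            class = "latsr_generator")
}

#' Project an image onto a linear generator's range
#'
#' Least-squares latent code `w* = A^+ (x - offset)`; `G(w*)` is the in-range
#' target closest to `x`.
#'
#' @param img C x H x W array in the internal range.
#' @param gen linear-oracle generator.
#' @return latent vector of length `gen$d`.
#' @export
project_latent <- function(img, gen) {
  stopifnot(gen$kind == "linear_oracle")
  A <- gen$params$A
  drop(qr.solve(crossprod(A), crossprod(A, as.numeric(img) - gen$params$offset)))
}

#' @export
print.latsr_generator <- function(x, ...) {
  cat(sprintf("<latsr_generator kind=%s d=%d L=%d output=%s bounded=%s>\n",
              x$kind, x$d, x$L, paste(x$output_shape, collapse = "x"),
              x$bounded))
  invisible(x)
}

# ---- mapping network ---------------------------------------------------

map_latent_batch <- function(Z, gen) {
  if (ncol(Z) != gen$d) stop("latent dimension mismatch: expected ", gen$d,
                             ", got ", ncol(Z), call. = FALSE)
  if (gen$kind == "linear_oracle") return(Z)
  H <- Z
  for (lay in gen$params$mapping)
    H <- lrelu(H %*% lay$W + rep(lay$b, each = nrow(H)),
               slope = gen$map_slope %||% 0.3)
  H
}

#' Map a noise vector to a style vector
#'
#' Applies the mapping network F. For the linear oracle, F is the identity.
#'
#' @param z numeric vector of length `gen$d` (standard-normal noise).
#' @param gen `latsr_generator`.
#' @return style vector w of length `gen$d`.
#' @export
map_latent <- function(z, gen) {
  if (length(z) != gen$d) stop("latent dimension mismatch: expected ", gen$d,
                               ", got ", length(z), call. = FALSE)
  drop(map_latent_batch(matrix(z, 1L), gen))
}

#' Mean style vector over random draws
#'
#' Draws `n` standard-normal noise vectors (reproducibly from `seed`), maps
#' them through F, and returns their mean — the latent-search initialization.
#'
#' @param gen `latsr_generator`.
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @return style vector of length `gen$d`.
#' @export
mean_latent <- function(gen, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  Z <- with_seed(seed, matrix(stats::rnorm(n * gen$d), n, gen$d))
  colMeans(map_latent_batch(Z, gen))
}

# ---- synthesis ---------------------------------------------------------

check_wplus <- function(wplus, gen) {
  if (is.null(dim(wplus))) wplus <- matrix(wplus, 1L)
  if (nrow(wplus) != gen$L || ncol(wplus) != gen$d)
    stop("W+ shape mismatch: expected ", gen$L, " x ", gen$d, call. = FALSE)
  if (!all(is.finite(wplus))) stop("W+ contains non-finite values",
                                   call. = FALSE)
  wplus
}

synth_style_forward <- function(wplus, gen, keep_cache = FALSE) {
  p <- gen$params
  M <- p$const
  cache <- if (keep_cache) vector("list", gen$L) else NULL
  l <- 0L
  n <- 4L
  for (b in seq_len(gen$n_blocks)) {
    gi <- gen_indices(2L * n)
    M <- M[gen_indices(n)$up, , drop = FALSE]
    n <- 2L * n
    for (k in 1:2) {
      l <- l + 1L
      lay <- p$layers[[l]]
      cin <- ncol(M)
      s <- 1 + drop(lay$A %*% wplus[l, ])
      Weff <- lay$W * rep(s, 9L)
      Xc <- im2col(M, gi$idx9)
      Ypre <- Xc %*% Weff + rep(lay$b, each = nrow(Xc))
      if (keep_cache) cache[[l]] <- list(Xc = Xc, Ypre = Ypre, s = s,
                                         cin = cin, n = n)
      M <- lrelu(Ypre)
    }
  }
  pre_rgb <- M %*% p$rgb$W + rep(p$rgb$b, each = nrow(M))
  out <- tanh(pre_rgb)
  sh <- gen$output_shape
  img <- array(0, sh)
  for (c in seq_len(sh[1L])) img[c, , ] <- matrix(out[, c], sh[2L], sh[3L])
  list(img = img, out = out, Mlast = M, cache = cache)
}

#' Synthesize an image from an extended latent
#'
#' @param wplus L x d matrix (or a length-d vector, broadcast over layers when
#'   L > 1 would be ambiguous — a vector is only accepted when L = 1).
#' @param gen `latsr_generator`.
#' @return C x H x W array; in `[-1, 1]` for bounded generators.
#' @export
synthesize <- function(wplus, gen) {
  wplus <- check_wplus(wplus, gen)
  if (gen$kind == "linear_oracle") {
    v <- gen$params$A %*% colMeans(wplus) + gen$params$offset
    return(array(v, gen$output_shape))
  }
  synth_style_forward(wplus, gen)$img
}

# forward pass returning the image and a backward closure over the cached
# intermediates (internal; one forward serves many upstream gradients)
synth_with_grad <- function(wplus, gen) {
  wplus <- check_wplus(wplus, gen)
  if (gen$kind == "linear_oracle") {
    v <- gen$params$A %*% colMeans(wplus) + gen$params$offset
    return(list(
      value = array(v, gen$output_shape),
      backward = function(grad_img) {
        gw <- drop(crossprod(gen$params$A, as.numeric(grad_img))) / gen$L
        matrix(rep(gw, each = gen$L), gen$L, gen$d)
      }))
  }
  fw <- synth_style_forward(wplus, gen, keep_cache = TRUE)
  p <- gen$params
  sh <- gen$output_shape
  P <- sh[2L] * sh[3L]
  list(value = fw$img, backward = function(grad_img) {
    Gout <- vapply(seq_len(sh[1L]), function(c) as.numeric(grad_img[c, , ]),
                   numeric(P))
    Gpre <- Gout * (1 - fw$out^2)
    GM <- Gpre %*% t(p$rgb$W)
    Gw <- matrix(0, gen$L, gen$d)
    for (b in rev(seq_len(gen$n_blocks))) {
      for (k in 2:1) {
        l <- 2L * (b - 1L) + k
        lay <- p$layers[[l]]
        cc <- fw$cache[[l]]
        gi <- gen_indices(cc$n)
        Gpre_l <- GM * lrelu_grad(cc$Ypre)
        GWeff <- crossprod(cc$Xc, Gpre_l)
        v <- rowSums(GWeff * lay$W)
        ds <- rowSums(matrix(v, cc$cin, 9L))
        Gw[l, ] <- drop(crossprod(lay$A, ds))
        Weff <- lay$W * rep(cc$s, 9L)
        GM <- col2im(Gpre_l %*% t(Weff), gi$idx9, nrow(GM), cc$cin)
      }
      # undo the 2x nearest upsample at the start of the block
      n_in <- 2L^(b + 1L)
      GM <- rowsum(GM, gen_indices(n_in)$up)
    }
    Gw
  })
}

#' Gradient of a scalar loss through the synthesis network
#'
#' Given `d loss / d image`, returns `d loss / d W+` by analytic
#' backpropagation (style modulation path and feature path).
#'
#' @param wplus L x d matrix.
#' @param gen `latsr_generator`.
#' @param grad_img C x H x W array of upstream gradients.
#' @return list with `value` (the synthesized image) and `grad` (L x d).
#' @export
synthesize_grad <- function(wplus, gen, grad_img) {
  s <- synth_with_grad(wplus, gen)
  list(value = s$value, grad = s$backward(grad_img))
}

# ---- checkpoints -------------------------------------------------------

#' Save / load generator checkpoints
#'
#' Uses the shared container format (JSON header + named double arrays), so
#' any externally trained generator matching the mapping/synthesis contract
#' can be packaged and loaded without code changes.
#'
#' @param gen `latsr_generator`.
#' @param path checkpoint file path.
#' @name generator-checkpoints
#' @export
save_generator <- function(gen, path) {
  meta <- list(kind = gen$kind, d = gen$d, L = gen$L,
               output_shape = gen$output_shape, bounded = gen$bounded)
  arrays <- list()
  if (gen$kind == "linear_oracle") {
    arrays$A <- gen$params$A
    arrays$offset <- gen$params$offset
  } else {
    meta$n_blocks <- gen$n_blocks
    meta$channels <- gen$channels
    for (i in 1:3) {
      arrays[[paste0("map_W", i)]] <- gen$params$mapping[[i]]$W
      arrays[[paste0("map_b", i)]] <- gen$params$mapping[[i]]$b
    }
    arrays$const <- gen$params$const
    for (l in seq_len(gen$L)) {
      arrays[[paste0("conv_W", l)]] <- gen$params$layers[[l]]$W
      arrays[[paste0("conv_b", l)]] <- gen$params$layers[[l]]$b
      arrays[[paste0("conv_A", l)]] <- gen$params$layers[[l]]$A
    }
    arrays$rgb_W <- gen$params$rgb$W
    arrays$rgb_b <- gen$params$rgb$b
  }
  write_checkpoint(meta, arrays, path)
}

#' @rdname generator-checkpoints
#' @export
load_generator <- function(path) {
  ck <- read_checkpoint(path)
  m <- ck$meta
  if (m$kind == "linear_oracle") {
    gen <- structure(list(kind = m$kind, d = as.integer(m$d),
                          L = as.integer(m$L),
                          output_shape = as.integer(m$output_shape),
                          bounded = FALSE,
                          params = list(A = ck$arrays$A,
                                        offset = ck$arrays$offset)),
                     class = "latsr_generator")
    return(gen)
  }
  mapping <- lapply(1:3, function(i)
    list(W = ck$arrays[[paste0("map_W", i)]],
         b = ck$arrays[[paste0("map_b", i)]]))
  layers <- lapply(seq_len(m$L), function(l)
    list(W = ck$arrays[[paste0("conv_W", l)]],
         b = ck$arrays[[paste0("conv_b", l)]],
         A = ck$arrays[[paste0("conv_A", l)]]))
  structure(list(kind = m$kind, d = as.integer(m$d), L = as.integer(m$L),
                 output_shape = as.integer(m$output_shape),
                 n_blocks = as.integer(m$n_blocks),
                 channels = as.integer(m$channels), bounded = TRUE,
                 params = list(mapping = mapping, const = ck$arrays$const,
                               layers = layers,
                               rgb = list(W = ck$arrays$rgb_W,
                                          b = ck$arrays$rgb_b))),
            class = "latsr_generator")
}
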