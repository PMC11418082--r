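#' Synthetic cell-painting-style microscopy simulator
#'
#' Renders 3-channel single-cell crops emulating cell-painting-style imagery
#' centered on a nucleus: channel 1 is the DNA stain (soft-edged nuclear
#' ellipse), channel 2 a phenotype reporter, channel 3 the cell body. Two
#' assays are parameterized:
#' \itemize{
#'   \item `translocation`: the reporter distributes between nucleus and
#'     cytoplasm with fraction `t` in the nucleus (t = 0 fully cytoplasmic,
#'     t = 1 fully nuclear), emulating cytokine-induced nuclear translocation
#'     of a transcription factor;
#'   \item `golgi`: the reporter is `n_spots` perinuclear discs of radius
#'     `spot_radius`, emulating drug-induced scattering of the Golgi
#'     apparatus into smaller stacks (many small spots vs one compact one).
#' }
#' Photon noise follows the standard fluorescence camera model
#' `Poisson(photon_scale * signal) / photon_scale + N(0, read_noise^2)`;
#' set `photon_scale = 0` and `read_noise = 0` for noiseless renders. Images
#' are emitted in the file range `[0, 1]`.
#'
#' @name latsr-simulate
NULL

#' Phenotype parameters for a rendered cell
#'
#' @param assay `"translocation"` or `"golgi"`.
#' @param t translocation fraction in `[0, 1]` (translocation assay).
#' @param n_spots,spot_radius Golgi spot count (>= 1) and radius in pixels.
#' @param nucleus_radius,cell_radius geometry in pixels (nucleus must be
#'   smaller than the cell).
#' @param jitter random center displacement in pixels.
#' @param photon_scale photons at unit signal (0 disables Poisson noise).
#' @param read_noise Gaussian read-noise standard deviation.
#' @param seed integer seed controlling geometry jitter, spot placement and
#'   noise.
#' @return list of class `latsr_phenotype`.
#' @export
phenotype_params <- function(assay = c("translocation", "golgi"), t = 0.5,
                             n_spots = 1L, spot_radius = 5,
                             nucleus_radius = 10, cell_radius = 24,
                             jitter = 2, photon_scale = 200,
                             read_noise = 0.01, seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(t >= 0, t <= 1, n_spots >= 1, nucleus_radius < cell_radius)
  structure(list(assay = assay, t = t, n_spots = as.integer(n_spots),
                 spot_radius = spot_radius, nucleus_radius = nucleus_radius,
                 cell_radius = cell_radius, jitter = jitter,
                 photon_scale = photon_scale, read_noise = read_noise,
                 seed = as.integer(seed)),
            class = "latsr_phenotype")
}

#' Control presets for the two assays
#'
#' Negative controls (vehicle) and positive controls (treated): the
#' translocation assay contrasts `t = 0.1` vs `t = 0.9`; the Golgi assay
#' contrasts one compact spot of radius 5 vs eight scattered spots of radius
#' 1.5.
#'
#' @param assay assay name.
#' @param condition `"control"` or `"treated"`.
#' @param ... overrides passed to [phenotype_params()].
#' @return `latsr_phenotype`.
#' @export
phenotype_preset <- function(assay = c("translocation", "golgi"),
                             condition = c("control", "treated"), ...) {
  assay <- match.arg(assay)
  condition <- match.arg(condition)
  args <- if (assay == "translocation") {
    list(assay = assay, t = if (condition == "control") 0.1 else 0.9)
  } else if (condition == "control") {
    list(assay = assay, n_spots = 1L, spot_radius = 5)
  } else {
    list(assay = assay, n_spots = 8L, spot_radius = 1.5)
  }
  do.call(phenotype_params, utils::modifyList(args, list(...)))
}

# soft-edged ellipse indicator on a size x size grid
soft_ellipse <- function(size, cy, cx, ry, rx, angle = 0, softness = 1) {
  ys <- matrix(rep(seq_len(size), size), size) - cy
  xs <- t(ys) + cy - cx
  ca <- cos(angle); sa <- sin(angle)
  yr <- ys * ca - xs * sa
  xr <- ys * sa + xs * ca
  r <- sqrt((yr / ry)^2 + (xr / rx)^2)
  1 / (1 + exp((r - 1) * max(ry, rx) / softness))
}

#' Render a single synthetic cell
#'
#' @param params [phenotype_params()].
#' @param size canvas side in pixels (default 64; warned when the cell does
#'   not comfortably fit).
#' @return list with `image` (3 x size x size array in `[0, 1]`) and `truth`
#'   (`nucleus_mask`, `cell_mask` logical matrices; `spot_centers`,
#'   `spot_areas` for the Golgi assay).
#' @export
render_cell <- function(params, size = 64L) {
  p <- params
  if (size < 2.2 * p$cell_radius)
    warning("canvas is small for the requested cell radius", call. = FALSE)
  geom <- with_seed(p$seed, {
    c0 <- (size + 1) / 2
    center <- c0 + stats::runif(2, -p$jitter, p$jitter)
    nrad <- p$nucleus_radius * stats::runif(2, 0.85, 1.15)
    angle <- stats::runif(1, 0, pi)
    spots <- NULL
    if (p$assay == "golgi") {
      # spot centers sit in the perinuclear ring; large compact spots may
      # overlap the nuclear edge, as the Golgi does
      r_in <- mean(nrad) + 1
      r_out <- p$cell_radius - p$spot_radius - 2
      if (r_out <= r_in) stop("spots cannot fit between nucleus and membrane",
                              call. = FALSE)
      centers <- matrix(0, 0, 2)
      tries <- 0L
      while (nrow(centers) < p$n_spots) {
        tries <- tries + 1L
        if (tries > 500L)
          stop("could not place Golgi spots without overlap", call. = FALSE)
        th <- stats::runif(1, 0, 2 * pi)
        rr <- sqrt(stats::runif(1, (r_in / r_out)^2, 1)) * r_out
        cand <- center + rr * c(sin(th), cos(th))
        if (nrow(centers) == 0L ||
            min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
              2 * p$spot_radius + 1.5)
          centers <- rbind(centers, cand)
      }
      spots <- centers
    }
    list(center = center, nrad = nrad, angle = angle, spots = spots)
  })
  nucleus <- soft_ellipse(size, geom$center[1L], geom$center[2L],
                          geom$nrad[1L], geom$nrad[2L], geom$angle,
                          softness = 1)
  cell <- soft_ellipse(size, geom$center[1L], geom$center[2L],
                       p$cell_radius, p$cell_radius * 0.95, 0,
                       softness = 1.5)
  cyto <- pmax(cell - nucleus, 0)
  dna <- 0.85 * nucleus + 0.02 * cell
  body <- 0.55 * cell + 0.15 * nucleus
  truth <- list(nucleus_mask = nucleus > 0.5, cell_mask = cell > 0.5,
                spot_centers = geom$spots, spot_areas = NULL)
  if (p$assay == "translocation") {
    reporter <- 0.9 * (p$t * nucleus + (1 - p$t) * cyto) + 0.02 * cell
  } else {
    reporter <- 0.03 * cell
    areas <- integer(nrow(geom$spots))
    for (i in seq_len(nrow(geom$spots))) {
      spot <- soft_ellipse(size, geom$spots[i, 1L], geom$spots[i, 2L],
                           p$spot_radius, p$spot_radius, 0, softness = 0.5)
      reporter <- reporter + 0.9 * spot
      areas[i] <- sum(spot > 0.5)
    }
    truth$spot_areas <- areas
    reporter <- pmin(reporter, 1)
  }
  img <- array(0, c(3L, size, size))
  img[1L, , ] <- dna
  img[2L, , ] <- reporter
  img[3L, , ] <- body
  if (p$photon_scale > 0 || p$read_noise > 0) {
    img <- with_seed(p$seed + 104729L, {
      x <- img
      if (p$photon_scale > 0)
        x <- array(stats::rpois(length(x), p$photon_scale * as.numeric(x)) /
                     p$photon_scale, dim(x))
      if (p$read_noise > 0)
        x <- x + array(stats::rnorm(length(x), 0, p$read_noise), dim(x))
      x
    })
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, truth = truth)
}

#' Build a two-condition sampler over phenotype parameters
#'
#' Returns a function of an index that yields a control or treated
#' [phenotype_preset()] with the given probability, with per-image seeds
#' derived from the base seed.
#'
#' @param assay assay name.
#' @param p_treated probability of the treated condition (default 0.5).
#' @param seed base seed.
#' @param ... overrides forwarded to [phenotype_preset()].
#' @return function(i) returning a list with `params` and `condition`.
#' @export
condition_sampler <- function(assay = c("translocation", "golgi"),
                              p_treated = 0.5, seed = 1L, ...) {
  assay <- match.arg(assay)
  extra <- list(...)
  function(i) {
    treated <- with_seed(seed + 7919L * i, stats::runif(1) < p_treated)
    cond <- if (treated) "treated" else "control"
    params <- do.call(phenotype_preset,
                      c(list(assay = assay, condition = cond,
                             seed = seed + 13L * i), extra))
    list(params = params, condition = cond)
  }
}

#' Simulate a dataset of synthetic cells
#'
#' Writes `n` multi-channel TIFFs and a CSV manifest (filename, assay,
#' condition, t or n_spots/spot_radius, seed); fully reproducible from the
#' seed embedded in the sampler.
#'
#' @param n number of images.
#' @param sampler a function(i) as returned by [condition_sampler()].
#' @param out_dir output directory (created if missing).
#' @param size canvas side in pixels.
#' @return the manifest data.frame (invisibly carries the image list as
#'   attribute `"images"`).
#' @export
make_dataset <- function(n, sampler, out_dir, size = 64L) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", n)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sampler(i)
    r <- render_cell(s$params, size = size)
    fn <- sprintf("cell_%04d.tif", i)
    write_image(r$image, file.path(out_dir, fn))
    imgs[[i]] <- r$image
    rows[[i]] <- data.frame(
      filename = fn, assay = s$params$assay, condition = s$condition,
      t = if (s$params$assay == "translocation") s$params$t else NA_real_,
      n_spots = if (s$params$assay == "golgi") s$params$n_spots else
        NA_integer_,
      spot_radius = if (s$params$assay == "golgi") s$params$spot_radius else
        NA_real_,
      seed = s$params$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "images") <- imgs
  invisible(manifest)
}
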