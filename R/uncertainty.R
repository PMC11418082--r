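#' Uncertainty of the super-resolved reconstruction
#'
#' Super-resolution is ill-posed: several nearby HR images are consistent
#' with one LR input. To expose this, K latent codes are drawn from a
#' Gaussian posterior centered at the MAP latent, `w_k ~ N(w_MAP, sigma^2 I)`
#' per style copy, where the shared scale has an inverse-gamma prior
#' `sigma^2 ~ InvGamma(alpha, beta)`. The scale is estimated by maximizing
#' the log posterior: the Laplace log-likelihood of the MAP residual (the
#' objective's data term) at scale sigma plus the inverse-gamma log prior —
#' the prior itself penalizes large sigma, so no additional penalty term is
#' added. Each sampled latent is optionally refined for a few objective
#' steps to keep the samples data-consistent, and the per-pixel standard
#' deviation across the K syntheses summarizes the reconstruction
#' variability.
#'
#' @name latsr-uncertainty
NULL

#' Uncertainty-sampling configuration
#'
#' @param K number of posterior samples (default 5).
#' @param alpha,beta inverse-gamma shape/scale (> 0, defaults 1, 1).
#' @param refine_iters per-sample refinement steps on the objective
#'   (default 20; 0 gives pure prior samples).
#' @param refine_lr step size of the refinement (default 0.1 — much smaller
#'   than the global search step: refinement must restore data consistency
#'   without traversing the posterior and collapsing sample diversity).
#' @param data_tol_mult data-consistency tolerance: a refined sample whose
#'   data term exceeds `data_tol_mult` times the MAP data term is flagged.
#' @param seed integer seed.
#' @return list of class `latsr_unc_config`.
#' @export
uncertainty_config <- function(K = 5L, alpha = 1, beta = 1,
                               refine_iters = 20L, refine_lr = 0.1,
                               data_tol_mult = 2, seed = 1L) {
  stopifnot(K >= 1, alpha > 0, beta > 0, refine_iters >= 0, refine_lr > 0)
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 refine_iters = as.integer(refine_iters),
                 refine_lr = refine_lr,
                 data_tol_mult = data_tol_mult, seed = as.integer(seed)),
            class = "latsr_unc_config")
}

#' Estimate the posterior latent scale
#'
#' Maximizes, over sigma, the Laplace log-likelihood of the MAP data residual
#' plus the inverse-gamma log prior on sigma^2, by 1-D bounded search. With a
#' zero residual the likelihood carries no information and the prior mode
#' `beta / (alpha + 1)` is returned.
#'
#' @param result `latsr_rls_result` from [superresolve()].
#' @param cfg [uncertainty_config()].
#' @param n_pixels number of LR pixels behind the residual (taken from the
#'   result's data term scale; default 64 when unknown only affects the
#'   likelihood weight).
#' @return scalar sigma-hat > 0.
#' @export
estimate_sigma <- function(result, cfg = uncertainty_config(),
                           n_pixels = NULL) {
  E <- unname(result$final_terms["data"])
  if (!is.finite(E) || E < 1e-12) return(cfg$beta / (cfg$alpha + 1))
  n <- n_pixels %||% 64L
  logpost <- function(log_sigma) {
    s <- exp(log_sigma)
    ll <- -n * E / s - n * log(2 * s)
    lp <- -(cfg$alpha + 1) * 2 * log_sigma - cfg$beta / s^2
    ll + lp
  }
  opt <- stats::optimize(logpost, interval = c(log(1e-4), log(50)),
                         maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

#' Sample plausible super-resolved reconstructions
#'
#' Draws `K` latents from `N(w_MAP, sigma_hat^2 I)`, refines each for
#' `refine_iters` objective steps, synthesizes the K images and computes the
#' per-pixel standard deviation. Samples whose refined data term exceeds the
#' configured tolerance multiple of the MAP data term are flagged (never
#' dropped).
#'
#' @param lr_img the LR image used for the MAP fit (internal range).
#' @param result `latsr_rls_result` from [superresolve()] on `lr_img`.
#' @param gen,op,flow,rls_cfg as in [superresolve()].
#' @param unc_cfg [uncertainty_config()].
#' @param sigma override for sigma-hat (e.g. forcing 0 reproduces the MAP
#'   image K times).
#' @return object of class `latsr_sr_samples`: `images`, `latents`,
#'   `sigma_hat`, `pixel_std` (C x H x W), `data_terms`, `flagged`.
#' @export
sample_sr <- function(lr_img, result, gen, op, flow,
                      rls_cfg = rls_config(), unc_cfg = uncertainty_config(),
                      sigma = NULL) {
  check_image(lr_img, "lr_img")
  sigma_hat <- sigma %||% estimate_sigma(result, unc_cfg,
                                         n_pixels = length(lr_img))
  w0 <- result$wplus
  K <- unc_cfg$K
  draws <- with_seed(unc_cfg$seed,
                     lapply(seq_len(K), function(k)
                       w0 + matrix(stats::rnorm(length(w0), 0, sigma_hat),
                                   nrow(w0), ncol(w0))))
  refine_cfg <- rls_cfg
  refine_cfg$iterations <- unc_cfg$refine_iters
  refine_cfg$learning_rate <- unc_cfg$refine_lr %||% 0.1
  images <- vector("list", K)
  latents <- vector("list", K)
  data_terms <- numeric(K)
  for (k in seq_len(K)) {
    if (unc_cfg$refine_iters > 0L) {
      rk <- superresolve(lr_img, gen, op, flow, refine_cfg,
                         wplus_init = draws[[k]])
      latents[[k]] <- rk$wplus
      images[[k]] <- rk$sr_image
      data_terms[k] <- unname(rk$final_terms["data"])
    } else {
      latents[[k]] <- draws[[k]]
      images[[k]] <- synthesize(draws[[k]], gen)
      data_terms[k] <- data_term_value(images[[k]], lr_img,
                                       operator_factor(op),
                                       rls_cfg$data_norm)
    }
  }
  map_data <- unname(result$final_terms["data"])
  flagged <- data_terms > unc_cfg$data_tol_mult * max(map_data, 1e-12)
  stack <- vapply(images, as.numeric, numeric(length(images[[1L]])))
  px_sd <- if (K > 1L) apply(stack, 1L, stats::sd) else
    numeric(nrow(stack))
  structure(list(images = images, latents = latents, sigma_hat = sigma_hat,
                 pixel_std = array(px_sd, dim(images[[1L]])),
                 data_terms = data_terms, map_data_term = map_data,
                 flagged = flagged),
            class = "latsr_sr_samples")
}

#' @export
print.latsr_sr_samples <- function(x, ...) {
  cat(sprintf(
    "<latsr_sr_samples K=%d sigma_hat=%.4g mean_pixel_std=%.4g flagged=%d>\n",
    length(x$images), x$sigma_hat, mean(x$pixel_std), sum(x$flagged)))
  invisible(x)
}
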