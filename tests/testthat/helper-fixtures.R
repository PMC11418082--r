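# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; no stored data.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# tiny style generator for gradient-level tests
tiny_gen <- function() fixture("tiny_gen", function() {
  make_style_mini(d = 8, size = 16, seed = 3)
})

# desk-scale study generator (d = 16, 64 x 64, L = 8)
study_gen <- function() fixture("study_gen", function() {
  make_style_mini(d = 16, size = 64, seed = 11)
})

# 20k mapped style samples for flow training
study_latents <- function() fixture("study_latents", function() {
  gen <- study_gen()
  Z <- with_seed_test(5, matrix(stats::rnorm(20000 * gen$d), 20000, gen$d))
  latsr:::map_latent_batch(Z, gen)
})

# flow trained on the mapped style distribution (desk scale: 2 blocks x 64)
study_flow <- function() fixture("study_flow", function() {
  train_flow(study_latents(),
             flow_config(n_blocks = 2, hidden = 64, n_samples = 20000,
                         epochs = 20, batch_size = 256,
                         learning_rate = 2e-3, lr_decay = 0.9, seed = 4))
})

# in-range LR/HR pair from the study generator
study_target <- function(i, factor = 8) {
  gen <- study_gen()
  z <- with_seed_test(400 + i, stats::rnorm(gen$d))
  wstar <- map_latent(z, gen)
  hr <- synthesize(matrix(rep(wstar, each = gen$L), gen$L, gen$d), gen)
  op <- forward_operator(op_step("bicubic_downscale", factor = factor))
  list(wstar = wstar, hr = hr, lr = apply_operator(op, hr), op = op,
       factor = factor)
}

# PCA cell generator + flow for the two-step workflow tests
pca_assets <- function(assay) fixture(paste0("pca_", assay), function() {
  n_train <- if (assay == "golgi") 400L else 200L
  d <- if (assay == "golgi") 96L else 32L
  train_imgs <- lapply(seq_len(n_train), function(i) {
    cond <- if (i %% 2L == 0L) "treated" else "control"
    p <- phenotype_preset(assay, cond, seed = 2000L + i)
    to_internal(render_cell(p, size = 64)$image)
  })
  gen <- fit_pca_generator(train_imgs, d = d, L = 1L)
  W <- t(vapply(train_imgs, function(x) project_latent(x, gen), numeric(d)))
  flow <- train_flow(W, flow_config(n_blocks = 2, hidden = 32,
                                    n_samples = nrow(W), epochs = 30,
                                    batch_size = 32, learning_rate = 2e-3,
                                    lr_decay = 0.95, seed = 3))
  list(gen = gen, flow = flow)
})

# local-seed helper mirroring the package's internal convention
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# MAP result on a fixed in-range target, shared by the uncertainty tests
study_map_result <- function() fixture("study_map_result", function() {
  tg <- study_target(55)
  cfg <- rls_config(iterations = 150, seed = 9, init_samples = 2000)
  list(tg = tg, cfg = cfg,
       res = superresolve(tg$lr, study_gen(), tg$op, study_flow(), cfg))
})
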