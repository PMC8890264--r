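tiny_config <- function(...) {
  args <- utils::modifyList(
    list(grid_points = 8L, lig_channels = 4L, rec_channels = 4L,
         latent_dim = 6L, n_levels = 1L, block_widths = 4L),
    list(...))
  do.call(model_config, args)
}

random_grid <- function(spec, seed = 1) {
  set.seed(seed)
  np <- spec$points_per_axis
  density_grid(array(abs(rnorm(spec$n_channels * np^3, sd = 0.3)),
                     c(spec$n_channels, np, np, np)), spec)
}

test_that("KL divergence matches the diagonal-Gaussian closed form", {
  expect_equal(kl_divergence(latent_distribution(rep(0, 8), rep(1, 8))), 0)
  expect_equal(kl_divergence(latent_distribution(1, 1)), 0.5)
  expect_error(latent_distribution(0, 0), "positive")
  set.seed(4)
  mu <- rnorm(4); sd <- exp(rnorm(4, sd = 0.3))
  kl <- kl_divergence(latent_distribution(mu, sd))
  # Monte-Carlo oracle: E_q[log q - log p] over 1e5 samples
  n <- 1e5
  z <- matrix(rnorm(n * 4), n, 4)
  x <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  lq <- rowSums(sapply(1:4, function(d) dnorm(x[, d], mu[d], sd[d], log = TRUE)))
  lp <- rowSums(dnorm(x, log = TRUE))
  mc <- mean(lq - lp)
  se <- sd(lq - lp) / sqrt(n)
  expect_lt(abs(kl - mc), 3 * se)
})

test_that("reconstruction loss is the summed squared voxel error", {
  spec <- grid_spec(side = 2, n_channels = 2L)
  g <- random_grid(spec, 1)
  expect_equal(reconstruction_loss(g, g), 0)
  g2 <- g
  g2$values[1, 2, 2, 2] <- g2$values[1, 2, 2, 2] + 1
  expect_equal(reconstruction_loss(g2, g), 1)
  h <- random_grid(spec, 2)
  manual <- 0
  np <- spec$points_per_axis
  for (c in 1:2) for (ix in 1:np) for (iy in 1:np) for (iz in 1:np) {
    manual <- manual + (g$values[c, ix, iy, iz] - h$values[c, ix, iy, iz])^2
  }
  expect_equal(reconstruction_loss(g, h), manual, tolerance = 1e-10)
  expect_equal(reconstruction_loss(g, h, form = "mean"),
               manual / length(g$values), tolerance = 1e-10)
})

test_that("the KL weight ramps linearly between the printed endpoints", {
  w <- loss_weights()
  expect_equal(lambda_kl(0, w), 0.1)
  expect_equal(lambda_kl(449999, w), 0.1)
  expect_equal(lambda_kl(650000, w), 1.6)
  expect_equal(lambda_kl(550000, w), 0.85)
  expect_equal(lambda_kl(900000, w), 1.6)
  expect_error(lambda_kl(-1, w), "nonnegative")
})

test_that("total_loss is the weighted sum of its terms", {
  cfg <- tiny_config()
  spec_l <- model_grid_spec(cfg, role = "ligand")
  spec_r <- model_grid_spec(cfg, role = "receptor")
  lig <- random_grid(spec_l, 1); gen <- random_grid(spec_l, 2)
  rec <- random_grid(spec_r, 3)
  lat <- latent_distribution(c(1, -1), c(0.5, 2))
  w <- loss_weights()
  tl <- total_loss(lig, gen, rec, lat, w, iteration = 0)
  expect_equal(tl$total,
               4.0 * tl$terms$recon + 0.1 * tl$terms$kl + 1.0 * tl$terms$steric)
  w0 <- loss_weights(lambda_recon = 0, lambda_kl_init = 0, lambda_kl_final = 0,
                     lambda_steric = 0)
  expect_equal(total_loss(lig, gen, rec, lat, w0, 0)$total, 0)
  expect_equal(total_loss(lig, gen, rec, lat, w, 0)$terms$steric,
               steric_overlap(rec, gen))
})

test_that("encoders and decoder satisfy their shape and determinism contracts", {
  cfg <- tiny_config()
  m <- cvae_model(cfg, rng_seed = 5)
  spec_l <- model_grid_spec(cfg, role = "ligand")
  spec_r <- model_grid_spec(cfg, role = "receptor")
  rec <- random_grid(spec_r, 1); lig <- random_grid(spec_l, 2)
  lat <- encode_input(rec, lig, m)
  expect_length(lat$mean, cfg$latent_dim)
  expect_true(all(lat$std > 0))
  lat2 <- encode_input(rec, lig, m)
  expect_identical(lat$mean, lat2$mean)

  cond <- encode_condition(rec, m)
  expect_length(cond$vector, cfg$latent_dim)
  expect_length(cond$skips, cfg$n_levels)
  expect_equal(nrow(cond$skips[[1]]), cfg$grid_points^3)
  zero_rec <- density_grid(array(0, dim(rec$values)), spec_r)
  expect_true(all(is.finite(encode_condition(zero_rec, m)$vector)))

  z <- rnorm(cfg$latent_dim)
  out <- decode(z, cond, m)
  expect_equal(dim(out$values),
               c(cfg$lig_channels, rep(cfg$grid_points, 3)))
  expect_true(all(out$values >= 0))
  expect_identical(decode(z, cond, m)$values, out$values)
  expect_error(decode(rnorm(3), cond, m), "length")
  bad <- density_grid(array(0, c(4, 8, 8, 8)),
                      grid_spec(side = 3.5, n_channels = 4L))
  expect_error(encode_input(bad, bad, cvae_model(tiny_config(grid_points = 16L),
                                                 rng_seed = 1)),
               "does not match")
})

test_that("the end-to-end loss gradient matches finite differences", {
  cfg <- model_config(grid_points = 4L, lig_channels = 2L, rec_channels = 2L,
                      latent_dim = 3L, n_levels = 1L, block_widths = 3L,
                      spectral_norm = TRUE)
  m <- cvae_model(cfg, rng_seed = 2)
  set.seed(3)
  rmat <- matrix(abs(rnorm(64 * 2)), 64, 2)
  lmat <- matrix(abs(rnorm(64 * 2)), 64, 2)
  rg <- gridmol:::mat_to_grid(rmat, model_grid_spec(cfg, role = "receptor"))
  w <- loss_weights()
  eps <- rnorm(3)
  st <- gridmol:::cvae_step(m, rmat, lmat, rg, w, 0L, eps)
  h <- 1e-5
  for (nm in names(m$params)) {
    for (k in sample(length(m$params[[nm]]$W), 2)) {
      m$params[[nm]]$W[k] <- m$params[[nm]]$W[k] + h
      lp <- gridmol:::cvae_step(m, rmat, lmat, rg, w, 0L, eps)$total
      m$params[[nm]]$W[k] <- m$params[[nm]]$W[k] - 2 * h
      lm_ <- gridmol:::cvae_step(m, rmat, lmat, rg, w, 0L, eps)$total
      m$params[[nm]]$W[k] <- m$params[[nm]]$W[k] + h
      num <- (lp - lm_) / (2 * h)
      ana <- gridmol:::sn_grad(st$grads[[nm]]$W, m$params[[nm]]$W, m$sn[[nm]])[k]
      expect_equal(ana, num, tolerance = 1e-3, label = paste("grad", nm))
    }
  }
})

test_that("training with zero learning rate leaves weights unchanged", {
  cxs <- list(make_fixture_complex(rng_seed = 1, shell_radius = 3.2,
                                   cavity_radius = 1.2, n_ligand_atoms = 2L,
                                   min_separation = 1.2,
                                   n_receptor_atoms = 6L))
  cfg <- tiny_config(rec_channels = 18L, lig_channels = 18L)
  m <- cvae_model(cfg, rng_seed = 1)
  before <- m$params$ie1$W
  tc <- train_config(learning_rate = 0, batch_size = 1L, rng_seed = 2)
  m <- train_cvae(cxs, m, tc, n_iterations = 3)
  expect_identical(m$params$ie1$W, before)
  expect_equal(nrow(attr(m, "history")), 3L)
})

test_that("checkpoints round-trip model state", {
  cfg <- tiny_config()
  m <- cvae_model(cfg, rng_seed = 7)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  spec_r <- model_grid_spec(cfg, role = "receptor")
  rec <- random_grid(spec_r, 1)
  expect_identical(encode_condition(rec, m)$vector,
                   encode_condition(rec, m2)$vector)
})

test_that("run configurations round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_run_config(path,
                   model = model_config(grid_points = 16L, latent_dim = 8L,
                                        n_levels = 2L,
                                        block_widths = c(4L, 8L)),
                   train = train_config(learning_rate = 1e-4, batch_size = 2L),
                   weights = loss_weights(lambda_steric = 0.5))
  cfg <- read_run_config(path)
  expect_equal(cfg$model$grid_points, 16L)
  expect_equal(cfg$model$block_widths, c(4L, 8L))
  expect_equal(cfg$train$learning_rate, 1e-4)
  expect_equal(cfg$weights$lambda_steric, 0.5)
  expect_s3_class(cfg$fit, "fit_config")
  writeLines("model:\n  grid_pionts: 8", path)
  expect_error(read_run_config(path), "unknown model config keys")
})
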