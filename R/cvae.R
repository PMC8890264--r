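# Conditional variational autoencoder over density grids --------------------
#
# Architecture: an input encoder maps the (receptor, ligand) grid pair to
# the mean and log-standard-deviation of a diagonal Gaussian posterior over
# the latent space; a conditional encoder maps the receptor grid to a
# conditional vector plus per-level skip feature maps; the decoder maps the
# concatenated (z, c) vector back to a nonnegative ligand grid, upsampling
# with nearest neighbors and concatenating the conditional encoder's skip
# features at matching resolutions (U-Net style). Convolutional blocks use
# leaky-ReLU activations with identity residuals where channel counts
# match, alternated with 2x average pooling; spectral normalization is
# applied to all weight matrices when enabled.

#' CVAE architecture configuration
#'
#' @param grid_points Grid points per axis; must be divisible by
#'   `2^n_levels` (default 48; tests use 12-16).
#' @param lig_channels,rec_channels Ligand/receptor channel counts
#'   (default 18 each).
#' @param latent_dim Latent dimensionality (default 128).
#' @param n_levels Pooling depth (default 3).
#' @param block_widths Feature maps per level; default doubles from 32.
#' @param use_skip_connections Concatenate conditional-encoder features
#'   into the decoder (default TRUE).
#' @param spectral_norm Spectrally normalize weight matrices (default TRUE).
#' @return A `model_config`.
#' @export
model_config <- function(grid_points = 48L, lig_channels = 18L,
                         rec_channels = 18L, latent_dim = 128L,
                         n_levels = 3L, block_widths = NULL,
                         use_skip_connections = TRUE, spectral_norm = TRUE) {
  if (is.null(block_widths)) block_widths <- 32L * 2L^(seq_len(n_levels) - 1L)
  stopifnot(length(block_widths) == n_levels, latent_dim >= 1)
  if (grid_points %% 2L^n_levels != 0L) {
    stop("grid_points must be divisible by 2^n_levels")
  }
  structure(list(grid_points = as.integer(grid_points),
                 lig_channels = as.integer(lig_channels),
                 rec_channels = as.integer(rec_channels),
                 latent_dim = as.integer(latent_dim),
                 n_levels = as.integer(n_levels),
                 block_widths = as.integer(block_widths),
                 use_skip_connections = isTRUE(use_skip_connections),
                 spectral_norm = isTRUE(spectral_norm)),
            class = "model_config")
}

#' Grid geometry matching a model configuration
#'
#' @param config A [model_config()].
#' @param center Grid center.
#' @param resolution Grid step (default 0.5 A).
#' @param role `"ligand"` or `"receptor"` (sets the channel count).
#' @return A [grid_spec()] with `points_per_axis == config$grid_points`.
#' @export
model_grid_spec <- function(config, center = c(0, 0, 0), resolution = 0.5,
                            role = c("ligand", "receptor")) {
  role <- match.arg(role)
  nch <- if (role == "ligand") config$lig_channels else config$rec_channels
  grid_spec(center = center, side = (config$grid_points - 1L) * resolution,
            resolution = resolution, n_channels = nch)
}

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

#' Initialize a CVAE model
#'
#' @param config A [model_config()].
#' @param rng_seed Seed for weight initialization.
#' @return A `cvae_model` environment holding parameters, spectral-norm
#'   state and optimizer state.
#' @export
cvae_model <- function(config = model_config(), rng_seed = 1L) {
  L <- config$n_levels; w <- config$block_widths
  P <- config$grid_points
  flat <- (P / 2L^L)^3 * w[L]
  params <- list()
  add <- function(name, nin, nout) {
    params[[name]] <<- list(W = glorot(nin, nout), b = numeric(nout))
  }
  with_seed(rng_seed, {
    cin <- config$rec_channels + config$lig_channels
    for (l in seq_len(L)) { add(paste0("ie", l), 27L * cin, w[l]); cin <- w[l] }
    add("iemu", flat, config$latent_dim)
    add("iels", flat, config$latent_dim)
    cin <- config$rec_channels
    for (l in seq_len(L)) { add(paste0("ce", l), 27L * cin, w[l]); cin <- w[l] }
    add("cefc", flat, config$latent_dim)
    add("defc", 2L * config$latent_dim, flat)
    ch <- w[L]
    for (l in rev(seq_len(L))) {
      cin <- ch + if (config$use_skip_connections) w[l] else 0L
      ch <- w[max(l - 1L, 1L)]
      add(paste0("de", l), 27L * cin, ch)
    }
    add("deout", 27L * ch, config$lig_channels)
    sn <- lapply(params, function(p) sn_init(p$W))
  })
  model <- new.env(parent = emptyenv())
  model$config <- config
  model$params <- params
  model$sn <- sn
  model$rms <- NULL
  model$iteration <- 0L
  class(model) <- "cvae_model"
  model
}

#' @export
print.cvae_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<cvae_model> %d^3 grid, latent %d, %d levels, %s parameters\n",
              x$config$grid_points, x$config$latent_dim, x$config$n_levels,
              format(np, big.mark = ",")))
  invisible(x)
}

getW <- function(model, name) {
  W <- model$params[[name]]$W
  if (model$config$spectral_norm) sn_normalize(W, model$sn[[name]]) else W
}

grid_to_mat <- function(grid) {
  nch <- grid$spec$n_channels
  t(matrix(grid$values, nch))
}

mat_to_grid <- function(mat, spec) {
  density_grid(array(t(mat), dim = c(spec$n_channels, rep(spec$points_per_axis, 3))),
               spec)
}

check_grid_shape <- function(grid, config, role) {
  nch <- if (role == "ligand") config$lig_channels else config$rec_channels
  if (grid$spec$n_channels != nch ||
      grid$spec$points_per_axis != config$grid_points) {
    stop(role, " grid shape (", grid$spec$n_channels, ", ",
         grid$spec$points_per_axis, "^3) does not match model config")
  }
}

# Encoder trunk shared by the input and conditional encoders.
trunk_fwd <- function(model, X, prefix) {
  cfg <- model$config
  P <- cfg$grid_points
  caches <- list()
  skips <- list()
  for (l in seq_len(cfg$n_levels)) {
    nm <- paste0(prefix, l)
    cv <- conv3_fwd(X, getW(model, nm), model$params[[nm]]$b, P)
    A <- lrelu_fwd(cv$Y)
    res <- ncol(A) == ncol(X)
    if (res) A <- A + X
    skips[[l]] <- A
    pt <- pool_idx(P)
    Xn <- pool_fwd(A, pt)
    caches[[l]] <- list(X = X, Y = cv$Y, res = res, P = P)
    X <- Xn
    P <- P %/% 2L
  }
  list(X = X, caches = caches, skips = skips)
}

trunk_bwd <- function(model, trunk, dX, dskips, prefix, grads) {
  cfg <- model$config
  for (l in rev(seq_len(cfg$n_levels))) {
    cc <- trunk$caches[[l]]
    pt <- pool_idx(cc$P)
    dA <- pool_bwd(dX, pt)
    if (!is.null(dskips) && !is.null(dskips[[l]])) dA <- dA + dskips[[l]]
    dXin_res <- if (cc$res) dA else 0
    dY <- lrelu_bwd(dA, cc$Y)
    nm <- paste0(prefix, l)
    bk <- conv3_bwd(dY, cc$X, getW(model, nm), cc$P)
    grads[[nm]] <- acc_grad(grads[[nm]], bk$dW, bk$db)
    dX <- bk$dX + dXin_res
  }
  list(dX = dX, grads = grads)
}

acc_grad <- function(g, dW, db) {
  if (is.null(g)) list(W = dW, b = db) else list(W = g$W + dW, b = g$b + db)
}

#' Latent distribution
#'
#' Per-dimension means and standard deviations of a diagonal Gaussian over
#' the latent space.
#'
#' @param mean,std Numeric vectors of equal length; `std` strictly positive.
#' @return A `latent_distribution`.
#' @export
latent_distribution <- function(mean, std) {
  if (length(mean) != length(std)) stop("mean and std lengths differ")
  if (any(std <= 0)) stop("latent std must be strictly positive")
  structure(list(mean = as.numeric(mean), std = as.numeric(std)),
            class = "latent_distribution")
}

#' Encode a complex into the approximate posterior
#'
#' The input encoder consumes the channel-concatenated receptor and ligand
#' grids and returns the mean and standard deviation of the approximate
#' posterior; the standard deviation is produced through an exponential map
#' of a log-std head, so it is strictly positive.
#'
#' @param rec,lig Receptor and ligand `density_grid`s on the same geometry.
#' @param model A `cvae_model`.
#' @return A [latent_distribution()].
#' @export
encode_input <- function(rec, lig, model) {
  check_grid_shape(rec, model$config, "receptor")
  check_grid_shape(lig, model$config, "ligand")
  X <- cbind(grid_to_mat(rec), grid_to_mat(lig))
  tr <- trunk_fwd(model, X, "ie")
  f <- matrix(as.numeric(tr$X), 1)
  mu <- drop(f %*% getW(model, "iemu") + model$params$iemu$b)
  ls <- drop(f %*% getW(model, "iels") + model$params$iels$b)
  latent_distribution(mu, exp(ls))
}

#' Encode the conditional receptor
#'
#' @param rec Receptor `density_grid`.
#' @param model A `cvae_model`.
#' @return A `conditional_code`: conditional vector plus one skip feature
#'   map per resolution level and the grid geometry for decoding.
#' @export
encode_condition <- function(rec, model) {
  check_grid_shape(rec, model$config, "receptor")
  tr <- trunk_fwd(model, grid_to_mat(rec), "ce")
  f <- matrix(as.numeric(tr$X), 1)
  cvec <- drop(f %*% getW(model, "cefc") + model$params$cefc$b)
  structure(list(vector = cvec, skips = tr$skips, spec = rec$spec),
            class = "conditional_code")
}

decode_fwd <- function(model, z, cond) {
  cfg <- model$config
  L <- cfg$n_levels; w <- cfg$block_widths; P <- cfg$grid_points
  zc <- matrix(c(z, cond$vector), 1)
  f <- drop(zc %*% getW(model, "defc") + model$params$defc$b)
  Q <- P %/% 2L^L
  X <- matrix(f, Q^3, w[L])
  caches <- list()
  for (l in rev(seq_len(L))) {
    Pf <- Q * 2L
    pt <- pool_idx(Pf)
    Xu <- up_fwd(X, pt)
    skip_ch <- 0L
    if (cfg$use_skip_connections) {
      Xu <- cbind(Xu, cond$skips[[l]])
      skip_ch <- ncol(cond$skips[[l]])
    }
    nm <- paste0("de", l)
    cv <- conv3_fwd(Xu, getW(model, nm), model$params[[nm]]$b, Pf)
    A <- lrelu_fwd(cv$Y)
    res <- ncol(A) == ncol(Xu)
    if (res) A <- A + Xu
    caches[[as.character(l)]] <- list(X = Xu, Y = cv$Y, P = Pf,
                                      cin = ncol(Xu), skip_ch = skip_ch,
                                      res = res)
    X <- A
    Q <- Pf
  }
  cv <- conv3_fwd(X, getW(model, "deout"), model$params$deout$b, P)
  out <- softplus_fwd(cv$Y)
  list(out = out, caches = caches, out_cache = list(X = X, Y = cv$Y), zc = zc)
}

decode_bwd <- function(model, dec, dout, grads) {
  cfg <- model$config
  L <- cfg$n_levels; P <- cfg$grid_points
  dY <- softplus_bwd(dout, dec$out_cache$Y)
  bk <- conv3_bwd(dY, dec$out_cache$X, getW(model, "deout"), P)
  grads$deout <- acc_grad(grads$deout, bk$dW, bk$db)
  dX <- bk$dX
  dskips <- vector("list", L)
  for (l in seq_len(L)) {
    cc <- dec$caches[[as.character(l)]]
    dA <- dX
    dXu_res <- if (cc$res) dA else 0
    dY <- lrelu_bwd(dA, cc$Y)
    nm <- paste0("de", l)
    bk <- conv3_bwd(dY, cc$X, getW(model, nm), cc$P)
    grads[[nm]] <- acc_grad(grads[[nm]], bk$dW, bk$db)
    dXu <- bk$dX + dXu_res
    if (cc$skip_ch > 0L) {
      main_ch <- cc$cin - cc$skip_ch
      dskips[[l]] <- dXu[, (main_ch + 1L):cc$cin, drop = FALSE]
      dXu <- dXu[, seq_len(main_ch), drop = FALSE]
    }
    pt <- pool_idx(cc$P)
    dX <- up_bwd(dXu, pt)
  }
  df <- matrix(as.numeric(dX), 1)
  dW <- crossprod(dec$zc, df)
  grads$defc <- acc_grad(grads$defc, dW, drop(df))
  dzc <- drop(df %*% t(getW(model, "defc")))
  latent <- cfg$latent_dim
  list(grads = grads, dz = dzc[seq_len(latent)],
       dc = dzc[(latent + 1L):(2L * latent)], dskips = dskips)
}

#' Decode a latent vector into a ligand density grid
#'
#' The latent vector and conditional vector are concatenated and mapped
#' through the decoder; the final softplus activation makes every output
#' voxel nonnegative.
#'
#' @param z Latent vector of length `latent_dim`.
#' @param cond A `conditional_code` from [encode_condition()].
#' @param model A `cvae_model`.
#' @return A `density_grid` with `lig_channels` channels.
#' @export
decode <- function(z, cond, model) {
  if (length(z) != model$config$latent_dim) stop("latent vector length mismatch")
  dec <- decode_fwd(model, z, cond)
  spec <- cond$spec
  lig_spec <- grid_spec(center = spec$center, side = spec$side,
                        resolution = spec$resolution,
                        n_channels = model$config$lig_channels,
                        atomic_radius = spec$atomic_radius,
                        cutoff_mult = spec$cutoff_mult)
  mat_to_grid(dec$out, lig_spec)
}

# Losses ---------------------------------------------------------------------

#' Kullback-Leibler divergence to the standard-normal prior
#'
#' Closed form for a diagonal Gaussian:
#' `sum over dims of (mu^2 + sigma^2 - 2 log sigma - 1) / 2`; zero exactly
#' when the distribution is the standard normal.
#'
#' @param latent A [latent_distribution()].
#' @return Scalar divergence (`>= 0`).
#' @export
kl_divergence <- function(latent) {
  if (any(latent$std <= 0)) stop("latent std must be positive")
  sum(0.5 * (latent$mean^2 + latent$std^2 - 2 * log(latent$std) - 1))
}

#' Reconstruction loss between generated and reference ligand grids
#'
#' Summed squared error over all voxels and channels (Gaussian likelihood
#' up to constants); `form = "mean"` switches to the per-voxel mean.
#'
#' @param lig_gen,lig `density_grid`s (or plain arrays) of equal shape.
#' @param form `"sum"` (default) or `"mean"`.
#' @return Scalar loss, zero iff the grids are equal.
#' @export
reconstruction_loss <- function(lig_gen, lig, form = c("sum", "mean")) {
  form <- match.arg(form)
  a <- if (inherits(lig_gen, "density_grid")) lig_gen$values else lig_gen
  b <- if (inherits(lig, "density_grid")) lig$values else lig
  if (!all(dim(a) == dim(b))) stop("grid shapes differ")
  s <- sum((a - b)^2)
  if (form == "mean") s / length(a) else s
}

#' Loss weights and KL ramp schedule
#'
#' @param lambda_recon Reconstruction weight (default 4.0).
#' @param lambda_kl_init Initial KL weight (default 0.1).
#' @param lambda_kl_final Final KL weight (default 1.6).
#' @param ramp_start_iter Iteration at which the KL ramp starts
#'   (default 450000).
#' @param ramp_length Ramp duration in iterations (default 200000).
#' @param lambda_steric Steric clash weight (default 1.0).
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(lambda_recon = 4.0, lambda_kl_init = 0.1,
                         lambda_kl_final = 1.6, ramp_start_iter = 450000L,
                         ramp_length = 200000L, lambda_steric = 1.0) {
  stopifnot(lambda_recon >= 0, lambda_kl_init >= 0, lambda_kl_final >= 0,
            lambda_steric >= 0, ramp_length > 0)
  structure(list(lambda_recon = lambda_recon, lambda_kl_init = lambda_kl_init,
                 lambda_kl_final = lambda_kl_final,
                 ramp_start_iter = ramp_start_iter, ramp_length = ramp_length,
                 lambda_steric = lambda_steric),
            class = "loss_weights")
}

#' KL weight at a training iteration
#'
#' Constant at the initial value before the ramp start, linear up to the
#' final value over the ramp length, constant after.
#'
#' @param iteration Training iteration (`>= 0`).
#' @param weights A [loss_weights()].
#' @return The KL weight.
#' @export
lambda_kl <- function(iteration, weights = loss_weights()) {
  if (any(iteration < 0)) stop("iteration must be nonnegative")
  frac <- pmin(pmax((iteration - weights$ramp_start_iter) / weights$ramp_length, 0), 1)
  weights$lambda_kl_init + frac * (weights$lambda_kl_final - weights$lambda_kl_init)
}

#' Assemble the training loss
#'
#' Weighted sum `lambda_recon * L_recon + lambda_KL(iter) * L_KL +
#' lambda_steric * L_steric`, with the steric term the channel-summed
#' density product of the receptor and generated ligand grids.
#'
#' @param lig,lig_gen Reference and generated ligand `density_grid`s.
#' @param rec Receptor `density_grid`.
#' @param latent A [latent_distribution()].
#' @param weights A [loss_weights()].
#' @param iteration Training iteration (drives the KL ramp).
#' @return List with `total` and the per-term breakdown.
#' @export
total_loss <- function(lig, lig_gen, rec, latent, weights = loss_weights(),
                       iteration = 0L) {
  lkl <- lambda_kl(iteration, weights)
  terms <- list(recon = reconstruction_loss(lig_gen, lig),
                kl = kl_divergence(latent),
                steric = steric_overlap(rec, lig_gen))
  list(total = weights$lambda_recon * terms$recon + lkl * terms$kl +
         weights$lambda_steric * terms$steric,
       terms = terms, lambda_kl = lkl)
}

# Training --------------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate RMSprop learning rate (default 1e-5).
#' @param batch_size Complexes per iteration (default 8).
#' @param max_iterations Iteration budget (default 1e6).
#' @param rng_seed Seed controlling sampling, augmentation and latent noise.
#' @param augment Apply random rotation + translation each iteration
#'   (default TRUE).
#' @param max_translation Augmentation translation bound in angstroms
#'   (default 2).
#' @param resolution Grid resolution in angstroms (default 0.5).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 8L,
                         max_iterations = 1e6, rng_seed = 1L, augment = TRUE,
                         max_translation = 2.0, resolution = 0.5) {
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 rng_seed = as.integer(rng_seed), augment = isTRUE(augment),
                 max_translation = max_translation, resolution = resolution),
            class = "train_config")
}

rmsprop_update <- function(model, grads, lr, decay = 0.9, eps = 1e-8) {
  if (is.null(model$rms)) {
    model$rms <- lapply(model$params, function(p) {
      list(W = array(0, dim(p$W)), b = numeric(length(p$b)))
    })
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    dW <- g$W
    if (model$config$spectral_norm) {
      dW <- sn_grad(dW, model$params[[nm]]$W, model$sn[[nm]])
    }
    model$rms[[nm]]$W <- decay * model$rms[[nm]]$W + (1 - decay) * dW^2
    model$rms[[nm]]$b <- decay * model$rms[[nm]]$b + (1 - decay) * g$b^2
    model$params[[nm]]$W <- model$params[[nm]]$W -
      lr * dW / (sqrt(model$rms[[nm]]$W) + eps)
    model$params[[nm]]$b <- model$params[[nm]]$b -
      lr * g$b / (sqrt(model$rms[[nm]]$b) + eps)
  }
  invisible(model)
}

# Full forward + backward for one complex; returns loss terms and gradient
# contributions.
cvae_step <- function(model, rmat, lmat, rec_grid, weights, iteration, eps) {
  cfg <- model$config
  # input encoder
  X <- cbind(rmat, lmat)
  ie <- trunk_fwd(model, X, "ie")
  f <- matrix(as.numeric(ie$X), 1)
  mu <- drop(f %*% getW(model, "iemu") + model$params$iemu$b)
  ls <- drop(f %*% getW(model, "iels") + model$params$iels$b)
  sd <- exp(ls)
  z <- mu + sd * eps
  # conditional encoder
  ce <- trunk_fwd(model, rmat, "ce")
  fc <- matrix(as.numeric(ce$X), 1)
  cvec <- drop(fc %*% getW(model, "cefc") + model$params$cefc$b)
  cond <- list(vector = cvec, skips = ce$skips, spec = rec_grid$spec)
  dec <- decode_fwd(model, z, cond)
  out <- dec$out

  recon <- sum((out - lmat)^2)
  kl <- sum(0.5 * (mu^2 + sd^2 - 2 * ls - 1))
  recsum <- rowSums(rmat)
  outsum <- rowSums(out)
  steric <- sum(recsum * outsum)
  lkl <- lambda_kl(iteration, weights)
  total <- weights$lambda_recon * recon + lkl * kl + weights$lambda_steric * steric
  if (!is.finite(total)) {
    stop(sprintf("non-finite training loss at iteration %d (recon %.3g, kl %.3g, steric %.3g)",
                 iteration, recon, kl, steric))
  }

  # backward
  grads <- list()
  dout <- weights$lambda_recon * 2 * (out - lmat) +
    weights$lambda_steric * matrix(recsum, nrow(out), ncol(out))
  db <- decode_bwd(model, dec, dout, grads)
  grads <- db$grads
  # latent heads: z = mu + sd * eps, kl term
  dmu <- db$dz + lkl * mu
  dls <- db$dz * sd * eps + lkl * (sd^2 - 1)
  grads$iemu <- acc_grad(grads$iemu, crossprod(f, matrix(dmu, 1)), dmu)
  grads$iels <- acc_grad(grads$iels, crossprod(f, matrix(dls, 1)), dls)
  dfin <- dmu %*% t(getW(model, "iemu")) + dls %*% t(getW(model, "iels"))
  dXie <- matrix(as.numeric(dfin), nrow(ie$X), ncol(ie$X))
  tb <- trunk_bwd(model, ie, dXie, NULL, "ie", grads)
  grads <- tb$grads
  # conditional encoder: fc head + skip gradients from decoder
  dcvec <- db$dc
  grads$cefc <- acc_grad(grads$cefc, crossprod(fc, matrix(dcvec, 1)), dcvec)
  dfc <- dcvec %*% t(getW(model, "cefc"))
  dXce <- matrix(as.numeric(dfc), nrow(ce$X), ncol(ce$X))
  dskips <- if (cfg$use_skip_connections) db$dskips else NULL
  tb <- trunk_bwd(model, ce, dXce, dskips, "ce", grads)
  grads <- tb$grads

  list(grads = grads, recon = recon, kl = kl, steric = steric, total = total)
}

#' Train the CVAE on receptor-ligand complexes
#'
#' Each iteration grids a batch of complexes with fresh pose augmentation,
#' encodes them, draws reparameterized latent samples, decodes conditioned
#' on the receptor, assembles the weighted loss and takes an RMSprop step.
#' Training aborts with diagnostics if the loss turns non-finite.
#'
#' @param complexes List of `list(receptor=, ligand=)` `typed_struct` pairs.
#' @param model A `cvae_model` (updated in place and returned).
#' @param config A [train_config()].
#' @param weights A [loss_weights()].
#' @param n_iterations Number of iterations to run (capped by
#'   `config$max_iterations`).
#' @param verbose Print progress every 100 iterations.
#' @return The model, with attribute `"history"`: data.frame of per-term
#'   losses and the KL weight per iteration.
#' @export
train_cvae <- function(complexes, model, config = train_config(),
                       weights = loss_weights(),
                       n_iterations = config$max_iterations, verbose = FALSE) {
  stopifnot(length(complexes) >= 1)
  n_iter <- min(n_iterations, config$max_iterations)
  cfg <- model$config
  hist <- data.frame(iteration = integer(0), recon = numeric(0),
                     kl = numeric(0), steric = numeric(0), total = numeric(0),
                     lambda_kl = numeric(0))
  with_seed(config$rng_seed, {
    for (it in seq_len(n_iter)) {
      idx <- sample.int(length(complexes), config$batch_size, replace = TRUE)
      sums <- c(recon = 0, kl = 0, steric = 0, total = 0)
      grads_acc <- list()
      for (b in idx) {
        cx <- complexes[[b]]
        center <- colMeans(cx$ligand$coords)
        spec_l <- model_grid_spec(cfg, center, config$resolution, "ligand")
        spec_r <- model_grid_spec(cfg, center, config$resolution, "receptor")
        tf <- if (config$augment) random_transform(config$max_translation) else NULL
        lig <- molecule_to_grid(cx$ligand, spec_l, tf)
        rec <- molecule_to_grid(cx$receptor, spec_r, tf)
        eps <- stats::rnorm(cfg$latent_dim)
        st <- cvae_step(model, grid_to_mat(rec), grid_to_mat(lig), rec,
                        weights, model$iteration, eps)
        for (nm in names(st$grads)) {
          grads_acc[[nm]] <- acc_grad(grads_acc[[nm]], st$grads[[nm]]$W,
                                      st$grads[[nm]]$b)
        }
        sums <- sums + c(st$recon, st$kl, st$steric, st$total)
      }
      nb <- length(idx)
      for (nm in names(grads_acc)) {
        grads_acc[[nm]]$W <- grads_acc[[nm]]$W / nb
        grads_acc[[nm]]$b <- grads_acc[[nm]]$b / nb
      }
      rmsprop_update(model, grads_acc, config$learning_rate)
      if (cfg$spectral_norm) {
        for (nm in names(model$params)) {
          model$sn[[nm]] <- sn_power_iterate(model$params[[nm]]$W, model$sn[[nm]])
        }
      }
      model$iteration <- model$iteration + 1L
      hist <- rbind(hist, data.frame(iteration = model$iteration,
                                     recon = sums[1] / nb, kl = sums[2] / nb,
                                     steric = sums[3] / nb, total = sums[4] / nb,
                                     lambda_kl = lambda_kl(model$iteration, weights)))
      if (verbose && it %% 100L == 0L) {
        message(sprintf("iter %d: recon %.2f kl %.2f steric %.3f",
                        model$iteration, sums[1] / nb, sums[2] / nb, sums[3] / nb))
      }
    }
  })
  attr(model, "history") <- hist
  model
}

#' Save / load a model checkpoint
#'
#' One archive holding the weights, spectral-norm state, configuration and
#' iteration counter.
#'
#' @param model A `cvae_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params, sn = model$sn,
               iteration = model$iteration), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- cvae_model(ck$config, rng_seed = 0L)
  model$params <- ck$params
  model$sn <- ck$sn
  model$iteration <- ck$iteration
  model
}

#' Write a training history to CSV
#'
#' @param model Trained model carrying a `"history"` attribute.
#' @param path Output CSV path.
#' @export
write_train_log <- function(model, path) {
  hist <- attr(model, "history")
  if (is.null(hist)) stop("model carries no training history")
  utils::write.csv(hist, path, row.names = FALSE)
  invisible(path)
}
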