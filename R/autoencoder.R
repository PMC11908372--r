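# Stage 1: a deformation-field autoencoder trained jointly with a learned
# template. The encoder sees the image and the template concatenated along
# the channel axis; its latent is decoded into a dense displacement field
# that warps the template; a registration loss (L1 similarity + displacement
# regularizer + slight KL + patch-adversarial term) trains everything.

#' Stage-1 configuration
#'
#' Defaults follow the reference setting: similarity is L1, the displacement
#' regularizer weights are alpha = 5 and beta = 1, the KL penalty weight is
#' 1e-7, and the patch-adversarial weight is 0.005. The latent grid sits at
#' 1/8 spatial resolution (3 stride-2 levels) with 8 channels. Channel
#' widths default to a desk-scale preset suitable for 32^3 grids; the
#' level count, not the widths, is the structural commitment.
#'
#' @param alpha displacement magnitude weight
#' @param beta displacement gradient weight
#' @param kl_weight weight of the KL penalty towards N(0, 1)
#' @param adversarial_weight weight of the patch-adversarial generator term
#' @param similarity similarity loss; only \code{"l1"} is implemented
#' @param conditional if TRUE, the template decoder takes the normalized
#'   condition vector as input and the condition is appended to the latent
#'   as constant channels (the conditional-autoencoder variant)
#' @param latent_channels latent channels (default 8)
#' @param enc_widths encoder channels at the three stride-2 levels
#' @param dec_widths decoder channels: c(base, level1, level2); the field
#'   and template heads are predicted at half resolution and trilinearly
#'   upsampled, a standard efficiency choice in learning-based registration
#' @param disc_widths discriminator channels at its two stride-2 levels
#' @param template_input_dim learnable input dimension of the unconditional
#'   template decoder
#' @param lr Adam learning rate
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param balanced use the decade-balanced age sampler during training
#' @param padding out-of-bounds rule for the warp
#' @param latent_export \code{"sample"} (reparameterized draw, default) or
#'   \code{"mean"}: which latent the diffusion stage is trained on
#' @param seed training seed
#' @return an object of class \code{stage1_config}
#' @export
stage1_config <- function(alpha = 5, beta = 1, kl_weight = 1e-7,
                          adversarial_weight = 0.005, similarity = "l1",
                          conditional = FALSE, latent_channels = 8L,
                          enc_widths = c(8L, 16L, 16L),
                          dec_widths = c(16L, 12L, 12L),
                          disc_widths = c(8L, 16L),
                          template_input_dim = 8L, lr = 1e-3, epochs = 30L,
                          batch_size = 8L, balanced = TRUE,
                          padding = c("border", "zeros"),
                          latent_export = c("sample", "mean"), seed = 0L) {
  stopifnot(alpha >= 0, beta >= 0, kl_weight >= 0, adversarial_weight >= 0,
            identical(similarity, "l1"), latent_channels >= 1,
            length(enc_widths) == 3, length(dec_widths) == 3)
  structure(list(alpha = alpha, beta = beta, kl_weight = kl_weight,
                 adversarial_weight = adversarial_weight,
                 similarity = similarity, conditional = isTRUE(conditional),
                 latent_channels = as.integer(latent_channels),
                 enc_widths = as.integer(enc_widths),
                 dec_widths = as.integer(dec_widths),
                 disc_widths = as.integer(disc_widths),
                 template_input_dim = as.integer(template_input_dim),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 balanced = isTRUE(balanced), padding = match.arg(padding),
                 latent_export = match.arg(latent_export),
                 seed = as.integer(seed)),
            class = "stage1_config")
}

#' Latent grid shape implied by an input grid
#'
#' Three stride-2 levels halve each axis three times.
#'
#' @param grid_shape input grid
#' @param latent_channels latent channel count
#' @return integer c(channels, D/8, H/8, W/8)
#' @export
latent_shape <- function(grid_shape, latent_channels = 8L) {
  as.integer(c(latent_channels, ceiling(grid_shape / 8)))
}

#' Initialize stage-1 states
#'
#' Builds the encoder, deformation decoder, template decoder and patch
#' discriminator. The template is a learnable full-resolution base image
#' plus an additive conv-decoded modulation of the input vector; the final
#' layers of both field and template conv heads are zero-initialized, so
#' training starts exactly at the identity deformation applied to a flat
#' mid-gray (0.5) template.
#'
#' @param grid_shape length-3 grid, each axis divisible by 8
#' @param config a \code{stage1_config}
#' @return an autoencoder state list (parameters plus bookkeeping)
#' @export
init_autoencoder <- function(grid_shape, config = stage1_config()) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape %% 8 != 0))
    stop("grid_shape must be divisible by 8 (three stride-2 levels)")
  w <- config$enc_widths; dw <- config$dec_widths; zc <- config$latent_channels
  base <- grid_shape %/% 8L
  zin <- zc + if (config$conditional) 2L else 0L
  tin <- if (config$conditional) 2L else config$template_input_dim
  with_seed(config$seed, {
    params <- list(
      enc = list(c1 = p_conv(2, w[1]), c2 = p_conv(w[1], w[2]),
                 c3 = p_conv(w[2], w[3]), mu = p_conv(w[3], zc),
                 lv = p_conv(w[3], zc, init = "zero")),
      dec = list(d1 = p_conv(zin, dw[1]), up = p_updec(dw, 3L, "zero")),
      tmpl = list(fc = p_dense(tin, dw[1] * prod(base)),
                  up = p_updec(dw, 1L, "zero"),
                  base = array(0.5, dim = grid_shape)),
      disc = list(c1 = p_conv(1, config$disc_widths[1]),
                  c2 = p_conv(config$disc_widths[1], config$disc_widths[2]),
                  c3 = p_conv(config$disc_widths[2], 1)),
      tmpl_input = if (config$conditional) NULL else rnorm(tin) * 0.1
    )
    list(params = params, config = config, grid_shape = grid_shape,
         base_shape = base)
  })
}

p_updec <- function(dw, cout, head_init) {
  list(d2 = p_conv(dw[1], dw[2]), d3 = p_conv(dw[2], dw[3]),
       out = p_conv(dw[3], cout, init = head_init),
       ref = p_conv(cout, cout))
}

# ---- shared upsampling decoder trunk ----------------------------------

# two nearest-upsample + conv levels to half resolution, the head conv, a
# trilinear x2 upsample, then a cheap full-resolution refinement conv that
# restores thin structures the upsampling blurs
updec_f <- function(p, x) {
  u1 <- .upsample2_fwd(x)
  a2 <- conv_f(p$d2, u1); r2 <- act_f(a2, "relu"); dim(r2) <- dim(a2)
  u2 <- .upsample2_fwd(r2)
  a3 <- conv_f(p$d3, u2); r3 <- act_f(a3, "relu"); dim(r3) <- dim(a3)
  half <- conv_f(p$out, r3)
  up <- .upsample2lin_fwd(half)
  out <- conv_f(p$ref, up)
  list(out = out, cache = list(u1 = u1, a2 = a2, u2 = u2, a3 = a3, r3 = r3,
                               up = up))
}

updec_b <- function(p, cache, gout) {
  b5 <- conv_b(p$ref, cache$up, gout)
  g <- .upsample2lin_bwd(b5$gx)
  b4 <- conv_b(p$out, cache$r3, g)
  g <- act_b(b4$gx, cache$a3, NULL, "relu"); dim(g) <- dim(cache$a3)
  b3 <- conv_b(p$d3, cache$u2, g)
  g <- .upsample2_bwd(b3$gx)
  g <- act_b(g, cache$a2, NULL, "relu"); dim(g) <- dim(cache$a2)
  b2 <- conv_b(p$d2, cache$u1, g)
  gx <- .upsample2_bwd(b2$gx)
  list(gx = gx,
       grads = list(d2 = list(w = b2$gw, b = b2$gb),
                    d3 = list(w = b3$gw, b = b3$gb),
                    out = list(w = b4$gw, b = b4$gb),
                    ref = list(w = b5$gw, b = b5$gb)))
}

# ---- encoder -----------------------------------------------------------

enc_f <- function(p, x0) {
  a1 <- conv_f(p$c1, x0, stride = 2); r1 <- act_f(a1, "relu"); dim(r1) <- dim(a1)
  a2 <- conv_f(p$c2, r1, stride = 2); r2 <- act_f(a2, "relu"); dim(r2) <- dim(a2)
  a3 <- conv_f(p$c3, r2, stride = 2); r3 <- act_f(a3, "relu"); dim(r3) <- dim(a3)
  mu <- conv_f(p$mu, r3)
  lv_raw <- conv_f(p$lv, r3)
  lv <- pmin(pmax(lv_raw, -10), 10); dim(lv) <- dim(lv_raw)
  list(mu = mu, lv = lv,
       cache = list(x0 = x0, a1 = a1, r1 = r1, a2 = a2, r2 = r2, a3 = a3,
                    r3 = r3, lv_raw = lv_raw))
}

enc_b <- function(p, cache, gmu, glv) {
  glv <- glv * (abs(cache$lv_raw) < 10); dim(glv) <- dim(cache$lv_raw)
  bm <- conv_b(p$mu, cache$r3, gmu)
  bl <- conv_b(p$lv, cache$r3, glv)
  g <- bm$gx + bl$gx; dim(g) <- dim(cache$a3)
  g <- act_b(g, cache$a3, NULL, "relu"); dim(g) <- dim(cache$a3)
  b3 <- conv_b(p$c3, cache$r2, g, stride = 2)
  g <- act_b(b3$gx, cache$a2, NULL, "relu"); dim(g) <- dim(cache$a2)
  b2 <- conv_b(p$c2, cache$r1, g, stride = 2)
  g <- act_b(b2$gx, cache$a1, NULL, "relu"); dim(g) <- dim(cache$a1)
  b1 <- conv_b(p$c1, cache$x0, g, stride = 2)
  list(gx0 = b1$gx,
       grads = list(c1 = list(w = b1$gw, b = b1$gb),
                    c2 = list(w = b2$gw, b = b2$gb),
                    c3 = list(w = b3$gw, b = b3$gb),
                    mu = list(w = bm$gw, b = bm$gb),
                    lv = list(w = bl$gw, b = bl$gb)))
}

# ---- deformation decoder ----------------------------------------------

dec_f <- function(p, zin) {
  a1 <- conv_f(p$d1, zin); r1 <- act_f(a1, "relu"); dim(r1) <- dim(a1)
  up <- updec_f(p$up, r1)
  list(out = up$out, cache = list(zin = zin, a1 = a1, r1 = r1, up = up$cache))
}

dec_b <- function(p, cache, gout) {
  ub <- updec_b(p$up, cache$up, gout)
  g <- act_b(ub$gx, cache$a1, NULL, "relu"); dim(g) <- dim(cache$a1)
  b1 <- conv_b(p$d1, cache$zin, g)
  list(gzin = b1$gx,
       grads = list(d1 = list(w = b1$gw, b = b1$gb), up = ub$grads))
}

# ---- template decoder --------------------------------------------------

# the template is a learnable full-resolution base image plus an additive
# modulation decoded from the input vector (learnable-atlas construction);
# output is linear in intensity space
tmpl_f <- function(p, vec, base_shape, base_channels) {
  h0 <- dense_f(p$fc, vec)
  hr <- act_f(h0, "relu")
  hx <- array(hr, dim = c(base_channels, base_shape))
  up <- updec_f(p$up, hx)
  y <- up$out + array(p$base, dim = dim(up$out))
  list(out = y, cache = list(vec = vec, h0 = h0, up = up$cache))
}

tmpl_b <- function(p, cache, gout) {
  ub <- updec_b(p$up, cache$up, gout)
  gh <- act_b(as.numeric(ub$gx), cache$h0, NULL, "relu")
  bf <- dense_b(p$fc, cache$vec, gh)
  gbase <- gout; dim(gbase) <- dim(p$base)
  list(gvec = bf$gx,
       grads = list(fc = list(w = bf$gw, b = bf$gb), up = ub$grads,
                    base = gbase))
}

# ---- patch discriminator ----------------------------------------------

disc_f <- function(p, x) {
  x0 <- array(x, dim = c(1, dim(x)))
  a1 <- conv_f(p$c1, x0, stride = 2); r1 <- act_f(a1, "lrelu"); dim(r1) <- dim(a1)
  a2 <- conv_f(p$c2, r1, stride = 2); r2 <- act_f(a2, "lrelu"); dim(r2) <- dim(a2)
  logits <- conv_f(p$c3, r2)
  list(logits = logits,
       cache = list(x0 = x0, a1 = a1, r1 = r1, a2 = a2, r2 = r2))
}

# critic backward returning parameter gradients only (no input gradient)
disc_param_grads <- function(p, cache, glogits) {
  b3 <- conv_b(p$c3, cache$r2, glogits, want_gx = TRUE)
  g <- act_b(b3$gx, cache$a2, NULL, "lrelu"); dim(g) <- dim(cache$a2)
  b2 <- conv_b(p$c2, cache$r1, g, stride = 2, want_gx = TRUE)
  g <- act_b(b2$gx, cache$a1, NULL, "lrelu"); dim(g) <- dim(cache$a1)
  b1 <- conv_b(p$c1, cache$x0, g, stride = 2, want_gx = FALSE)
  list(c1 = list(w = b1$gw, b = b1$gb),
       c2 = list(w = b2$gw, b = b2$gb),
       c3 = list(w = b3$gw, b = b3$gb))
}

disc_b <- function(p, cache, glogits) {
  b3 <- conv_b(p$c3, cache$r2, glogits)
  g <- act_b(b3$gx, cache$a2, NULL, "lrelu"); dim(g) <- dim(cache$a2)
  b2 <- conv_b(p$c2, cache$r1, g, stride = 2)
  g <- act_b(b2$gx, cache$a1, NULL, "lrelu"); dim(g) <- dim(cache$a1)
  b1 <- conv_b(p$c1, cache$x0, g, stride = 2)
  gx <- b1$gx; dim(gx) <- dim(cache$x0)[-1]
  list(gx = gx,
       grads = list(c1 = list(w = b1$gw, b = b1$gb),
                    c2 = list(w = b2$gw, b = b2$gb),
                    c3 = list(w = b3$gw, b = b3$gb)))
}

# ---- public operations -------------------------------------------------

state_of <- function(x) if (inherits(x, "morph_autoencoder")) x$state else x

#' Evaluate the template decoder
#'
#' Deterministic: the unconditional decoder is a fixed function of its
#' learnable input vector; the conditional decoder maps the normalized
#' condition (age/100, sex) to a condition-specific template.
#'
#' @param model a trained \code{morph_autoencoder} or a raw state from
#'   \code{\link{init_autoencoder}}
#' @param cond a \code{condition}, required in conditional mode
#' @return a \code{volume}
#' @export
template_forward <- function(model, cond = NULL) {
  st <- state_of(model)
  cfg <- st$config
  if (cfg$conditional && is.null(cond))
    stop("conditional template decoder requires a condition")
  if (!cfg$conditional && !is.null(cond))
    warning("condition ignored: template decoder is unconditional")
  vec <- if (cfg$conditional) normalize_condition(cond) else st$params$tmpl_input
  tf <- tmpl_f(st$params$tmpl, vec, st$base_shape, cfg$dec_widths[1])
  out <- tf$out; dim(out) <- dim(out)[-1]
  volume(out)
}

#' Encode an image against the template
#'
#' Returns the variational latent: per-element mean and log-variance on a
#' grid at 1/8 resolution with \code{latent_channels} channels, plus a
#' reparameterized sample \code{mean + exp(log_variance / 2) * eps}.
#'
#' @param model autoencoder model or state
#' @param image a \code{volume} (or 3D array)
#' @param template a \code{volume}; computed from the model if NULL
#' @param cond condition (used only to build the template in conditional
#'   mode)
#' @param eps optional noise array (for reproducibility); drawn from the
#'   current RNG stream if NULL
#' @return an object of class \code{latent_code} with fields \code{mean},
#'   \code{log_variance}, \code{sample}, \code{eps}
#' @export
encode <- function(model, image, template = NULL, cond = NULL, eps = NULL) {
  st <- state_of(model)
  image <- as_volume(image)
  if (is.null(template))
    template <- template_forward(st, if (st$config$conditional) cond else NULL)
  template <- as_volume(template)
  if (!identical(dim(image$intensities), dim(template$intensities)))
    stop("image and template grids differ")
  x0 <- array(0, dim = c(2, dim(image$intensities)))
  x0[1, , , ] <- image$intensities
  x0[2, , , ] <- template$intensities
  ef <- enc_f(st$params$enc, x0)
  if (is.null(eps)) eps <- array(rnorm(length(ef$mu)), dim = dim(ef$mu))
  smp <- ef$mu + exp(ef$lv / 2) * eps
  dim(smp) <- dim(ef$mu)
  structure(list(mean = ef$mu, log_variance = ef$lv, sample = smp, eps = eps),
            class = "latent_code")
}

#' Decode a latent into a displacement field
#'
#' In the conditional variant the normalized condition is appended to the
#' latent as channels constant across the spatial grid before decoding.
#'
#' @param model autoencoder model or state
#' @param latent a \code{latent_code} (its sample is used) or a plain latent
#'   array of shape \code{latent_shape(grid_shape)}
#' @param cond condition, required in conditional mode
#' @return a \code{displacement_field} at full resolution
#' @export
decode_deformation <- function(model, latent, cond = NULL) {
  st <- state_of(model)
  z <- if (inherits(latent, "latent_code")) latent$sample else latent
  zc <- st$config$latent_channels
  if (dim(z)[1] != zc)
    stop(sprintf("latent has %d channels, decoder expects %d", dim(z)[1], zc))
  zin <- append_condition_channels(st, z, cond)
  df <- dec_f(st$params$dec, zin)
  displacement_field(df$out)
}

append_condition_channels <- function(st, z, cond) {
  if (!st$config$conditional) return(z)
  if (is.null(cond)) stop("conditional decoder requires a condition")
  cn <- normalize_condition(cond)
  zin <- array(0, dim = dim(z) + c(2L, 0L, 0L, 0L))
  zin[seq_len(dim(z)[1]), , , ] <- z
  zin[dim(z)[1] + 1L, , , ] <- cn[1]
  zin[dim(z)[1] + 2L, , , ] <- cn[2]
  zin
}

#' Reconstruct an image as a deformed template
#'
#' Runs the full stage-1 composite: template, encode, decode, warp.
#'
#' @param model autoencoder model or state
#' @param image a \code{volume}
#' @param cond condition (conditional mode)
#' @param eps optional latent noise array
#' @return list with \code{deformed_template}, \code{field}, \code{latent},
#'   \code{template}
#' @export
reconstruct <- function(model, image, cond = NULL, eps = NULL) {
  st <- state_of(model)
  template <- template_forward(st, if (st$config$conditional) cond else NULL)
  latent <- encode(st, image, template, cond, eps)
  field <- decode_deformation(st, latent, cond)
  deformed <- warp(template, field, "trilinear", st$config$padding)
  list(deformed_template = deformed, field = field, latent = latent,
       template = template)
}

#' KL penalty of a latent towards the standard normal
#'
#' Mean over latent elements of \eqn{\frac12(\mu^2 + \sigma^2 - 1 -
#' \log\sigma^2)}; a slight pressure that prevents arbitrarily
#' high-variance latent spaces.
#'
#' @param latent a \code{latent_code}
#' @return nonnegative scalar
#' @export
kl_penalty <- function(latent) {
  mean(0.5 * (latent$mean^2 + exp(latent$log_variance) - 1 -
              latent$log_variance))
}

#' Patch-adversarial loss terms
#'
#' Least-squares GAN objective over the patch logits of a small strided 3D
#' convolutional critic: the discriminator term is
#' \eqn{\frac12 E(D(real)-1)^2 + \frac12 E D(fake)^2} and the generator
#' term \eqn{\frac12 E(D(fake)-1)^2}. The two terms carry separate
#' optimization contracts (the generator term backpropagates into the fake
#' image, the discriminator term into the critic only).
#'
#' @param model autoencoder model or state (its critic is used)
#' @param real real \code{volume} or array
#' @param fake generated \code{volume} or array
#' @return list with \code{generator_term} and \code{discriminator_term}
#' @export
patch_adversarial_loss <- function(model, real, fake) {
  st <- state_of(model)
  r <- if (inherits(real, "volume")) real$intensities else real
  f <- if (inherits(fake, "volume")) fake$intensities else fake
  if (!identical(dim(r), dim(f))) stop("real/fake shapes differ")
  dr <- disc_f(st$params$disc, r)$logits
  df <- disc_f(st$params$disc, f)$logits
  list(generator_term = 0.5 * mean((df - 1)^2),
       discriminator_term = 0.5 * mean((dr - 1)^2) + 0.5 * mean(df^2))
}

#' Stage-1 registration loss with component breakdown
#'
#' \code{total = L1(deformed_template, image) + alpha*magnitude +
#' beta*gradient + kl_weight*KL + adversarial_weight*generator_term},
#' with the regularizer evaluated on the grid-sampler-normalized field
#' (the scale the default alpha and beta are calibrated for).
#'
#' @param image target \code{volume}
#' @param recon output of \code{\link{reconstruct}}
#' @param config a \code{stage1_config}
#' @param model optional model/state providing the critic; the adversarial
#'   term is 0 when absent or when \code{adversarial_weight} is 0
#' @return list with \code{total} and the individual components
#' @export
registration_loss <- function(image, recon, config, model = NULL) {
  image <- as_volume(image)
  sim <- mean(abs(recon$deformed_template$intensities - image$intensities))
  reg <- displacement_regularizer(recon$field, config$alpha, config$beta,
                                  normalized = TRUE)
  kl <- kl_penalty(recon$latent)
  gen <- 0
  if (!is.null(model) && config$adversarial_weight > 0)
    gen <- patch_adversarial_loss(model, image,
                                  recon$deformed_template)$generator_term
  list(total = sim + reg$total + config$kl_weight * kl +
         config$adversarial_weight * gen,
       similarity = sim, reg_magnitude = reg$magnitude,
       reg_gradient = reg$gradient, kl = kl, generator_term = gen)
}

# ---- training ----------------------------------------------------------

# forward + backward for one item; returns component losses, generator
# grads (enc/dec/tmpl/tmpl_input), and discriminator grads
stage1_item_pass <- function(params, cfg, base_shape, x, cond) {
  cnorm <- normalize_condition(cond)
  tvec <- if (cfg$conditional) cnorm else params$tmpl_input
  tf <- tmpl_f(params$tmpl, tvec, base_shape, cfg$dec_widths[1])
  Tm <- tf$out; dim(Tm) <- dim(Tm)[-1]
  x0 <- array(0, dim = c(2, dim(x)))
  x0[1, , , ] <- x
  x0[2, , , ] <- Tm
  ef <- enc_f(params$enc, x0)
  eps <- array(rnorm(length(ef$mu)), dim = dim(ef$mu))
  sig <- exp(ef$lv / 2)
  z <- ef$mu + sig * eps; dim(z) <- dim(ef$mu)
  zin <- if (cfg$conditional) {
    za <- array(0, dim = dim(z) + c(2L, 0L, 0L, 0L))
    za[seq_len(dim(z)[1]), , , ] <- z
    za[dim(z)[1] + 1L, , , ] <- cnorm[1]
    za[dim(z)[1] + 2L, , , ] <- cnorm[2]
    za
  } else z
  df <- dec_f(params$dec, zin)
  u <- df$out
  Wv <- .warp_fwd(Tm, u, 0L, if (cfg$padding == "border") 0L else 1L)
  nvox <- length(x)
  sim <- mean(abs(Wv - x))
  regg <- .reg_terms_grad(u, cfg$alpha, cfg$beta, 1L, TRUE)
  reg <- list(total = regg$total, magnitude = regg$magnitude,
              gradient = regg$gradient)
  nz <- length(ef$mu)
  kl <- mean(0.5 * (ef$mu^2 + exp(ef$lv) - 1 - ef$lv))

  # adversarial passes (shared forward on the fake)
  gen_term <- 0; disc_term <- 0; disc_grads <- NULL; gW_adv <- 0
  if (cfg$adversarial_weight > 0) {
    fr <- disc_f(params$disc, x)
    ff <- disc_f(params$disc, Wv)
    np <- length(ff$logits)
    gen_term <- 0.5 * mean((ff$logits - 1)^2)
    disc_term <- 0.5 * mean((fr$logits - 1)^2) + 0.5 * mean(ff$logits^2)
    # generator path: gradient into the fake image
    gfake <- (ff$logits - 1) / np; dim(gfake) <- dim(ff$logits)
    gW_adv <- disc_b(params$disc, ff$cache, gfake)$gx
    # critic path: parameter gradients on real and detached fake
    gr <- (fr$logits - 1) / np; dim(gr) <- dim(fr$logits)
    gf <- ff$logits / np; dim(gf) <- dim(ff$logits)
    dgr <- disc_param_grads(params$disc, fr$cache, gr)
    dgf <- disc_param_grads(params$disc, ff$cache, gf)
    disc_grads <- tree_map2(`+`, dgr, dgf)
  }

  # backward through the generator path
  gW <- sign(Wv - x) / nvox
  if (cfg$adversarial_weight > 0) gW <- gW + cfg$adversarial_weight * gW_adv
  dim(gW) <- dim(x)
  wb <- .warp_bwd(Tm, u, gW, if (cfg$padding == "border") 0L else 1L)
  gu <- wb$gu + regg$grad
  dim(gu) <- dim(u)
  db <- dec_b(params$dec, df$cache, gu)
  gz <- db$gzin[seq_len(dim(z)[1]), , , , drop = FALSE]
  gmu <- gz + cfg$kl_weight * ef$mu / nz
  glv <- gz * eps * 0.5 * sig + cfg$kl_weight * 0.5 * (exp(ef$lv) - 1) / nz
  dim(gmu) <- dim(ef$mu); dim(glv) <- dim(ef$lv)
  eb <- enc_b(params$enc, ef$cache, gmu, glv)
  gT <- wb$gvol + eb$gx0[2, , , ]
  gT <- array(gT, dim = c(1, dim(x)))
  tb <- tmpl_b(params$tmpl, tf$cache, gT)

  grads <- list(enc = eb$grads, dec = db$grads, tmpl = tb$grads)
  if (!cfg$conditional) grads$tmpl_input <- tb$gvec
  list(sim = sim, reg = reg, kl = kl, gen = gen_term, disc = disc_term,
       total = sim + reg$total + cfg$kl_weight * kl +
         cfg$adversarial_weight * gen_term,
       grads = grads, disc_grads = disc_grads,
       u = u, latent_sd = stats::sd(z))
}

#' Train the stage-1 autoencoder
#'
#' Jointly optimizes the encoder, deformation decoder and template decoder
#' on the registration objective (and the patch critic adversarially) with
#' Adam, sampling minibatches with the decade-balanced age sampler. The run
#' is deterministic given the config seed. If the loss turns non-finite the
#' run aborts and the last finished epoch's parameters are returned with a
#' warning.
#'
#' @param cohort a \code{phantom_cohort} (or list of \code{phantom})
#' @param config a \code{stage1_config}
#' @return an object of class \code{morph_autoencoder}: fields \code{state}
#'   (trained parameters), \code{history} (per-epoch loss components),
#'   \code{latent_sd} (scalar latent standard deviation for stage-2
#'   scaling), \code{diverged}
#' @export
train_autoencoder <- function(cohort, config = stage1_config()) {
  stopifnot(length(cohort) >= 1)
  gs <- dim(cohort[[1]]$labels)
  st <- init_autoencoder(gs, config)
  params <- st$params
  gen_keys <- c("enc", "dec", "tmpl", if (!config$conditional) "tmpl_input")
  opt_g <- adam_init(params[gen_keys])
  opt_base <- adam_init(list(base = params$tmpl$base))
  opt_d <- if (config$adversarial_weight > 0) adam_init(params["disc"]) else NULL
  n <- length(cohort)
  hist <- list()
  diverged <- FALSE
  with_seed(derive_seed(config$seed, 1L), {
    for (epoch in seq_len(config$epochs)) {
      prev_params <- params
      batches <- if (config$balanced)
        balanced_age_batches(cohort, 10, config$batch_size,
                             seed = derive_seed(config$seed, 1000L + epoch))
      else split(sample(n), ceiling(seq_len(n) / config$batch_size))
      acc <- c(sim = 0, mag = 0, grad = 0, kl = 0, gen = 0, disc = 0,
               total = 0, lat_sd = 0)
      nit <- 0L
      epoch_failed <- tryCatch({
      for (batch in batches) {
        gsum <- NULL; dsum <- NULL
        for (i in batch) {
          it <- stage1_item_pass(params, config, st$base_shape,
                                 cohort[[i]]$image$intensities,
                                 cohort[[i]]$condition)
          acc <- acc + c(it$sim, it$reg$magnitude, it$reg$gradient, it$kl,
                         it$gen, it$disc, it$total, it$latent_sd)
          nit <- nit + 1L
          gsum <- if (is.null(gsum)) it$grads else tree_add(gsum, it$grads)
          if (!is.null(it$disc_grads))
            dsum <- if (is.null(dsum)) it$disc_grads
                    else tree_add(dsum, it$disc_grads)
        }
        gsum <- tree_scale(gsum, 1 / length(batch))
        gbase <- gsum$tmpl$base
        gsum$tmpl$base <- gsum$tmpl$base * 0   # base updated separately
        stp <- adam_step(params[gen_keys], gsum, opt_g, config$lr)
        params[gen_keys] <- stp$params
        opt_g <- stp$state
        # the direct template image trains faster than the conv paths
        stp <- adam_step(list(base = params$tmpl$base), list(base = gbase),
                         opt_base, 10 * config$lr)
        params$tmpl$base <- stp$params$base
        opt_base <- stp$state
        if (!is.null(dsum)) {
          dsum <- tree_scale(dsum, 1 / length(batch))
          stp <- adam_step(params["disc"], list(disc = dsum),
                           opt_d, config$lr)
          params["disc"] <- stp$params
          opt_d <- stp$state
        }
      }
      FALSE
      }, error = function(e) TRUE)
      acc <- acc / max(nit, 1L)
      if (epoch_failed || !all(is.finite(acc)) || tree_any_nonfinite(params)) {
        warning(sprintf("non-finite loss at epoch %d; reverting to last good checkpoint", epoch))
        params <- prev_params
        diverged <- TRUE
        break
      }
      hist[[epoch]] <- data.frame(epoch = epoch, similarity = acc["sim"],
                                  reg_magnitude = acc["mag"],
                                  reg_gradient = acc["grad"], kl = acc["kl"],
                                  generator = acc["gen"],
                                  discriminator = acc["disc"],
                                  total = acc["total"],
                                  latent_sd = acc["lat_sd"],
                                  row.names = NULL)
    }
  })
  st$params <- params
  history <- do.call(rbind, hist)
  structure(list(state = st, history = history,
                 latent_sd = history$latent_sd[nrow(history)],
                 diverged = diverged, config = config),
            class = "morph_autoencoder")
}

#' @export
print.morph_autoencoder <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<morph_autoencoder %s%s, %d epochs, similarity %.4f -> %.4f%s>\n",
    paste(x$state$grid_shape, collapse = "x"),
    if (x$config$conditional) " (conditional)" else "",
    nrow(h), h$similarity[1], h$similarity[nrow(h)],
    if (x$diverged) ", DIVERGED" else ""))
  invisible(x)
}

#' Encode a cohort for stage-2 training
#'
#' @param model a trained \code{morph_autoencoder}
#' @param cohort a \code{phantom_cohort}
#' @param seed seed for the reparameterization noise
#' @return list with \code{latents} (list of latent arrays, following the
#'   config's \code{latent_export} mode) and \code{conditions}
#' @export
encode_cohort <- function(model, cohort, seed = 0L) {
  st <- state_of(model)
  use_mean <- st$config$latent_export == "mean"
  latents <- with_seed(seed, lapply(cohort, function(ph) {
    lc <- encode(st, ph$image, cond = ph$condition)
    if (use_mean) lc$mean else lc$sample
  }))
  list(latents = latents,
       conditions = lapply(cohort, function(ph) ph$condition))
}
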