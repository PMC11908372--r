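# Stage 2: a time-conditioned denoiser over the stage-1 deformation latents
# (epsilon-prediction DDPM), with the condition injected by cross-attention
# over embedded (age, sex) tokens, plus ancestral/DDIM samplers and the
# full generative path latent -> deformation -> deformed template.

#' Diffusion noise schedule
#'
#' @param T_steps number of diffusion steps (desk default 100; 1000 at
#'   reference scale)
#' @param kind \code{"linear"} (betas linearly spaced, DDPM convention) or
#'   \code{"cosine"}
#' @param beta_start,beta_end linear schedule endpoints
#' @return object of class \code{diffusion_schedule} with \code{betas},
#'   \code{alphas}, \code{alpha_bar} (strictly decreasing cumulative
#'   products)
#' @export
diffusion_schedule <- function(T_steps = 100L, kind = c("linear", "cosine"),
                               beta_start = 1e-4, beta_end = 2e-2) {
  kind <- match.arg(kind)
  T_steps <- as.integer(T_steps)
  stopifnot(T_steps >= 1)
  if (kind == "linear") {
    betas <- seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    betas <- pmin(pmax(1 - ab[-1] / ab[-(T_steps + 1)], 1e-8), 0.999)
  }
  alphas <- 1 - betas
  structure(list(T_steps = T_steps, betas = betas, alphas = alphas,
                 alpha_bar = cumprod(alphas), kind = kind),
            class = "diffusion_schedule")
}

#' Forward diffusion: noise a latent to step t
#'
#' \deqn{z_t = \sqrt{\bar\alpha_t}\, z_0 + \sqrt{1 - \bar\alpha_t}\,\epsilon}
#'
#' @param z0 clean latent array
#' @param t integer step in 1..T
#' @param eps standard-normal noise, same shape as \code{z0}
#' @param schedule a \code{diffusion_schedule}
#' @return noised latent, same shape
#' @export
add_noise <- function(z0, t, eps, schedule) {
  if (t < 1 || t > schedule$T_steps)
    stop(sprintf("t = %d outside 1..%d", t, schedule$T_steps))
  stopifnot(identical(dim(z0), dim(eps)) || length(z0) == length(eps))
  ab <- schedule$alpha_bar[t]
  out <- sqrt(ab) * z0 + sqrt(1 - ab) * eps
  dim(out) <- dim(z0)
  out
}

#' Stage-2 configuration
#'
#' @param T_steps diffusion steps
#' @param schedule_kind \code{"linear"} or \code{"cosine"}
#' @param steps optimization steps
#' @param batch_size latents per step
#' @param lr Adam learning rate
#' @param base_channels first-level UNet channels (desk default 24; the
#'   reference-scale preset uses [384, 512, 512])
#' @param down_channels second-level UNet channels
#' @param token_dim condition token embedding width
#' @param seed training seed
#' @return object of class \code{stage2_config}
#' @export
stage2_config <- function(T_steps = 100L, schedule_kind = "linear",
                          steps = 2000L, batch_size = 16L, lr = 1e-3,
                          base_channels = 24L, down_channels = 32L,
                          token_dim = 16L, seed = 0L) {
  structure(list(T_steps = as.integer(T_steps), schedule_kind = schedule_kind,
                 steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr = lr, base_channels = as.integer(base_channels),
                 down_channels = as.integer(down_channels),
                 token_dim = as.integer(token_dim), seed = as.integer(seed)),
            class = "stage2_config")
}

time_embedding <- function(t, dim = 16L) {
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(t * freqs), cos(t * freqs))
}

#' Initialize the denoiser
#'
#' A small 3D UNet over latent grids: two resolution levels with a time
#' embedding added as channel bias, cross-attention over two condition
#' tokens at the latter (coarse) levels, a skip connection, and a
#' zero-initialized output head (so the untrained network predicts 0).
#'
#' @param latent_channels channels of the latents to denoise
#' @param config a \code{stage2_config}
#' @return denoiser state (parameter list)
#' @export
init_denoiser <- function(latent_channels, config = stage2_config()) {
  b1 <- config$base_channels; b2 <- config$down_channels
  dt <- config$token_dim; dk <- dt; te <- 16L
  with_seed(config$seed, list(
    cin = p_conv(latent_channels, b1),
    tp1 = p_dense(te, b1),
    down = p_conv(b1, b2),
    tp2 = p_dense(te, b2),
    tok = p_dense(2, 2 * dt),
    attn1 = p_attn(b2, dt, dk),
    mid = p_conv(b2, b2),
    attn2 = p_attn(b2, dt, dk),
    upc = p_conv(b2, b1),
    fuse = p_conv(2 * b1, b1),
    out = p_conv(b1, latent_channels, init = "zero"),
    dims = list(C = as.integer(latent_channels), b1 = b1, b2 = b2,
                dt = dt, dk = dk, te = te)))
}

p_attn <- function(ch, dt, dk) {
  list(Wq = matrix(rnorm(ch * dk) / sqrt(ch), ch, dk),
       Wk = matrix(rnorm(dt * dk) / sqrt(dt), dt, dk),
       Wv = matrix(rnorm(dt * ch) / sqrt(dt), dt, ch),
       Wo = matrix(rnorm(ch * ch) * 0.1 / sqrt(ch), ch, ch))
}

# cross-attention over token matrix Tok (M x dt); feat is (ch, spatial...)
attn_f <- function(p, feat, Tok) {
  d <- dim(feat)
  Fm <- t(matrix(feat, d[1]))                       # N x ch
  Q <- Fm %*% p$Wq
  K <- Tok %*% p$Wk
  V <- Tok %*% p$Wv
  S <- Q %*% t(K) / sqrt(ncol(Q))
  S <- S - apply(S, 1, max)
  A <- exp(S); A <- A / rowSums(A)
  O <- A %*% V
  out <- Fm + O %*% p$Wo
  y <- array(t(out), dim = d)
  list(out = y, cache = list(Fm = Fm, Q = Q, K = K, V = V, A = A, O = O,
                             Tok = Tok, d = d))
}

attn_b <- function(p, cache, gy) {
  d <- cache$d
  G <- t(matrix(gy, d[1]))                          # N x ch
  gWo <- t(cache$O) %*% G
  gO <- G %*% t(p$Wo)
  gA <- gO %*% t(cache$V)
  gV <- t(cache$A) %*% gO
  gS <- cache$A * (gA - rowSums(gA * cache$A))
  sc <- 1 / sqrt(ncol(cache$Q))
  gQ <- gS %*% cache$K * sc
  gK <- t(gS) %*% cache$Q * sc
  gWq <- t(cache$Fm) %*% gQ
  gF <- G + gQ %*% t(p$Wq)
  gWk <- t(cache$Tok) %*% gK
  gWv <- t(cache$Tok) %*% gV
  gTok <- gK %*% t(p$Wk) + gV %*% t(p$Wv)
  gfeat <- array(t(gF), dim = d)
  list(gx = gfeat, gTok = gTok,
       grads = list(Wq = gWq, Wk = gWk, Wv = gWv, Wo = gWo))
}

add_chan_bias <- function(x, bias) {
  d <- dim(x)
  out <- x + bias   # bias recycles along channel (first) axis
  dim(out) <- d
  out
}

crop_to <- function(x, sp) {
  d <- dim(x)
  if (identical(d[-1], sp)) return(x)
  x[, seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), drop = FALSE]
}

uncrop_to <- function(g, sp_big) {
  d <- dim(g)
  if (identical(d[-1], sp_big)) return(g)
  out <- array(0, dim = c(d[1], sp_big))
  out[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4])] <- g
  out
}

denoiser_f <- function(p, zt, t, cnorm) {
  te <- time_embedding(t, p$dims$te)
  tb1 <- dense_f(p$tp1, te)
  tb2 <- dense_f(p$tp2, te)
  Tok <- matrix(dense_f(p$tok, cnorm), nrow = 2)
  a0 <- add_chan_bias(conv_f(p$cin, zt), tb1)
  r0 <- act_f(a0, "relu"); dim(r0) <- dim(a0)
  a1 <- add_chan_bias(conv_f(p$down, r0, stride = 2), tb2)
  r1 <- act_f(a1, "relu"); dim(r1) <- dim(a1)
  at1 <- attn_f(p$attn1, r1, Tok)
  a2 <- conv_f(p$mid, at1$out)
  r2 <- act_f(a2, "relu"); dim(r2) <- dim(a2)
  at2 <- attn_f(p$attn2, r2, Tok)
  u1 <- crop_to(.upsample2_fwd(at2$out), dim(r0)[-1])
  a3 <- conv_f(p$upc, u1)
  r3 <- act_f(a3, "relu"); dim(r3) <- dim(a3)
  cat0 <- array(0, dim = dim(r3) + c(dim(r0)[1], 0, 0, 0))
  cat0[seq_len(dim(r3)[1]), , , ] <- r3
  cat0[dim(r3)[1] + seq_len(dim(r0)[1]), , , ] <- r0
  a4 <- conv_f(p$fuse, cat0)
  r4 <- act_f(a4, "relu"); dim(r4) <- dim(a4)
  out <- conv_f(p$out, r4)
  list(out = out,
       cache = list(zt = zt, te = te, cnorm = cnorm, Tok = Tok, a0 = a0,
                    r0 = r0, a1 = a1, at1 = at1$cache, h1 = at1$out, a2 = a2,
                    at2 = at2$cache, h2 = at2$out, u1 = u1, a3 = a3, r3 = r3,
                    cat0 = cat0, a4 = a4, r4 = r4))
}

denoiser_b <- function(p, cache, gout) {
  b_out <- conv_b(p$out, cache$r4, gout)
  g <- act_b(b_out$gx, cache$a4, NULL, "relu"); dim(g) <- dim(cache$a4)
  b_fuse <- conv_b(p$fuse, cache$cat0, g)
  c1 <- dim(cache$r3)[1]
  g3 <- b_fuse$gx[seq_len(c1), , , , drop = FALSE]
  g0_skip <- b_fuse$gx[c1 + seq_len(dim(cache$r0)[1]), , , , drop = FALSE]
  g <- act_b(g3, cache$a3, NULL, "relu"); dim(g) <- dim(cache$a3)
  b_upc <- conv_b(p$upc, cache$u1, g)
  g <- .upsample2_bwd(uncrop_to(b_upc$gx, 2L * dim(cache$h2)[-1]))
  ab2 <- attn_b(p$attn2, cache$at2, g)
  g <- act_b(ab2$gx, cache$a2, NULL, "relu"); dim(g) <- dim(cache$a2)
  b_mid <- conv_b(p$mid, cache$h1, g)
  ab1 <- attn_b(p$attn1, cache$at1, b_mid$gx)
  g <- act_b(ab1$gx, cache$a1, NULL, "relu"); dim(g) <- dim(cache$a1)
  gtb2 <- rowSums(matrix(g, dim(g)[1]))
  b_down <- conv_b(p$down, cache$r0, g, stride = 2)
  g <- b_down$gx + g0_skip
  g <- act_b(g, cache$a0, NULL, "relu"); dim(g) <- dim(cache$a0)
  gtb1 <- rowSums(matrix(g, dim(g)[1]))
  b_cin <- conv_b(p$cin, cache$zt, g)
  gTok <- ab1$gTok + ab2$gTok
  b_tok <- dense_b(p$tok, cache$cnorm, as.numeric(gTok))
  b_tp1 <- dense_b(p$tp1, cache$te, gtb1)
  b_tp2 <- dense_b(p$tp2, cache$te, gtb2)
  list(grads = list(
    cin = list(w = b_cin$gw, b = b_cin$gb),
    tp1 = list(w = b_tp1$gw, b = b_tp1$gb),
    down = list(w = b_down$gw, b = b_down$gb),
    tp2 = list(w = b_tp2$gw, b = b_tp2$gb),
    tok = list(w = b_tok$gw, b = b_tok$gb),
    attn1 = ab1$grads,
    mid = list(w = b_mid$gw, b = b_mid$gb),
    attn2 = ab2$grads,
    upc = list(w = b_upc$gw, b = b_upc$gb),
    fuse = list(w = b_fuse$gw, b = b_fuse$gb),
    out = list(w = b_out$gw, b = b_out$gb)))
}

#' One diffusion training step (loss and gradients)
#'
#' Samples t uniformly on 1..T and unit-normal noise per item, forms
#' \code{z_t}, and returns the mean squared error between the true noise
#' and the denoiser prediction, with parameter gradients. Gradients flow
#' to the denoiser only; stage 1 is frozen. A warning is logged if the
#' latents do not look standardized (overall SD far from 1).
#'
#' @param latents list of clean latent arrays (standardized)
#' @param conditions list of \code{condition}
#' @param state denoiser state from \code{\link{init_denoiser}}
#' @param schedule a \code{diffusion_schedule}
#' @param seed optional seed for the (t, eps) draws
#' @return list with \code{loss} (scalar MSE per element) and \code{grads}
#' @export
diffusion_training_step <- function(latents, conditions, state, schedule,
                                    seed = NULL) {
  run <- function() {
    sds <- stats::sd(unlist(latents[seq_len(min(8, length(latents)))]))
    if (is.finite(sds) && (sds > 3 || sds < 1 / 3))
      warning(sprintf("latent scale looks unstandardized (sd = %.3g); expected ~1", sds))
    loss <- 0; gsum <- NULL
    nb <- length(latents)
    for (i in seq_len(nb)) {
      z0 <- latents[[i]]
      t <- sample.int(schedule$T_steps, 1)
      eps <- array(rnorm(length(z0)), dim = dim(z0))
      zt <- add_noise(z0, t, eps, schedule)
      fw <- denoiser_f(state, zt, t, normalize_condition(conditions[[i]]))
      resid <- fw$out - eps
      loss <- loss + mean(resid^2)
      gout <- 2 * resid / length(resid); dim(gout) <- dim(resid)
      bw <- denoiser_b(state, fw$cache, gout)
      gsum <- if (is.null(gsum)) bw$grads else tree_add(gsum, bw$grads)
    }
    list(loss = loss / nb, grads = tree_scale(gsum, 1 / nb))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Train the latent diffusion model
#'
#' Latents are standardized by two scalars (mean subtracted, divided by
#' SD, both over the whole training set) before diffusion; samples are
#' mapped back on the way out. The run is deterministic given the config
#' seed.
#'
#' @param latents list of latent arrays from \code{\link{encode_cohort}}
#' @param conditions list of \code{condition}
#' @param config a \code{stage2_config}
#' @return object of class \code{morph_diffusion}: denoiser state,
#'   schedule, \code{latent_sd}, \code{latent_dim}, training history
#' @export
train_diffusion <- function(latents, conditions, config = stage2_config()) {
  stopifnot(length(latents) >= 1, length(latents) == length(conditions))
  flat <- unlist(latents)
  latent_center <- mean(flat)
  latent_sd <- stats::sd(flat)
  if (!is.finite(latent_sd) || latent_sd == 0) latent_sd <- 1
  if (!is.finite(latent_center)) latent_center <- 0
  zs <- lapply(latents, function(z) {
    z2 <- (z - latent_center) / latent_sd; dim(z2) <- dim(z); z2
  })
  schedule <- diffusion_schedule(config$T_steps, config$schedule_kind)
  state <- init_denoiser(dim(zs[[1]])[1], config)
  dims <- state$dims
  pkeys <- setdiff(names(state), "dims")
  opt <- adam_init(state[pkeys])
  losses <- numeric(config$steps)
  n <- length(zs)
  with_seed(derive_seed(config$seed, 2L), {
    for (s in seq_len(config$steps)) {
      idx <- sample.int(n, min(config$batch_size, n), replace = n < config$batch_size)
      st <- suppressWarnings(
        diffusion_training_step(zs[idx], conditions[idx], state, schedule))
      losses[s] <- st$loss
      stp <- adam_step(state[pkeys], st$grads, opt, config$lr)
      state[pkeys] <- stp$params
      opt <- stp$state
    }
  })
  state$dims <- dims
  structure(list(state = state, schedule = schedule, latent_sd = latent_sd,
                 latent_center = latent_center,
                 latent_dim = dim(zs[[1]]), config = config,
                 history = data.frame(step = seq_len(config$steps),
                                      loss = losses)),
            class = "morph_diffusion")
}

#' @export
print.morph_diffusion <- function(x, ...) {
  n <- nrow(x$history)
  w <- min(50, n)
  cat(sprintf("<morph_diffusion latent %s, T=%d, %d steps, loss %.3f -> %.3f>\n",
              paste(x$latent_dim, collapse = "x"), x$schedule$T_steps, n,
              mean(x$history$loss[seq_len(w)]),
              mean(x$history$loss[(n - w + 1):n])))
  invisible(x)
}

#' Sample a novel latent from the diffusion model
#'
#' Starts from unit Gaussian noise and iterates the chosen reverse process;
#' deterministic given the seed. Returns the latent on the original
#' (unstandardized) scale.
#'
#' @param model a \code{morph_diffusion}
#' @param cond a \code{condition}
#' @param sampler \code{"ancestral"} (stochastic DDPM) or \code{"ddim"}
#'   (deterministic)
#' @param steps reverse steps, <= T (default T)
#' @param seed integer seed
#' @return a latent array of the training latent shape
#' @export
sample_latent <- function(model, cond, sampler = c("ancestral", "ddim"),
                          steps = NULL, seed = 0L) {
  sampler <- match.arg(sampler)
  sch <- model$schedule
  if (is.null(steps)) steps <- sch$T_steps
  if (steps > sch$T_steps)
    stop(sprintf("steps = %d exceeds schedule T = %d", steps, sch$T_steps))
  ts <- unique(round(seq(sch$T_steps, 1, length.out = steps)))
  cnorm <- normalize_condition(cond)
  with_seed(seed, {
    z <- array(rnorm(prod(model$latent_dim)), dim = model$latent_dim)
    for (k in seq_along(ts)) {
      t <- ts[k]
      tprev <- if (k < length(ts)) ts[k + 1] else 0L
      ab_t <- sch$alpha_bar[t]
      ab_p <- if (tprev >= 1) sch$alpha_bar[tprev] else 1
      eps_hat <- denoiser_f(model$state, z, t, cnorm)$out
      x0 <- (z - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
      if (sampler == "ddim") {
        z <- sqrt(ab_p) * x0 + sqrt(1 - ab_p) * eps_hat
      } else {
        var_p <- (1 - ab_p) / (1 - ab_t) * (1 - ab_t / ab_p)
        var_p <- max(var_p, 0)
        z <- sqrt(ab_p) * x0 + sqrt(pmax(1 - ab_p - var_p, 0)) * eps_hat
        if (tprev >= 1)
          z <- z + sqrt(var_p) * array(rnorm(length(z)), dim = dim(z))
      }
      dim(z) <- model$latent_dim
    }
    z <- z * model$latent_sd + model$latent_center
    dim(z) <- model$latent_dim
    z
  })
}

#' Generate novel anatomies
#'
#' The full generative path: sample a latent for each requested condition,
#' decode it into a displacement field (appending the condition channels in
#' the conditional variant), and warp the (condition-specific or universal)
#' learned template.
#'
#' @param ae a trained \code{morph_autoencoder}
#' @param dm a trained \code{morph_diffusion}
#' @param conditions a \code{condition} or list of them (recycled to n)
#' @param n number of samples
#' @param seed master seed; per-sample seeds are derived
#' @param sampler,steps passed to \code{\link{sample_latent}}
#' @return list of samples, each a list with \code{volume}, \code{field},
#'   \code{condition}
#' @export
generate <- function(ae, dm, conditions, n = 1L, seed = 0L,
                     sampler = "ancestral", steps = NULL) {
  if (inherits(conditions, "condition")) conditions <- list(conditions)
  conditions <- rep(conditions, length.out = n)
  exp_shape <- latent_shape(ae$state$grid_shape, ae$config$latent_channels)
  if (!identical(as.integer(dm$latent_dim), exp_shape))
    stop(sprintf("latent shape mismatch: diffusion model has %s, autoencoder expects %s",
                 paste(dm$latent_dim, collapse = "x"),
                 paste(exp_shape, collapse = "x")))
  lapply(seq_len(n), function(i) {
    cond <- conditions[[i]]
    z <- sample_latent(dm, cond, sampler = sampler, steps = steps,
                       seed = derive_seed(seed, i))
    field <- decode_deformation(ae, z, cond)
    tmpl <- template_forward(ae, if (ae$config$conditional) cond else NULL)
    vol <- warp(tmpl, field, "trilinear", ae$config$padding)
    list(volume = vol, field = field, condition = cond)
  })
}
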