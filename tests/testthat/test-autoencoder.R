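# Stage-1 contracts: shapes, the zero-initialization law, loss closed
# forms and component consistency, plus trained-behaviour properties on
# the shared training run.

test_that("encoder obeys the latent shape law", {
  st <- init_autoencoder(c(32, 32, 32), stage1_config(seed = 1))
  img <- volume(array(runif(32^3), c(32, 32, 32)))
  lc <- with_seed(1, encode(st, img))
  expect_identical(dim(lc$mean), c(8L, 4L, 4L, 4L))
  expect_identical(dim(lc$log_variance), dim(lc$mean))
  expect_identical(latent_shape(c(160, 192, 176)), c(8L, 20L, 24L, 22L))
  # identical inputs and noise give identical latents
  lc2 <- encode(st, img, eps = lc$eps)
  expect_identical(lc2$sample, lc$sample)
})

test_that("fresh states start at the identity deformation on the template", {
  for (conditional in c(FALSE, TRUE)) {
    st <- init_autoencoder(c(16, 16, 16), stage1_config(conditional = conditional, seed = 2))
    cond <- if (conditional) condition(30, 1) else NULL
    img <- volume(array(runif(16^3), c(16, 16, 16)))
    rec <- with_seed(3, reconstruct(st, img, cond))
    expect_equal(max(abs(rec$field$u)), 0)
    expect_identical(rec$deformed_template$intensities, rec$template$intensities)
    expect_true(all(is.finite(rec$template$intensities)))
  }
})

test_that("template decoder is deterministic and validates its condition contract", {
  st_u <- init_autoencoder(c(16, 16, 16), stage1_config(seed = 4))
  expect_identical(template_forward(st_u)$intensities,
                   template_forward(st_u)$intensities)
  expect_warning(template_forward(st_u, condition(40, 0)), "unconditional")

  st_c <- init_autoencoder(c(16, 16, 16), stage1_config(conditional = TRUE, seed = 4))
  expect_error(template_forward(st_c), "condition")
})

test_that("decode_deformation checks channel count and appends condition channels", {
  st <- init_autoencoder(c(16, 16, 16), stage1_config(conditional = TRUE, seed = 5))
  z <- array(rnorm(8 * 2 * 2 * 2), c(8, 2, 2, 2))
  f <- decode_deformation(st, z, condition(70, 1))
  expect_identical(as.integer(f$grid_shape), c(16L, 16L, 16L))
  expect_error(decode_deformation(st, array(0, c(5, 2, 2, 2)), condition(70, 1)),
               "channels")
  expect_error(decode_deformation(st, z), "condition")
})

test_that("KL penalty matches its closed form and is nonnegative", {
  z <- array(0, c(2, 2, 2, 2))
  expect_equal(kl_penalty(list(mean = z, log_variance = z)), 0)
  expect_equal(kl_penalty(list(mean = z + 1, log_variance = z)), 0.5)
  with_seed(6, {
    lc <- list(mean = array(rnorm(16), c(2, 2, 2, 2)),
               log_variance = array(rnorm(16), c(2, 2, 2, 2)))
    expect_gte(kl_penalty(lc), 0)
  })
})

test_that("patch-adversarial terms take the least-squares coin-flip values for a constant critic", {
  st <- init_autoencoder(c(16, 16, 16), stage1_config(seed = 7))
  # zero all critic weights; final bias 0.5 => critic outputs exactly 0.5
  st$params$disc <- morphdiff:::tree_map(function(x) x * 0, st$params$disc)
  st$params$disc$c3$b[] <- 0.5
  x <- array(runif(16^3), c(16, 16, 16))
  y <- array(runif(16^3), c(16, 16, 16))
  adv <- patch_adversarial_loss(st, x, y)
  expect_equal(adv$generator_term, 0.5 * (0.5 - 1)^2)
  expect_equal(adv$discriminator_term, 0.5 * (0.5 - 1)^2 + 0.5 * 0.5^2)
})

test_that("registration loss components match independent recomputation", {
  st <- init_autoencoder(c(16, 16, 16), stage1_config(conditional = TRUE, seed = 8))
  img <- volume(array(runif(16^3), c(16, 16, 16)))
  cond <- condition(55, 0)
  rec <- with_seed(9, reconstruct(st, img, cond))
  cfg <- st$config
  rl <- registration_loss(img, rec, cfg, st)
  expect_equal(rl$similarity,
               mean(abs(rec$deformed_template$intensities - img$intensities)),
               tolerance = 1e-6)
  reg <- displacement_regularizer(rec$field, cfg$alpha, cfg$beta,
                                  normalized = TRUE)
  expect_equal(rl$reg_magnitude, reg$magnitude, tolerance = 1e-6)
  expect_equal(rl$reg_gradient, reg$gradient, tolerance = 1e-6)
  expect_equal(rl$kl, kl_penalty(rec$latent), tolerance = 1e-6)
  expect_equal(rl$total,
               rl$similarity + cfg$alpha * rl$reg_magnitude +
                 cfg$beta * rl$reg_gradient + cfg$kl_weight * rl$kl +
                 cfg$adversarial_weight * rl$generator_term,
               tolerance = 1e-10)
  # doubling alpha doubles only the magnitude contribution
  cfg2 <- cfg; cfg2$alpha <- 2 * cfg$alpha
  rl2 <- registration_loss(img, rec, cfg2, st)
  expect_equal(rl2$total - rl$total, cfg$alpha * rl$reg_magnitude,
               tolerance = 1e-10)
  # perfect-fit fixed point: deformed == image, zero field, prior latent
  perfect <- list(
    deformed_template = img, template = img,
    field = identity_field(c(16, 16, 16)),
    latent = list(mean = array(0, c(8, 2, 2, 2)),
                  log_variance = array(0, c(8, 2, 2, 2))))
  cfg0 <- cfg; cfg0$adversarial_weight <- 0
  expect_equal(registration_loss(img, perfect, cfg0)$total, 0)
})

test_that("tiny training runs are deterministic and abort cleanly on divergence", {
  co <- make_cohort(phantom_spec(c(16, 16, 16)), 12, seed = 31)
  cfg <- stage1_config(epochs = 2, batch_size = 4, conditional = TRUE, seed = 9)
  m1 <- train_autoencoder(co, cfg)
  m2 <- train_autoencoder(co, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$state$params, m2$state$params)
  # an absurd learning rate drives the loss non-finite; last good
  # checkpoint is kept
  cfg_bad <- stage1_config(epochs = 3, batch_size = 4, conditional = TRUE,
                           lr = 1e12, seed = 9)
  expect_warning(bad <- train_autoencoder(co, cfg_bad), "checkpoint")
  expect_true(bad$diverged)
  expect_false(morphdiff:::tree_any_nonfinite(bad$state$params))
})

test_that("adversarial-weight zero reduces the objective to L1 + R + KL exactly", {
  st <- init_autoencoder(c(16, 16, 16), stage1_config(adversarial_weight = 0, seed = 10))
  img <- volume(array(runif(16^3), c(16, 16, 16)))
  rec <- with_seed(12, reconstruct(st, img))
  rl <- registration_loss(img, rec, st$config, st)
  expect_equal(rl$generator_term, 0)
  expect_equal(rl$total,
               rl$similarity + st$config$alpha * rl$reg_magnitude +
                 st$config$beta * rl$reg_gradient + st$config$kl_weight * rl$kl)
})

test_that("stage-1 training halves the similarity loss and learns useful deformations", {
  ae <- trained_ae()
  h <- ae$history
  expect_false(ae$diverged)
  expect_lte(h$similarity[nrow(h)], 0.5 * h$similarity[1])

  # deformed template beats the raw template on held-out phantoms
  wins <- 0
  held <- heldout_cohort()
  set.seed(71)
  for (ph in held) {
    rec <- reconstruct(ae, ph$image, ph$condition)
    a <- mean(abs(rec$deformed_template$intensities - ph$image$intensities))
    b <- mean(abs(rec$template$intensities - ph$image$intensities))
    wins <- wins + (a < b)
  }
  expect_gte(wins / length(held), 0.9)
})

test_that("the learned template sits near the deformation centroid and latents stay tame", {
  ae <- trained_ae()
  co <- training_cohort()
  set.seed(72)
  us <- lapply(co[seq(1, 200, by = 2)], function(ph)
    reconstruct(ae, ph$image, ph$condition)$field$u)
  rms <- function(u) sqrt(mean(u^2))
  expect_lte(rms(Reduce(`+`, us) / length(us)),
             0.5 * mean(vapply(us, rms, numeric(1))))

  # KL pressure: no variance blow-up (the penalty's purpose); the
  # posterior naturally sharpens toward a deterministic encoder, so only
  # the upper bound is meaningful
  set.seed(73)
  lcs <- lapply(co[seq(1, 200, by = 10)], function(ph)
    encode(ae, ph$image, cond = ph$condition))
  vars <- unlist(lapply(lcs, function(lc) range(exp(lc$log_variance))))
  expect_lte(max(vars), 10)
  expect_lte(max(vapply(lcs, function(lc) sd(lc$sample), numeric(1))), 10)
})

test_that("conditional templates grow their ventricles with age", {
  ae <- trained_ae()
  counts <- vapply(c(10, 30, 50, 70, 90), function(a)
    sum(threshold_segment(template_forward(ae, condition(a, 0)), std_spec()) == 5L),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[1], 0)
})
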