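# Metric suite: MS-SSIM, regional volumes, Cohen's d, Frechet distance,
# condition predictors and adherence.

test_that("MS-SSIM is 1 for identical samples, low for anti-correlated ones, deterministic", {
  sphere <- make_phantom(phantom_spec(noise_sd = 0), condition(40, 0), 1)$image
  same <- ms_ssim_diversity(list(sphere, sphere, sphere), n_pairs = 20, seed = 1)
  expect_equal(same$mean, 1.0, tolerance = 1e-9)
  expect_true(all(same$pairs > 0 & same$pairs <= 1 + 1e-12))

  bin <- array(0, c(32, 32, 32)); bin[8:24, 8:24, 8:24] <- 1
  anti <- ms_ssim_diversity(list(volume(bin), volume(1 - bin)), n_pairs = 10, seed = 2)
  expect_lt(anti$mean, 0.5)

  co <- make_cohort(phantom_spec(), 6, seed = 3)
  m1 <- ms_ssim_diversity(lapply(co, `[[`, "image"), n_pairs = 50, seed = 4)
  m2 <- ms_ssim_diversity(lapply(co, `[[`, "image"), n_pairs = 50, seed = 4)
  expect_identical(m1$mean, m2$mean)
  expect_lt(m1$mean, 1)
  expect_error(ms_ssim_diversity(list(volume(array(0, c(6, 6, 6))),
                                      volume(array(1, c(6, 6, 6))))),
               "filter support")
})

test_that("regional volumes follow the counting and units laws", {
  # analytic sphere of radius 8 voxels
  spec <- phantom_spec(c(32, 32, 32),
                       regions = list(region_spec("sphere", c(.5, .5, .5),
                                                  rep(8 / 32, 3), .8)),
                       fold_amplitude = 0, noise_sd = 0, smoothing_sigma = 0)
  ph <- make_phantom(spec, condition(40, 0), 1)
  tab <- region_table(spec)
  rv <- regional_volumes(ph$labels, c(1, 1, 1), tab)
  expect_equal(unname(rv["sphere"]), 4 / 3 * pi * 8^3, tolerance = 0.05)
  rv2 <- regional_volumes(ph$labels, c(2, 2, 2), tab)
  expect_equal(unname(rv2["sphere"]), 8 * unname(rv["sphere"]))

  # empty region flagged, unknown ids rejected
  tab2 <- rbind(tab, data.frame(label = 2L, name = "ghost", intensity = 0.5))
  rv3 <- regional_volumes(ph$labels, c(1, 1, 1), tab2)
  expect_equal(unname(rv3["ghost"]), 0)
  expect_identical(attr(rv3, "empty_regions"), "ghost")
  bad <- ph$labels; bad[1] <- 9L
  expect_error(regional_volumes(bad, c(1, 1, 1), tab), "9")
})

test_that("absolute Cohen's d matches the pooled-SD formula and its symmetries", {
  mk <- function(v) structure(c(region = v), class = "regional_volumes")
  real <- lapply(c(2, 4, 6), mk)
  synth <- lapply(c(5, 7, 9), mk)
  es <- abs_cohens_d(real, synth)
  expect_equal(es$d, 1.5)            # |4 - 7| / pooled SD 2
  expect_equal(abs_cohens_d(synth, real)$d, 1.5)
  expect_equal(abs_cohens_d(real, real)$d, 0)

  # random-cohort oracle: independent recomputation to 1e-10
  with_seed(20, {
    for (rep in 1:50) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      a <- rnorm(n1, sd = runif(1, .5, 2)); b <- rnorm(n2, mean = runif(1, -1, 1))
      d_pkg <- abs_cohens_d(lapply(a, mk), lapply(b, mk))$d
      sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
      expect_equal(d_pkg, abs(mean(a) - mean(b)) / sp, tolerance = 1e-10)
    }
  })

  # degenerate pooled SD
  flat <- lapply(c(3, 3, 3), mk)
  up <- lapply(c(4, 4, 4), mk)
  expect_equal(abs_cohens_d(flat, flat)$d, 0)
  es_inf <- abs_cohens_d(flat, up)
  expect_true(is.infinite(es_inf$d))
  expect_equal(es_inf$flag, "infinite_d")
})

test_that("Frechet distance has its closed forms and symmetries", {
  with_seed(21, {
    f <- matrix(rnorm(200 * 4), 200, 4)
    expect_lt(frechet_distance(f, f), 1e-6)
    # 1-D N(0,1) vs N(3,1) at large n: distance ~ (3)^2 + 0 = 9
    a <- matrix(rnorm(20000), ncol = 1)
    b <- matrix(rnorm(20000, mean = 3), ncol = 1)
    expect_equal(frechet_distance(a, b), 9, tolerance = 0.5)
    expect_equal(frechet_distance(a, b), frechet_distance(b, a), tolerance = 1e-8)
    # equal covariances: the trace term cancels, leaving ||mean shift||^2
    base <- matrix(rnorm(5000 * 3), ncol = 3)
    shift <- sweep(base, 2, c(1, -2, 0.5), `+`)
    expect_equal(frechet_distance(base, shift), sum(c(1, -2, 0.5)^2),
                 tolerance = 1e-6)
    expect_error(frechet_distance(matrix(0, 3, 2), matrix(0, 3, 3)), "dimensions")
  })
})

test_that("the age predictor learns the volumetric age signal", {
  p <- age_predictor()
  expect_lte(p$metrics$mae, 10)
  # self-consistency: adherence on real held-out phantoms reproduces the MAE
  co <- predictor_cohort()
  cond <- cohort_conditions(co)
  adh <- condition_adherence(lapply(co[p$val_idx], `[[`, "image"),
                             cond[p$val_idx, ], age_predictor = p)
  expect_equal(adh$age_mae, p$metrics$mae, tolerance = 1e-8)
  expect_true(all(adh$per_decade$mae >= 0))
})

test_that("sex prediction is at chance when the phantom carries no sex signal", {
  spec0 <- phantom_spec(fold_amplitude = 0)
  spec0$regions <- lapply(spec0$regions, function(r) { r$sex_effect <- 0; r })
  co <- make_cohort(spec0, 120, seed = 404)
  p <- train_condition_predictor(co, "sex", epochs = 4, seed = 6)
  expect_gt(p$metrics$accuracy, 0.25)
  expect_lt(p$metrics$accuracy, 0.75)
  single <- co
  attr(single, "conditions")$sex <- 0
  expect_error(train_condition_predictor(single, "sex", seed = 1), "both classes")
})

test_that("predictor training is deterministic and features feed the Frechet metric", {
  co <- make_cohort(phantom_spec(), 30, seed = 505)
  p1 <- train_condition_predictor(co, "age", epochs = 2, seed = 7)
  p2 <- train_condition_predictor(co, "age", epochs = 2, seed = 7)
  expect_identical(p1$metrics, p2$metrics)
  f <- predictor_features(p1, lapply(co[1:10], `[[`, "image"))
  expect_identical(dim(f), c(10L, 16L))
  expect_lt(frechet_distance(f[1:5, ], f[1:5, ]), 1e-6)
})

test_that("condition adherence quantifies a condition-blind generator correctly", {
  p <- age_predictor()
  co <- predictor_cohort()
  # a "generator" that always returns the same volume: its age MAE equals
  # the mean |requested - constant prediction|
  fixed <- co[[1]]$image
  req <- data.frame(age = seq(10, 90, length.out = 20), sex = rep(0:1, 10))
  adh <- condition_adherence(rep(list(fixed), 20), req, age_predictor = p)
  chat <- predict(p, fixed)
  expect_equal(adh$age_mae, mean(abs(req$age - chat)), tolerance = 1e-8)
})
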