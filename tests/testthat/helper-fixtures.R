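# Shared fixtures, built once per test session and cached in memory.
# The two-stage training run is the expensive one (the study conditions:
# 200 phantoms at 32^3, 30 stage-1 epochs, conditional variant); every
# trained-behaviour test reuses it.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

std_spec <- function() phantom_spec()

training_cohort <- function() {
  fixture("training_cohort", function() make_cohort(std_spec(), 200, seed = 101))
}

heldout_cohort <- function() {
  fixture("heldout_cohort", function() make_cohort(std_spec(), 50, seed = 202))
}

trained_ae <- function() {
  fixture("trained_ae", function() {
    train_autoencoder(training_cohort(), stage1_config(conditional = TRUE, seed = 1))
  })
}

trained_dm <- function() {
  fixture("trained_dm", function() {
    enc <- encode_cohort(trained_ae(), training_cohort(), seed = 11)
    train_diffusion(enc$latents, enc$conditions, stage2_config(seed = 12))
  })
}

# 50 samples across ages 5-95, alternating sex: the conditional-recovery set
generated_samples <- function() {
  fixture("generated_samples", function() {
    ages <- seq(5, 95, length.out = 50)
    conds <- lapply(seq_along(ages), function(i) condition(ages[i], (i - 1) %% 2))
    list(ages = ages, conds = conds,
         samples = generate(trained_ae(), trained_dm(), conds, n = 50, seed = 33))
  })
}

ventricle_voxels <- function(samples) {
  vapply(samples, function(s)
    sum(threshold_segment(s$volume, std_spec()) == 5L), numeric(1))
}

# predictor training set (larger, labels only needed at the phantom level)
predictor_cohort <- function() {
  fixture("predictor_cohort", function() make_cohort(std_spec(), 500, seed = 303))
}

age_predictor <- function() {
  fixture("age_predictor", function()
    train_condition_predictor(predictor_cohort(), "age", seed = 5))
}

# toy scalar-latent diffusion run shared by distribution-recovery checks
toy_diffusion <- function() {
  fixture("toy_diffusion", function() {
    z0 <- with_seed(21, lapply(1:256, function(i)
      array(rnorm(1, mean = 2, sd = 0.5), c(1, 1, 1, 1))))
    conds <- lapply(1:256, function(i) condition(50, 0))
    dm <- train_diffusion(z0, conds,
                          stage2_config(T_steps = 100, steps = 1500,
                                        batch_size = 16, base_channels = 8L,
                                        down_channels = 8L, token_dim = 4L,
                                        seed = 22))
    list(z0 = unlist(z0), dm = dm, cond = conds[[1]])
  })
}

with_seed <- morphdiff:::with_seed

# independent scalar triple-lerp oracle used by the warp equivalence tests
warp_oracle <- function(vol, u, padding = "border") {
  d <- dim(vol)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c(i, j, k) - 1 + u[, i, j, k]
    if (padding == "border") p <- pmin(pmax(p, 0), d - 1)
    f <- floor(p); t <- p - f
    acc <- 0
    for (cd in 0:1) for (ch in 0:1) for (cw in 0:1) {
      q <- f + c(cd, ch, cw)
      wt <- prod(ifelse(c(cd, ch, cw) == 1, t, 1 - t))
      if (padding == "border") {
        q <- pmin(pmax(q, 0), d - 1)
        v <- vol[q[1] + 1, q[2] + 1, q[3] + 1]
      } else {
        v <- if (all(q >= 0) && all(q <= d - 1))
          vol[q[1] + 1, q[2] + 1, q[3] + 1] else 0
      }
      acc <- acc + wt * v
    }
    out[i, j, k] <- acc
  }
  out
}
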