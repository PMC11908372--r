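# Warp, displacement regularizer and Jacobian diagnostics against
# independent oracles and closed forms.

test_that("warping with the identity field is the identity", {
  v <- volume(array(runif(5 * 6 * 7), c(5, 6, 7)))
  f0 <- identity_field(c(5, 6, 7))
  expect_equal(warp(v, f0)$intensities, v$intensities, tolerance = 1e-12)
  expect_identical(warp(v, f0, "nearest")$intensities, v$intensities)
})

test_that("integer-shift fields reproduce exact array re-indexing", {
  v <- array(as.numeric(1:64), c(4, 4, 4))
  u <- array(0, c(3, 4, 4, 4)); u[1, , , ] <- 1
  got <- warp(volume(v), displacement_field(u), "trilinear", "zeros")$intensities
  man <- array(0, c(4, 4, 4)); man[1:3, , ] <- v[2:4, , ]
  expect_identical(got, man)
  # shift along the third axis too
  u2 <- array(0, c(3, 4, 4, 4)); u2[3, , , ] <- -2
  got2 <- warp(volume(v), displacement_field(u2), "trilinear", "zeros")$intensities
  man2 <- array(0, c(4, 4, 4)); man2[, , 3:4] <- v[, , 1:2]
  expect_identical(got2, man2)
})

test_that("trilinear warp matches the per-voxel interpolation oracle on random instances", {
  with_seed(10, {
    for (rep in 1:20) {
      d <- sample(3:8, 3, replace = TRUE)
      v <- array(rnorm(prod(d)), d)
      u <- array(rnorm(3 * prod(d), sd = 0.7), c(3, d))
      for (padding in c("border", "zeros")) {
        got <- warp(volume(v), displacement_field(u), "trilinear", padding)$intensities
        expect_lt(max(abs(got - warp_oracle(v, u, padding))), 1e-6)
      }
    }
  })
})

test_that("trilinear sampling is linear in the sampled volume", {
  with_seed(11, {
    d <- c(6, 5, 7)
    x <- array(rnorm(prod(d)), d); y <- array(rnorm(prod(d)), d)
    u <- displacement_field(array(rnorm(3 * prod(d), sd = 0.5), c(3, d)))
    lhs <- warp(volume(2 * x + 3 * y), u)$intensities
    rhs <- 2 * warp(volume(x), u)$intensities + 3 * warp(volume(y), u)$intensities
    expect_equal(lhs, rhs, tolerance = 1e-10)
  })
})

test_that("displacement regularizer reproduces hand-computed values", {
  gs <- c(6, 6, 6)
  expect_equal(displacement_regularizer(identity_field(gs), 5, 1)$total, 0)

  uc <- array(0, c(3, gs)); uc[1, , , ] <- 1
  r <- displacement_regularizer(displacement_field(uc), alpha = 5, beta = 1)
  expect_equal(r$total, 5)          # 5 * mean|u|^2 + 1 * 0
  expect_equal(r$magnitude, 1)
  expect_equal(r$gradient, 0)

  # single axis-1 step of height h between adjacent planes
  h <- 0.4
  us <- array(0, c(3, gs)); us[1, 4:6, , ] <- h
  r2 <- displacement_regularizer(displacement_field(us), alpha = 0, beta = 1)
  nstep <- 6 * 6                    # voxels on the plane where the diff is h
  expect_equal(r2$total, h^2 * nstep / prod(gs), tolerance = 1e-12)
})

test_that("regularizer scales quadratically and its gradient term ignores constants", {
  with_seed(12, {
    u <- array(rnorm(3 * 5 * 5 * 5, sd = .5), c(3, 5, 5, 5))
    f <- displacement_field(u)
    f3 <- displacement_field(3 * u)
    expect_equal(displacement_regularizer(f3, 1, 0)$total,
                 9 * displacement_regularizer(f, 1, 0)$total, tolerance = 1e-10)
    expect_equal(displacement_regularizer(f3, 0, 1)$total,
                 9 * displacement_regularizer(f, 0, 1)$total, tolerance = 1e-10)
    uc <- u; uc[1, , , ] <- uc[1, , , ] + 2; uc[3, , , ] <- uc[3, , , ] - 1
    expect_equal(displacement_regularizer(displacement_field(uc), 0, 1)$total,
                 displacement_regularizer(f, 0, 1)$total, tolerance = 1e-10)
  })
})

test_that("regularizer gradient matches finite differences in both unit conventions", {
  with_seed(13, {
    u <- array(rnorm(3 * 4 * 4 * 4, sd = .3), c(3, 4, 4, 4))
    for (normalized in c(FALSE, TRUE)) {
      g <- morphdiff:::regularizer_grad(u, 5, 1, normalized)
      L <- function(uu) displacement_regularizer(displacement_field(uu), 5, 1,
                                                 normalized)$total
      for (i in sample(length(u), 8)) {
        u2 <- u; u2[i] <- u2[i] + 1e-6
        expect_equal((L(u2) - L(u)) / 1e-6, g[i], tolerance = 1e-3)
      }
    }
    # normalized form rescales by the half grid extent: on a cubic grid a
    # constant field scales by (1 / half)^2 in the magnitude term
    uc <- array(0, c(3, 5, 5, 5)); uc[1, , , ] <- 1
    f <- displacement_field(uc)
    expect_equal(displacement_regularizer(f, 1, 0, normalized = TRUE)$total,
                 displacement_regularizer(f, 1, 0)$total / 4)
  })
})

test_that("Jacobian determinant matches closed forms", {
  gs <- c(8, 8, 8)
  jd <- jacobian_determinant(identity_field(gs))
  expect_equal(max(abs(jd$det - 1)), 0)
  expect_equal(jd$frac_nonpositive, 0)

  uc <- array(0, c(3, gs)); uc[1, , , ] <- 2.5; uc[2, , , ] <- -1
  expect_equal(max(abs(jacobian_determinant(displacement_field(uc))$det - 1)), 0)

  # 10% isotropic expansion: det = 1.1^3 in the interior
  u <- array(0, c(3, gs))
  for (a in 1:3) {
    coord <- slice.index(array(0, gs), a) - 1
    u[a, , , ] <- 0.1 * (coord - 3.5)
  }
  det <- jacobian_determinant(displacement_field(u))$det
  expect_equal(det[3:6, 3:6, 3:6], array(1.331, c(4, 4, 4)), tolerance = 1e-9)
})

test_that("warp rejects mismatched shapes", {
  v <- volume(array(0, c(4, 4, 4)))
  expect_error(warp(v, identity_field(c(4, 4, 5))), "mismatch")
})
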