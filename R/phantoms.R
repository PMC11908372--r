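# Synthetic morphology phantoms: attribute-dependent ellipsoid "anatomy"
# with ground-truth region labels, so the full pipeline is trainable and
# testable without any imaging data download.

#' Construct a subject condition
#'
#' Age in years on [0, 100] and sex coded 0/1. The normalization to model
#' units is fixed package-wide: age/100 and sex as-is (see
#' \code{\link{normalize_condition}}); it is invertible by construction.
#'
#' @param age years, in [0, 100]
#' @param sex 0 or 1 (aliases "M" = 0, "F" = 1 accepted)
#' @return an object of class \code{condition}
#' @export
condition <- function(age, sex) {
  if (is.character(sex)) sex <- c(M = 0, F = 1)[[toupper(sex)]]
  stopifnot(is.numeric(age), age >= 0, age <= 100, sex %in% c(0, 1))
  structure(list(age = as.numeric(age), sex = as.numeric(sex)),
            class = "condition")
}

#' Normalize a condition to model units
#'
#' @param cond a \code{condition}
#' @return numeric c(age/100, sex)
#' @export
normalize_condition <- function(cond) c(cond$age / 100, cond$sex)

#' Invert \code{normalize_condition}
#' @param x numeric length-2 vector in model units
#' @return a \code{condition}
#' @export
denormalize_condition <- function(x) condition(100 * x[1], round(x[2]))

#' Declare a phantom region
#'
#' @param name region name
#' @param center normalized coordinates in [0,1]^3
#' @param radii base semi-axes in normalized units
#' @param intensity tissue intensity in [0,1], distinct across regions
#' @param age_effect additive radius coefficient on normalized age (age/100),
#'   applied to every semi-axis, in normalized units
#' @param sex_effect additive radius offset for sex = 1
#' @param fold logical, whether the folding perturbation applies to this
#'   region's boundary
#' @return a list describing the region
#' @export
region_spec <- function(name, center, radii, intensity, age_effect = 0,
                        sex_effect = 0, fold = FALSE) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0),
            intensity >= 0, intensity <= 1)
  list(name = name, center = as.numeric(center), radii = as.numeric(radii),
       intensity = intensity, age_effect = age_effect, sex_effect = sex_effect,
       fold = isTRUE(fold))
}

#' Declare a phantom cohort specification
#'
#' Geometry is concentric head/brain/ventricle ellipsoids plus lateral
#' subregions; regions are painted in list order, so later (inner) regions
#' overwrite earlier ones in the label map. Region radii vary linearly with
#' normalized age and with sex; the outer boundary carries a sinusoidal
#' "cortical folding" perturbation whose phase depends on sex, giving a
#' purely morphological sex signal.
#'
#' @param grid_shape length-3 positive integers, each >= 8
#' @param regions list of \code{\link{region_spec}}; defaults to the
#'   standard head/brain/ventricle anatomy
#' @param fold_amplitude relative boundary perturbation amplitude, >= 0
#' @param noise_sd additive intensity noise SD, >= 0
#' @param smoothing_sigma Gaussian blur width in voxels, >= 0
#' @return an object of class \code{phantom_spec}
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), regions = NULL,
                         fold_amplitude = 0.06, noise_sd = 0.02,
                         smoothing_sigma = 0.6) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            fold_amplitude >= 0, noise_sd >= 0, smoothing_sigma >= 0)
  if (is.null(regions)) regions <- default_regions()
  # radii must stay strictly positive over age in [0,100] and both sexes
  for (r in regions) {
    worst <- min(r$radii) + min(0, r$age_effect) + min(0, r$sex_effect)
    if (worst <= 0)
      stop(sprintf("region '%s': radius becomes nonpositive within the declared age/sex range", r$name))
  }
  ints <- vapply(regions, `[[`, numeric(1), "intensity")
  if (anyDuplicated(c(0, ints)))
    stop("region intensities (and background 0) must be distinct")
  structure(list(grid_shape = as.integer(grid_shape), regions = regions,
                 fold_amplitude = fold_amplitude, noise_sd = noise_sd,
                 smoothing_sigma = smoothing_sigma),
            class = "phantom_spec")
}

default_regions <- function() {
  list(
    region_spec("head",      c(0.50, 0.50, 0.50), c(0.44, 0.46, 0.42), 0.25,
                fold = TRUE),
    region_spec("brain",     c(0.50, 0.50, 0.50), c(0.36, 0.38, 0.34), 0.55,
                age_effect = -0.02, sex_effect = 0.010),
    region_spec("left_sub",  c(0.30, 0.56, 0.50), c(0.07, 0.07, 0.07), 0.75,
                age_effect = -0.010, sex_effect = 0.012),
    region_spec("right_sub", c(0.70, 0.56, 0.50), c(0.07, 0.07, 0.07), 0.40,
                age_effect = -0.010, sex_effect = -0.012),
    # ventricles grow markedly with age, the morphology the model must recover
    region_spec("ventricle", c(0.50, 0.50, 0.46), c(0.08, 0.10, 0.08), 0.95,
                age_effect = 0.080)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec %s, %d regions: %s>\n",
              paste(x$grid_shape, collapse = "x"), length(x$regions),
              paste(vapply(x$regions, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Region label table of a phantom spec
#'
#' @param spec a \code{phantom_spec}
#' @return data.frame with columns \code{label}, \code{name},
#'   \code{intensity} (label 0 = background is not listed)
#' @export
region_table <- function(spec) {
  data.frame(label = seq_along(spec$regions),
             name = vapply(spec$regions, `[[`, character(1), "name"),
             intensity = vapply(spec$regions, `[[`, numeric(1), "intensity"),
             stringsAsFactors = FALSE)
}

# effective radii of a region under a condition (normalized units)
region_radii <- function(r, cond) {
  r$radii + r$age_effect * (cond$age / 100) + r$sex_effect * cond$sex
}

#' Generate one phantom
#'
#' Deterministic in (spec, condition, seed): region \code{r}'s semi-axes are
#' \code{base + age_effect * age/100 + sex_effect * sex} (before the folding
#' perturbation), labels are painted in region order, the noiseless image is
#' the per-label intensity, then Gaussian smoothing and additive noise are
#' applied to the image only. Labels remain the exact ground truth.
#'
#' @param spec a \code{phantom_spec}
#' @param cond a \code{condition}
#' @param seed integer seed for the intensity noise
#' @return an object of class \code{phantom}: fields \code{image} (a
#'   \code{volume} with intensities in [0,1]), \code{labels} (integer array),
#'   \code{condition}, \code{seed}
#' @export
make_phantom <- function(spec, cond, seed = 0L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(cond, "condition"))
  gs <- spec$grid_shape
  # voxel-center coordinates in normalized [0,1]^3 units
  ax <- lapply(1:3, function(a) (seq_len(gs[a]) - 0.5) / gs[a])
  X <- array(rep(ax[[1]], times = gs[2] * gs[3]), dim = gs)
  Y <- array(rep(rep(ax[[2]], each = gs[1]), times = gs[3]), dim = gs)
  Z <- array(rep(ax[[3]], each = gs[1] * gs[2]), dim = gs)
  labels <- array(0L, dim = gs)
  for (j in seq_along(spec$regions)) {
    r <- spec$regions[[j]]
    rad <- region_radii(r, cond)
    if (any(rad <= 0))
      stop(sprintf("region '%s': nonpositive radius for age=%g sex=%g",
                   r$name, cond$age, cond$sex))
    dx <- (X - r$center[1]) / rad[1]
    dy <- (Y - r$center[2]) / rad[2]
    dz <- (Z - r$center[3]) / rad[3]
    rho <- sqrt(dx^2 + dy^2 + dz^2)
    bound <- 1
    if (r$fold && spec$fold_amplitude > 0) {
      theta <- atan2(dy, dx)
      phi <- atan2(sqrt(dx^2 + dy^2), dz)
      phase <- cond$sex * pi / 2
      bound <- 1 + spec$fold_amplitude * sin(4 * theta + phase) * sin(3 * phi)
    }
    labels[rho <= bound] <- j
  }
  counts <- tabulate(labels, nbins = length(spec$regions))
  if (any(counts == 0))
    stop(sprintf("region '%s' occupies no voxel at this grid size",
                 spec$regions[[which(counts == 0)[1]]]$name))
  ints <- c(0, vapply(spec$regions, `[[`, numeric(1), "intensity"))
  img <- array(ints[labels + 1L], dim = gs)
  if (spec$smoothing_sigma > 0) img <- .blur3d(img, spec$smoothing_sigma)
  if (spec$noise_sd > 0)
    img <- img + with_seed(seed, array(rnorm(prod(gs), sd = spec$noise_sd), gs))
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- gs
  structure(list(image = volume(img), labels = labels, condition = cond,
                 seed = as.integer(seed)), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s, age %.1f, sex %d, seed %d>\n",
              paste(dim(x$labels), collapse = "x"), x$condition$age,
              x$condition$sex, x$seed))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Ages are drawn from the declared sampler, sexes are allocated exactly at
#' \code{sex_ratio} (round(n * sex_ratio) subjects with sex = 1) and
#' shuffled, and each subject gets an independent seed derived from the
#' master seed, so cohorts are reproducible end to end.
#'
#' @param spec a \code{phantom_spec}
#' @param n cohort size, >= 1
#' @param age_sampler either a function(n) returning ages or the string
#'   \code{"uniform"} (uniform on \code{age_range})
#' @param age_range used by the uniform sampler, default c(5, 100)
#' @param sex_ratio fraction of sex = 1 subjects
#' @param seed master seed
#' @return an object of class \code{phantom_cohort} (a list of
#'   \code{phantom} with a \code{conditions} attribute)
#' @export
make_cohort <- function(spec, n, age_sampler = "uniform",
                        age_range = c(5, 100), sex_ratio = 0.5, seed = 0L) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    ages <- if (is.function(age_sampler)) age_sampler(n)
            else runif(n, age_range[1], age_range[2])
    n1 <- round(n * sex_ratio)
    sexes <- sample(c(rep(1, n1), rep(0, n - n1)))
    seeds <- sample.int(2147483646L, n)
    list(ages = pmin(pmax(ages, 0), 100), sexes = sexes, seeds = seeds)
  })
  items <- vector("list", n)
  for (i in seq_len(n)) {
    items[[i]] <- make_phantom(spec, condition(draws$ages[i], draws$sexes[i]),
                               draws$seeds[i])
  }
  structure(items, class = "phantom_cohort", spec = spec,
            conditions = data.frame(age = draws$ages, sex = draws$sexes,
                                    seed = draws$seeds))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf("<phantom_cohort n=%d, ages %.1f-%.1f, %d/%d sex 0/1>\n",
              length(x), min(cond$age), max(cond$age), sum(cond$sex == 0),
              sum(cond$sex == 1)))
  invisible(x)
}

#' Cohort conditions table
#' @param cohort a \code{phantom_cohort}
#' @return data.frame with columns age, sex, seed
#' @export
cohort_conditions <- function(cohort) attr(cohort, "conditions")

#' Age-balanced batch sampler
#'
#' Emits index batches by first drawing an age bin uniformly among nonempty
#' bins, then a member uniformly within the bin (with replacement), so the
#' expected draw count per nonempty bin is equal — the decade-balanced
#' sampling used during training on age-skewed cohorts.
#'
#' @param cohort a \code{phantom_cohort} (or anything with a conditions table)
#' @param bin_width bin width in years, default 10 (decades)
#' @param batch_size draws per emitted batch
#' @param n_batches number of batches; default covers one epoch
#'   (\code{ceiling(n / batch_size)})
#' @param seed integer seed
#' @return list of integer index vectors into the cohort
#' @export
balanced_age_batches <- function(cohort, bin_width = 10, batch_size = 8L,
                                 n_batches = NULL, seed = 0L) {
  cond <- cohort_conditions(cohort)
  n <- nrow(cond)
  if (is.null(n) || n == 0) stop("empty cohort")
  if (is.null(n_batches)) n_batches <- ceiling(n / batch_size)
  bins <- split(seq_len(n), floor(cond$age / bin_width))
  bins <- bins[vapply(bins, length, integer(1)) > 0]
  with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      vapply(seq_len(batch_size), function(i) {
        bin <- bins[[sample.int(length(bins), 1)]]
        bin[sample.int(length(bin), 1)]
      }, integer(1))
    })
  })
}
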