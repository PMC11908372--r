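# Evaluation suite: MS-SSIM diversity, regional-volume effect sizes
# (absolute Cohen's d), condition adherence via trained CNN predictors,
# and a Frechet distance over pluggable feature embeddings.

# ---- MS-SSIM -----------------------------------------------------------

# single-pair 3D multi-scale SSIM; standard 5-scale weights, scales
# reduced automatically until the 11^3 Gaussian window fits
msssim_pair <- function(x, y, data_range = 1, sigma = 1.5) {
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  min_side <- 11
  n_scales <- 0
  cs_vals <- numeric(0)
  l_val <- NA_real_
  repeat {
    if (min(dim(x)) < min_side || n_scales == 5) break
    n_scales <- n_scales + 1
    mx <- .blur3d(x, sigma); my <- .blur3d(y, sigma)
    sxx <- .blur3d(x * x, sigma) - mx^2
    syy <- .blur3d(y * y, sigma) - my^2
    sxy <- .blur3d(x * y, sigma) - mx * my
    cs <- mean((2 * sxy + C2) / (sxx + syy + C2))
    cs_vals <- c(cs_vals, max(cs, 0))
    l_val <- mean((2 * mx * my + C1) / (mx^2 + my^2 + C1))
    if (min(dim(x)) < 2 * min_side || n_scales == 5) break
    x <- .downsample2_avg(x); y <- .downsample2_avg(y)
  }
  if (n_scales == 0) stop("volume smaller than the minimal SSIM filter support (11 voxels)")
  w <- weights[seq_len(n_scales)]
  w <- w / sum(w)
  vals <- cs_vals
  vals[n_scales] <- vals[n_scales] * max(l_val, 0)
  score <- prod(vals^w)
  attr(score, "n_scales") <- n_scales
  score
}

#' MS-SSIM diversity of a sample set
#'
#' Draws random pairs (uniform, no self-pairing) and averages 3D multi-scale
#' SSIM over them; a high mean indicates similar samples and therefore low
#' diversity. The scale count is reduced automatically on small grids and
#' recorded in the result.
#'
#' @param samples list of \code{volume} (or 3D arrays)
#' @param n_pairs number of random pairs (1000 in the reference protocol)
#' @param seed pair-sampling seed
#' @return list with \code{mean}, \code{pairs} (per-pair values),
#'   \code{n_scales}, \code{note}
#' @export
ms_ssim_diversity <- function(samples, n_pairs = 1000L, seed = 0L) {
  stopifnot(length(samples) >= 2)
  arrs <- lapply(samples, function(s) if (inherits(s, "volume")) s$intensities else s)
  idx <- with_seed(seed, {
    t(vapply(seq_len(n_pairs), function(k) {
      i <- sample.int(length(arrs), 1)
      j <- sample.int(length(arrs) - 1, 1)
      if (j >= i) j <- j + 1L
      c(i, j)
    }, integer(2)))
  })
  vals <- numeric(n_pairs)
  nsc <- NA_integer_
  for (k in seq_len(n_pairs)) {
    s <- msssim_pair(arrs[[idx[k, 1]]], arrs[[idx[k, 2]]])
    vals[k] <- as.numeric(s)
    nsc <- attr(s, "n_scales")
  }
  note <- if (nsc < 5)
    sprintf("scales reduced to %d for grid %s", nsc,
            paste(dim(arrs[[1]]), collapse = "x")) else NULL
  list(mean = mean(vals), pairs = vals, n_scales = nsc, note = note)
}

# ---- regional volumes and effect sizes --------------------------------

#' Regional volumes from a label map
#'
#' \code{volume(name) = count(labels == id) * prod(spacing)} in mm^3.
#'
#' @param labels integer 3D label array (0 = background)
#' @param spacing voxel spacing in mm
#' @param table data.frame with columns \code{label}, \code{name} (e.g.
#'   \code{\link{region_table}})
#' @param subject optional subject id
#' @param source provenance tag, \code{"ground_truth_labels"} or
#'   \code{"threshold_segmentation"}
#' @return object of class \code{regional_volumes}: named numeric vector of
#'   mm^3 volumes with \code{empty_regions} attribute
#' @export
regional_volumes <- function(labels, spacing = c(1, 1, 1), table,
                             subject = NA_character_,
                             source = "ground_truth_labels") {
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  unknown <- setdiff(ids, table$label)
  if (length(unknown) > 0)
    stop(sprintf("label ids not in region table: %s",
                 paste(unknown, collapse = ", ")))
  vv <- prod(spacing)
  counts <- vapply(table$label, function(id) sum(labels == id), numeric(1))
  vols <- counts * vv
  names(vols) <- table$name
  structure(vols, class = "regional_volumes", subject = subject,
            source = source, empty_regions = table$name[counts == 0])
}

#' @export
print.regional_volumes <- function(x, ...) {
  cat(sprintf("<regional_volumes (%s)>\n", attr(x, "source")))
  print(unclass(x)[seq_along(x)])
  emp <- attr(x, "empty_regions")
  if (length(emp)) cat("present-but-empty:", paste(emp, collapse = ", "), "\n")
  invisible(x)
}

#' Absolute Cohen's d of regional volumes between two cohorts
#'
#' Classical two-sample form with pooled standard deviation:
#' \deqn{d = |m_1 - m_2| / s_p,\quad
#'   s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2) / (n_1+n_2-2)}.}
#' A d near 0 means the synthetic cohort's regional volumes match the real
#' cohort's. Regions with zero pooled SD are flagged (infinite d when the
#' means differ, 0 when they agree), never silently dropped.
#'
#' @param real list of \code{regional_volumes} (>= 2 subjects)
#' @param synth list of \code{regional_volumes} (>= 2 subjects)
#' @return object of class \code{effect_size_report}: a data.frame with
#'   per-region d, means, SDs, cohort sizes and flags
#' @export
abs_cohens_d <- function(real, synth) {
  stopifnot(length(real) >= 2, length(synth) >= 2)
  rn <- names(real[[1]])
  if (!identical(sort(rn), sort(names(synth[[1]]))))
    stop("region sets differ between cohorts")
  M1 <- do.call(rbind, lapply(real, function(v) unclass(v)[rn]))
  M2 <- do.call(rbind, lapply(synth, function(v) unclass(v)[rn]))
  n1 <- nrow(M1); n2 <- nrow(M2)
  m1 <- colMeans(M1); m2 <- colMeans(M2)
  s1 <- apply(M1, 2, stats::sd); s2 <- apply(M2, 2, stats::sd)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- ifelse(sp > 0, abs(m1 - m2) / sp,
              ifelse(abs(m1 - m2) < .Machine$double.eps^0.5, 0, Inf))
  out <- data.frame(region = rn, d = unname(d), mean_real = unname(m1),
                    mean_synth = unname(m2), sd_real = unname(s1),
                    sd_synth = unname(s2), n_real = n1, n_synth = n2,
                    flag = ifelse(is.infinite(d), "infinite_d", ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("effect_size_report", "data.frame")
  out
}

# ---- threshold segmentation of generated images -----------------------

#' Segment a generated image by nearest declared intensity
#'
#' Maps each voxel to the region (or background) whose declared intensity
#' is nearest — equivalent to thresholding at the midpoints of the
#' phantom's intensity table. Stands in for a learned segmenter on
#' generated images whose ground-truth labels are unknown.
#'
#' @param vol a \code{volume} or 3D array
#' @param spec the \code{phantom_spec} declaring the intensity table
#' @return integer label array (0 = background)
#' @export
threshold_segment <- function(vol, spec) {
  x <- if (inherits(vol, "volume")) vol$intensities else vol
  ints <- c(0, vapply(spec$regions, `[[`, numeric(1), "intensity"))
  lab <- apply_nearest(x, ints)
  array(lab, dim = dim(x))
}

apply_nearest <- function(x, levels) {
  # midpoint thresholding against sorted levels, mapped back to label ids
  ord <- order(levels)
  sorted <- levels[ord]
  mids <- (sorted[-1] + sorted[-length(sorted)]) / 2
  k <- findInterval(as.numeric(x), mids) + 1L
  as.integer(ord[k] - 1L)  # label = position in `levels` minus 1 (bg = 0)
}

# ---- condition predictors ---------------------------------------------

pred_net_init <- function(widths = c(8L, 16L, 16L), seed = 0L) {
  with_seed(seed, list(c1 = p_conv(1, widths[1]), c2 = p_conv(widths[1], widths[2]),
                       c3 = p_conv(widths[2], widths[3]),
                       fc = p_dense(widths[3], 1)))
}

pred_net_f <- function(p, x) {
  x0 <- array(x, dim = c(1, dim(x)))
  a1 <- conv_f(p$c1, x0, stride = 2); r1 <- act_f(a1, "relu"); dim(r1) <- dim(a1)
  a2 <- conv_f(p$c2, r1, stride = 2); r2 <- act_f(a2, "relu"); dim(r2) <- dim(a2)
  a3 <- conv_f(p$c3, r2, stride = 2); r3 <- act_f(a3, "relu"); dim(r3) <- dim(a3)
  feat <- rowMeans(matrix(r3, dim(r3)[1]))         # global average pool
  out <- dense_f(p$fc, feat)
  list(out = out, feat = feat,
       cache = list(x0 = x0, a1 = a1, r1 = r1, a2 = a2, r2 = r2, a3 = a3,
                    r3 = r3, feat = feat))
}

pred_net_b <- function(p, cache, gout) {
  bf <- dense_b(p$fc, cache$feat, gout)
  nsp <- prod(dim(cache$r3)[-1])
  g <- array(rep(bf$gx / nsp, nsp), dim = dim(cache$r3))
  g <- act_b(g, cache$a3, NULL, "relu"); dim(g) <- dim(cache$a3)
  b3 <- conv_b(p$c3, cache$r2, g, stride = 2)
  g <- act_b(b3$gx, cache$a2, NULL, "relu"); dim(g) <- dim(cache$a2)
  b2 <- conv_b(p$c2, cache$r1, g, stride = 2)
  g <- act_b(b2$gx, cache$a1, NULL, "relu"); dim(g) <- dim(cache$a1)
  b1 <- conv_b(p$c1, cache$x0, g, stride = 2)
  list(grads = list(c1 = list(w = b1$gw, b = b1$gb),
                    c2 = list(w = b2$gw, b = b2$gb),
                    c3 = list(w = b3$gw, b = b3$gb),
                    fc = list(w = bf$gw, b = bf$gb)))
}

#' Train a CNN condition predictor on a phantom cohort
#'
#' A small 3D convolutional regressor (age) or classifier (sex) with a
#' seeded held-out split; its penultimate (global-average-pooled) features
#' double as the bundled feature extractor for the Frechet distance.
#'
#' @param cohort a \code{phantom_cohort}
#' @param target \code{"age"} or \code{"sex"}
#' @param epochs,lr,batch_size optimizer settings
#' @param val_fraction held-out fraction
#' @param seed seed for split, init and batching
#' @return object of class \code{condition_predictor} with held-out
#'   \code{metrics} (MAE in years, or accuracy)
#' @export
train_condition_predictor <- function(cohort, target = c("age", "sex"),
                                      epochs = 12L, lr = 3e-3,
                                      batch_size = 16L, val_fraction = 0.2,
                                      seed = 0L) {
  target <- match.arg(target)
  cond <- cohort_conditions(cohort)
  if (target == "sex" && length(unique(cond$sex)) < 2)
    stop("sex classifier needs both classes in the cohort")
  n <- length(cohort)
  split <- with_seed(derive_seed(seed, 3L), sample(n))
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- split[seq_len(n_val)]
  tr_idx <- split[-seq_len(n_val)]
  y <- if (target == "age") cond$age / 100 else ifelse(cond$sex == 1, 1, -1)
  params <- pred_net_init(seed = derive_seed(seed, 4L))
  opt <- adam_init(params)
  with_seed(derive_seed(seed, 5L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        gsum <- NULL
        for (i in b) {
          fw <- pred_net_f(params, cohort[[i]]$image$intensities)
          gout <- if (target == "age") 2 * (fw$out - y[i])
                  else -y[i] / (1 + exp(y[i] * fw$out))
          bw <- pred_net_b(params, fw$cache, gout)
          gsum <- if (is.null(gsum)) bw$grads else tree_add(gsum, bw$grads)
        }
        stp <- adam_step(params, tree_scale(gsum, 1 / length(b)), opt, lr)
        params <- stp$params
        opt <- stp$state
      }
    }
  })
  preds <- vapply(val_idx, function(i)
    pred_net_f(params, cohort[[i]]$image$intensities)$out, numeric(1))
  metrics <- if (target == "age") {
    list(mae = mean(abs(100 * preds - cond$age[val_idx])))
  } else {
    list(accuracy = mean((preds > 0) == (cond$sex[val_idx] == 1)))
  }
  structure(list(params = params, target = target, metrics = metrics,
                 grid_shape = dim(cohort[[1]]$labels),
                 spec_hash = content_hash(attr(cohort, "spec")),
                 val_idx = val_idx, seed = seed),
            class = "condition_predictor")
}

#' @export
print.condition_predictor <- function(x, ...) {
  m <- if (x$target == "age") sprintf("held-out MAE %.2f years", x$metrics$mae)
       else sprintf("held-out accuracy %.3f", x$metrics$accuracy)
  cat(sprintf("<condition_predictor (%s), %s>\n", x$target, m))
  invisible(x)
}

#' Predict conditions for volumes
#'
#' @param object a \code{condition_predictor}
#' @param volumes a \code{volume} or list of volumes
#' @param ... unused
#' @return numeric vector: predicted age in years, or sex in {0, 1}
#' @export
predict.condition_predictor <- function(object, volumes, ...) {
  if (inherits(volumes, "volume") || (is.array(volumes) && length(dim(volumes)) == 3))
    volumes <- list(volumes)
  vapply(volumes, function(v) {
    x <- if (inherits(v, "volume")) v$intensities else v
    if (!identical(dim(x), object$grid_shape))
      stop("volume grid does not match the predictor's training grid")
    o <- pred_net_f(object$params, x)$out
    if (object$target == "age") 100 * o else as.numeric(o > 0)
  }, numeric(1))
}

#' Penultimate feature embedding of a predictor
#'
#' @param predictor a \code{condition_predictor}
#' @param volumes list of volumes
#' @return matrix (n x feature_dim) of pooled convolutional features
#' @export
predictor_features <- function(predictor, volumes) {
  t(vapply(volumes, function(v) {
    x <- if (inherits(v, "volume")) v$intensities else v
    pred_net_f(predictor$params, x)$feat
  }, numeric(length(predictor$params$fc$b) * ncol(predictor$params$fc$w))))
}

#' Condition adherence of generated samples
#'
#' Passes samples through trained predictors and compares predictions with
#' the requested conditions: overall age MAE, sex accuracy, and age MAE
#' binned by requested-age decade.
#'
#' @param volumes list of generated \code{volume}
#' @param requested data.frame with columns \code{age}, \code{sex} (or list
#'   of \code{condition})
#' @param age_predictor,sex_predictor trained
#'   \code{\link{train_condition_predictor}} objects (either may be NULL)
#' @param spec_hash optional generator spec hash; if both sides carry one
#'   and they differ, an error is raised
#' @return list with \code{age_mae}, \code{sex_accuracy},
#'   \code{per_decade} (data.frame decade/mae/n)
#' @export
condition_adherence <- function(volumes, requested, age_predictor = NULL,
                                sex_predictor = NULL, spec_hash = NULL) {
  if (!is.data.frame(requested))
    requested <- data.frame(age = vapply(requested, `[[`, numeric(1), "age"),
                            sex = vapply(requested, `[[`, numeric(1), "sex"))
  out <- list(age_mae = NA_real_, sex_accuracy = NA_real_, per_decade = NULL)
  for (p in list(age_predictor, sex_predictor)) {
    if (!is.null(p) && !is.null(spec_hash) && !identical(p$spec_hash, spec_hash))
      stop("predictor was trained on a different phantom spec than the generator")
  }
  if (!is.null(age_predictor)) {
    pred_age <- predict(age_predictor, volumes)
    out$age_mae <- mean(abs(pred_age - requested$age))
    dec <- floor(requested$age / 10)
    out$per_decade <- do.call(rbind, lapply(sort(unique(dec)), function(d) {
      sel <- dec == d
      data.frame(decade = d, mae = mean(abs(pred_age[sel] - requested$age[sel])),
                 n = sum(sel))
    }))
  }
  if (!is.null(sex_predictor)) {
    pred_sex <- predict(sex_predictor, volumes)
    out$sex_accuracy <- mean(pred_sex == requested$sex)
  }
  out
}

# ---- Frechet distance --------------------------------------------------

#' Frechet distance between two feature distributions
#'
#' Gaussian fits to the two embeddings:
#' \deqn{\|\mu_1-\mu_2\|^2 + \mathrm{Tr}(\Sigma_1+\Sigma_2 -
#'   2(\Sigma_1\Sigma_2)^{1/2}),}
#' computed with a symmetrized matrix square root
#' \eqn{(\Sigma_1^{1/2}\Sigma_2\Sigma_1^{1/2})^{1/2}} and an eigenvalue
#' floor at 0 against numerically tiny negatives. The feature extractor is
#' pluggable; \code{\link{predictor_features}} is the bundled default.
#'
#' @param real_features matrix n1 x d
#' @param synth_features matrix n2 x d
#' @return nonnegative scalar
#' @export
frechet_distance <- function(real_features, synth_features) {
  f1 <- as.matrix(real_features); f2 <- as.matrix(synth_features)
  if (ncol(f1) != ncol(f2))
    stop(sprintf("feature dimensions differ: %d vs %d", ncol(f1), ncol(f2)))
  stopifnot(nrow(f1) >= 2, nrow(f2) >= 2)
  mu1 <- colMeans(f1); mu2 <- colMeans(f2)
  S1 <- stats::cov(f1); S2 <- stats::cov(f2)
  sqrtm <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    v <- pmax(e$values, 0)
    e$vectors %*% (sqrt(v) * t(e$vectors))
  }
  R1 <- sqrtm(S1)
  mid <- sqrtm(R1 %*% S2 %*% R1)
  val <- sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * sum(diag(mid))
  max(val, 0)
}
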