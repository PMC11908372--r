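# Shared engineering: NIfTI read/write, cohort manifests, run
# configuration with presets and overrides, and content hashing.

#' Read a NIfTI volume
#'
#' @param path a .nii or .nii.gz file
#' @return a \code{volume} (3D) — 4D inputs are rejected unless they are
#'   3-channel displacement-field files, for which
#'   \code{\link{read_field}} should be used
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4) {
    if (d[4] == 3)
      stop("4D 3-channel file looks like a displacement field; use read_field()")
    stop(sprintf("expected a 3D volume, got %s", paste(d, collapse = "x")))
  }
  stopifnot(length(d) == 3)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = d)
  volume(arr, sp, affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a volume as NIfTI
#'
#' Volumes are written RAS with a spacing-scaled affine by default.
#'
#' @param vol a \code{volume}
#' @param path destination (.nii or .nii.gz)
#' @return invisibly, the path
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from 4D NIfTI
#'
#' Fields persist with the 3 displacement channels as the last dimension;
#' internally the package stores them channel-first.
#'
#' @param path a 4D .nii/.nii.gz with last dim 3
#' @return a \code{displacement_field}
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[4] != 3)
    stop(sprintf("expected a 4D 3-channel field file, got %s",
                 paste(d, collapse = "x")))
  u <- aperm(array(as.numeric(img), dim = d), c(4, 1, 2, 3))
  displacement_field(u, RNifti::pixdim(img)[1:3])
}

#' Write a displacement field as 4D NIfTI
#'
#' @param field a \code{displacement_field}
#' @param path destination
#' @return invisibly, the path
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(aperm(field$u, c(2, 3, 4, 1)))
  RNifti::pixdim(img) <- c(field$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a phantom cohort to disk
#'
#' BIDS-flavoured layout: \code{sub-XXXX_T1w.nii.gz},
#' \code{sub-XXXX_seg.nii.gz} and a \code{participants.tsv} manifest with
#' columns id, age, sex, seed.
#'
#' @param cohort a \code{phantom_cohort}
#' @param dir output directory (created if needed)
#' @param save_fields optional list of \code{displacement_field} written
#'   alongside as \code{sub-XXXX_field.nii.gz}
#' @return invisibly, the manifest path
#' @export
write_cohort <- function(cohort, dir, save_fields = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cond <- cohort_conditions(cohort)
  ids <- sprintf("sub-%04d", seq_along(cohort))
  for (i in seq_along(cohort)) {
    write_volume(cohort[[i]]$image, file.path(dir, paste0(ids[i], "_T1w.nii.gz")))
    write_volume(volume(cohort[[i]]$labels + 0),
                 file.path(dir, paste0(ids[i], "_seg.nii.gz")))
    if (!is.null(save_fields))
      write_field(save_fields[[i]], file.path(dir, paste0(ids[i], "_field.nii.gz")))
  }
  man <- data.frame(id = ids, age = cond$age, sex = cond$sex, seed = cond$seed)
  path <- file.path(dir, "participants.tsv")
  write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a cohort manifest
#'
#' Validates columns and paths; sex accepts M/F aliases (mapped to 0/1
#' with a message).
#'
#' @param path a participants.tsv written by \code{\link{write_cohort}} (or
#'   compatible)
#' @return data.frame with columns id, image, labels, age, sex, seed
#' @export
load_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(man$age)) stop("manifest ages must be numeric")
  if (is.character(man$sex)) {
    message("mapping sex aliases M/F -> 0/1")
    man$sex <- c(M = 0, F = 1)[toupper(man$sex)]
  }
  if (!all(man$sex %in% c(0, 1))) stop("sex must be 0/1 (or M/F)")
  dir <- dirname(path)
  man$image <- file.path(dir, paste0(man$id, "_T1w.nii.gz"))
  man$labels <- file.path(dir, paste0(man$id, "_seg.nii.gz"))
  missing_img <- !file.exists(man$image)
  if (any(missing_img))
    stop("missing image file(s): ", paste(man$image[missing_img], collapse = ", "))
  man$labels[!file.exists(man$labels)] <- NA_character_
  man
}

# ---- configuration -----------------------------------------------------

default_run_config <- function(preset = c("desk32", "reference_full")) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = 0L,
    deterministic = TRUE,
    data = list(grid_shape = c(32L, 32L, 32L), n = 200L, sex_ratio = 0.5,
                age_range = c(5, 100), fold_amplitude = 0.06,
                noise_sd = 0.02, smoothing_sigma = 0.6),
    stage1 = list(alpha = 5, beta = 1, kl_weight = 1e-7,
                  adversarial_weight = 0.005, conditional = TRUE,
                  latent_channels = 8L, enc_widths = c(8L, 16L, 16L),
                  dec_widths = c(16L, 12L, 12L), lr = 1e-3,
                  epochs = 30L, batch_size = 8L),
    stage2 = list(T_steps = 100L, schedule_kind = "linear", steps = 2000L,
                  batch_size = 16L, lr = 1e-3, base_channels = 24L,
                  down_channels = 32L),
    eval = list(n_pairs = 1000L, n_generate = 50L, predictor_epochs = 12L)
  )
  if (preset == "reference_full") {
    cfg$data$grid_shape <- c(160L, 192L, 176L)
    cfg$data$n <- 27066L
    cfg$stage1$enc_widths <- c(64L, 128L, 128L)
    cfg$stage1$dec_widths <- c(128L, 128L, 64L)
    cfg$stage1$lr <- 1e-4
    cfg$stage2$T_steps <- 1000L
    cfg$stage2$base_channels <- 384L
    cfg$stage2$down_channels <- 512L
  }
  cfg
}

#' Resolve a run configuration
#'
#' Starts from a named preset, merges an optional YAML file, then applies
#' \code{key.path=value} overrides (applied after file load). Unknown keys
#' raise an error naming them.
#'
#' @param path optional YAML file
#' @param overrides character vector like \code{"stage1.alpha=2"}
#' @param preset \code{"desk32"} (default) or \code{"reference_full"}
#' @return the resolved config list, with a \code{hash} attribute
#' @export
resolve_config <- function(path = NULL, overrides = character(),
                           preset = "desk32") {
  cfg <- default_run_config(preset)
  merge_in <- function(base, extra, prefix = "") {
    for (k in names(extra)) {
      key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
      if (!k %in% names(base)) stop("unknown config key: ", key)
      base[[k]] <- if (is.list(extra[[k]]) && is.list(base[[k]]))
        merge_in(base[[k]], extra[[k]], key) else extra[[k]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key=value: ", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    node <- cfg
    for (k in keys) {
      if (!k %in% names(node)) stop("unknown config key: ", kv[1])
      node <- node[[k]]
    }
    cfg[[keys]] <- val
  }
  attr(cfg, "hash") <- content_hash(cfg)
  cfg
}

#' Deterministic content hash
#'
#' FNV-1a over the canonical serialization; stable across machines for
#' identical inputs.
#'
#' @param x any R object
#' @return an 8-hex-digit string
#' @export
content_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 3, xdr = TRUE)
  bytes <- bytes[-seq_len(14)]  # drop the encoding-dependent header
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  hi <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(h %% 65536))
}
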