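# Synthetic thoracic CT phantom with ground-truth label maps.
#
# The phantom is a stated world for testing the HU-window pipeline: a
# soft-tissue thorax ellipsoid containing two lung ellipsoids of aerated
# parenchyma, focal contusion blobs (GGO, optionally with consolidation
# cores), an anterior pleural air cap standing in for pneumothorax, and an
# optional pure-air airway column reaching the top of the volume. Tissue HU
# distributions are truncated so no voxel crosses a class threshold and the
# truth masks are unambiguous.

# Truncated-normal sampling by inverse CDF (deterministic under set.seed).
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Phantom configuration
#'
#' @param shape grid size `(nz, ny, nx)`, each at least (32, 64, 64).
#' @param spacing voxel spacing `(dz, dy, dx)` in mm.
#' @param target_contusion_fraction contusion volume as % of total lung,
#'   in \[0, 100\].
#' @param pneumothorax_fraction pleural air volume as % of total lung, in
#'   \[0, 50\].
#' @param contusion_texture `"ggo"` for pure ground-glass blobs or
#'   `"ggo+consolidation"` to add dense cores inside each blob.
#' @param hu_model per-tissue `(mean, sd)` HU plus truncation bounds; see
#'   `default_hu_model()`. Only the sides of the -950 / -450 thresholds
#'   matter for the pipeline; the defaults are conventional radiology values.
#' @param include_airway add a pure-air trachea column connected to the top
#'   face of the volume (exercises the airway-exclusion step).
#' @param seed RNG seed; a fixed seed makes the phantom bit-reproducible.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(96L, 128L, 128L),
                           spacing = c(2.5, 1.5, 1.5),
                           target_contusion_fraction = 25,
                           pneumothorax_fraction = 0,
                           contusion_texture = c("ggo+consolidation", "ggo"),
                           hu_model = default_hu_model(),
                           include_airway = TRUE,
                           seed = 1L) {
  contusion_texture <- match.arg(contusion_texture)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(32L, 64L, 64L)))
    cv_stop("cv_config_error", "grid must be at least 32 x 64 x 64 (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    cv_stop("cv_config_error", "spacing must be three positive values")
  if (target_contusion_fraction < 0 || target_contusion_fraction > 100)
    cv_stop("cv_config_error", "target_contusion_fraction must be in [0, 100]")
  if (pneumothorax_fraction < 0 || pneumothorax_fraction > 50)
    cv_stop("cv_config_error", "pneumothorax_fraction must be in [0, 50]")
  structure(list(
    shape = shape, spacing = spacing,
    target_contusion_fraction = target_contusion_fraction,
    pneumothorax_fraction = pneumothorax_fraction,
    contusion_texture = contusion_texture,
    hu_model = hu_model,
    include_airway = isTRUE(include_airway),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default per-tissue HU model
#'
#' Means/SDs with truncation bounds per tissue class. Aerated lung is
#' truncated to (-949, -451) so it sits strictly inside the normal-lung
#' window; pleural and airway air to at most -951 HU; ground-glass opacity
#' to (-449, -100); consolidation and soft tissue above -100 HU.
#' @return named list of `c(mean, sd, lo, hi)` vectors.
#' @export
default_hu_model <- function() {
  list(
    background    = c(mean = -1000, sd = 6,  lo = -1024, hi = -951),
    body          = c(mean = 40,    sd = 10, lo = -100,  hi = 200),
    aerated_lung  = c(mean = -750,  sd = 60, lo = -949,  hi = -451),
    ggo           = c(mean = -300,  sd = 80, lo = -449,  hi = -100),
    consolidation = c(mean = 20,    sd = 30, lo = -99,   hi = 150),
    pleural_air   = c(mean = -990,  sd = 8,  lo = -1024, hi = -951),
    airway_air    = c(mean = -1000, sd = 6,  lo = -1024, hi = -951)
  )
}

draw_hu <- function(model, class, n) {
  p <- model[[class]]
  rtrunc_norm(n, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]])
}

#' Generate a thoracic CT phantom with ground truth
#'
#' Builds the phantom described in [phantom_config()] and returns the CT
#' volume together with exact truth masks. The truth masks partition the
#' total lung: `normal_lung`, `contusion` and `pneumothorax` are pairwise
#' disjoint and union to `total_lung`. The contusion is accreted from
#' random ellipsoidal blobs (posterior-biased, mimicking gravity-dependent
#' distribution) and the last blob is trimmed from its rim inward, so the
#' achieved fraction matches the target to well under one percentage point.
#'
#' @param config a [phantom_config()].
#' @return A `phantom_truth` list: `ct` ([ct_volume()]), masks `total_lung`,
#'   `normal_lung`, `contusion`, `pneumothorax` ([mask_volume()]), and
#'   `achieved` (percent fractions measured on the truth masks).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  d <- config$shape; sp <- config$spacing
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  L <- d * sp
  cz <- L[1] / 2; cy <- L[2] / 2; cx <- L[3] / 2
  zmm <- (seq_len(nz) - 0.5) * sp[1]
  ymm <- (seq_len(ny) - 0.5) * sp[2]
  xmm <- (seq_len(nx) - 0.5) * sp[3]
  Z <- array(rep(zmm, times = ny * nx), dim = d)
  Y <- array(rep(rep(ymm, each = nz), times = nx), dim = d)
  X <- array(rep(xmm, each = nz * ny), dim = d)

  model <- config$hu_model
  hu <- array(draw_hu(model, "background", prod(d)), dim = d)

  body_semi <- c(0.48, 0.44, 0.47) * L
  body <- ((Z - cz) / body_semi[1])^2 + ((Y - cy) / body_semi[2])^2 +
          ((X - cx) / body_semi[3])^2 <= 1
  hu[body] <- draw_hu(model, "body", sum(body))

  lung_semi <- c(0.36 * L[1], 0.27 * L[2], 0.16 * L[3])
  lung_off <- 0.23 * L[3]
  eqL <- ((Z - cz) / lung_semi[1])^2 + ((Y - cy) / lung_semi[2])^2 +
         ((X - (cx - lung_off)) / lung_semi[3])^2
  eqR <- ((Z - cz) / lung_semi[1])^2 + ((Y - cy) / lung_semi[2])^2 +
         ((X - (cx + lung_off)) / lung_semi[3])^2
  lung <- (eqL <= 1) | (eqR <= 1)
  hu[lung] <- draw_hu(model, "aerated_lung", sum(lung))

  if (config$include_airway) {
    aw_r <- 0.045 * L[3]
    airway <- ((Y - cy)^2 + (X - cx)^2 <= aw_r^2) & (Z <= cz) & !lung
    hu[airway] <- draw_hu(model, "airway_air", sum(airway))
  }

  n_lung <- sum(lung)
  lung_idx <- which(lung)
  Zv <- Z[lung_idx]; Yv <- Y[lung_idx]; Xv <- X[lung_idx]

  # pneumothorax: anterior (low y) cap of the right lung, exact voxel count
  ptx_v <- logical(n_lung)
  n_ptx <- round(config$pneumothorax_fraction / 100 * n_lung)
  if (n_ptx > 0) {
    right <- which(Xv > cx)
    if (n_ptx > 0.95 * length(right))
      cv_stop("cv_config_error",
              "pneumothorax fraction unreachable; best achievable about %.1f%%",
              95 * length(right) / n_lung)
    ord <- right[order(Yv[right], right)]
    ptx_v[ord[seq_len(n_ptx)]] <- TRUE
  }

  # contusion: accrete random posterior-biased ellipsoid blobs
  cont_v <- logical(n_lung)
  core_v <- logical(n_lung)
  n_target <- round(config$target_contusion_fraction / 100 * n_lung)
  avail_max <- sum(!ptx_v)
  if (n_target > avail_max)
    cv_stop("cv_config_error",
            "contusion fraction unreachable with %.1f%% pneumothorax; best achievable %.1f%%",
            config$pneumothorax_fraction, 100 * avail_max / n_lung)
  if (n_target > 0) {
    w <- exp(1.5 * (Yv - cy) / (L[2] / 2))
    blob_count <- 0L
    while (sum(cont_v) < n_target) {
      blob_count <- blob_count + 1L
      if (blob_count > 1000L)
        cv_stop("cv_config_error", "contusion accretion failed to reach target")
      ctr <- sample.int(n_lung, 1L, prob = w)
      semi <- c(runif(1, 10, 28), runif(1, 10, 28), runif(1, 10, 28))
      eq <- ((Zv - Zv[ctr]) / semi[1])^2 + ((Yv - Yv[ctr]) / semi[2])^2 +
            ((Xv - Xv[ctr]) / semi[3])^2
      new <- which(eq <= 1 & !cont_v & !ptx_v)
      if (length(new) == 0L) next
      room <- n_target - sum(cont_v)
      if (length(new) > room) {
        new <- new[order(eq[new], new)][seq_len(room)]   # trim rim inward
      }
      cont_v[new] <- TRUE
      core_v[new[eq[new] <= 0.2]] <- TRUE
    }
  }

  n_cont <- sum(cont_v)
  if (n_cont > 0) {
    cont_idx <- lung_idx[cont_v]
    hu[cont_idx] <- draw_hu(model, "ggo", n_cont)
    if (config$contusion_texture == "ggo+consolidation" && any(core_v)) {
      core_idx <- lung_idx[core_v]
      hu[core_idx] <- draw_hu(model, "consolidation", length(core_idx))
    }
  }
  if (n_ptx > 0) {
    hu[lung_idx[ptx_v]] <- draw_hu(model, "pleural_air", n_ptx)
  }

  to_mask <- function(v) {
    m <- array(FALSE, dim = d)
    m[lung_idx[v]] <- TRUE
    mask_volume(m, sp)
  }
  normal_v <- !cont_v & !ptx_v
  structure(list(
    ct = ct_volume(hu, sp),
    total_lung = mask_volume(lung, sp),
    normal_lung = to_mask(normal_v),
    contusion = to_mask(cont_v),
    pneumothorax = to_mask(ptx_v),
    achieved = list(
      contusion_fraction = 100 * n_cont / n_lung,
      pneumothorax_fraction = 100 * n_ptx / n_lung,
      total_lung_ml = n_lung * prod(sp) / 1000
    ),
    config = config
  ), class = "phantom_truth")
}

#' Generate a grid of phantoms
#'
#' Cartesian product of seeds and target contusion fractions, sharing all
#' other settings from `base`.
#'
#' @param seeds integer vector of RNG seeds.
#' @param fractions numeric vector of target contusion fractions (%).
#' @param base a [phantom_config()] supplying every other parameter.
#' @return list of `phantom_truth`, ordered fractions-within-seed.
#' @export
phantom_suite <- function(seeds, fractions,
                          base = phantom_config()) {
  out <- list()
  for (s in seeds) {
    for (f in fractions) {
      cfg <- base
      cfg$seed <- as.integer(s)
      cfg$target_contusion_fraction <- f
      out[[length(out) + 1L]] <- generate_phantom(cfg)
    }
  }
  out
}

#' Write a phantom and its truth masks to disk
#'
#' CT as float NIfTI, masks as uint8 NIfTI, plus a JSON manifest echoing
#' the configuration and the achieved fractions.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_phantom <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_ct(truth$ct, file.path(dir, "ct.nii.gz"))
  for (m in c("total_lung", "normal_lung", "contusion", "pneumothorax"))
    save_mask(truth[[m]], file.path(dir, paste0(m, ".nii.gz")))
  manifest <- list(
    config = truth$config[setdiff(names(truth$config), "hu_model")],
    hu_model = truth$config$hu_model,
    achieved = truth$achieved
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: grid %s, total lung %.0f mL, contusion %.2f%%, pneumothorax %.2f%%\n",
              paste(x$config$shape, collapse = "x"),
              x$achieved$total_lung_ml,
              x$achieved$contusion_fraction,
              x$achieved$pneumothorax_fraction))
  invisible(x)
}
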