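#' Specify a synthetic head-CT phantom
#'
#' Describes a synthetic non-contrast head CT with known ground truth: an
#' ellipsoidal cranial cavity of parenchyma-density noise enclosed by a
#' high-density skull shell and surrounded by air, containing one or more
#' hyperdense lesions with irregular boundaries. Lesions can carry internal
#' hypodense pockets (heterogeneous clot, still labelled lesion, matching the
#' convention of annotating the complete haemorrhage volume) and linear
#' streak artefacts crossing them (beam-hardening look-alikes).
#'
#' Default appearance values are typical acute NCCT: fresh blood 50-90 HU,
#' parenchyma ~35 HU with ~5 HU texture, skull ~1000 HU, air -1000 HU,
#' ~4 HU acquisition noise, modest streaks (15 HU). The default grid is
#' 96x96x96 voxels at 0.43 x 0.43 x 0.5 mm — large enough to hold one
#' minimal 92^3 network input while staying CPU-friendly; lesion volumes of
#' 1-4 mL are proportionate to that reduced field of view.
#'
#' @param grid_shape voxel triple.
#' @param spacing mm triple (default Radboudumc-like 0.43 x 0.43 x 0.5).
#' @param n_lesions number of lesions (>= 0; 0 gives a negative control).
#' @param lesion_volume_range mL interval from which each lesion's target
#'   volume is drawn.
#' @param lesion_hu_range HU interval for lesion voxels (before noise,
#'   pockets and streaks).
#' @param parenchyma_hu length-2 vector (mean, sd) of brain-tissue HU.
#' @param skull_hu skull shell HU.
#' @param heterogeneity fraction of lesion voxels replaced by hypodense
#'   pockets (ground-truth label remains lesion).
#' @param streak_amplitude HU amplitude of linear streak artefacts crossing
#'   each lesion; 0 disables them.
#' @param noise_std HU standard deviation of global acquisition noise.
#' @param cavity_centre_jitter per-axis cavity centre offset as a fraction of
#'   the grid (uniform in +/- the value). Real heads are only approximately
#'   centred in the scanner field of view; without this variation a cohort of
#'   identically centred phantoms would let a segmentation model exploit
#'   position instead of appearance.
#' @param cavity_axes_jitter relative per-axis variation of the cavity
#'   semi-axes (uniform in +/- the value): head-size variation.
#' @param seed RNG seed; identical seed + spec give a voxel-identical phantom.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 96L),
                         spacing = c(0.43, 0.43, 0.5),
                         n_lesions = 1L,
                         lesion_volume_range = c(1, 4),
                         lesion_hu_range = c(50, 90),
                         parenchyma_hu = c(mean = 35, sd = 5),
                         skull_hu = 1000,
                         heterogeneity = 0.15,
                         streak_amplitude = 15,
                         noise_std = 4,
                         cavity_centre_jitter = 0.04,
                         cavity_axes_jitter = 0.08,
                         seed = 1L) {
  grid_shape <- as.integer(check_triple(grid_shape, "grid_shape"))
  spacing <- check_triple(spacing, "spacing")
  if (!is_count(n_lesions, min = 0L)) stopf("n_lesions must be a count >= 0")
  if (length(lesion_volume_range) != 2L || diff(lesion_volume_range) < 0 ||
      lesion_volume_range[1] <= 0)
    stopf("lesion_volume_range must be a non-empty positive mL interval")
  if (length(lesion_hu_range) != 2L || diff(lesion_hu_range) <= 0)
    stopf("lesion_hu_range must be a non-empty HU interval")
  if (heterogeneity < 0 || heterogeneity > 0.5)
    stopf("heterogeneity must be in [0, 0.5]")
  spec <- list(grid_shape = grid_shape, spacing = spacing,
               n_lesions = as.integer(n_lesions),
               lesion_volume_range = as.numeric(lesion_volume_range),
               lesion_hu_range = as.numeric(lesion_hu_range),
               parenchyma_hu = as.numeric(parenchyma_hu),
               skull_hu = skull_hu, heterogeneity = heterogeneity,
               streak_amplitude = streak_amplitude, noise_std = noise_std,
               cavity_centre_jitter = cavity_centre_jitter,
               cavity_axes_jitter = cavity_axes_jitter,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  # feasibility: lesions must fit the eroded cavity with room to spare
  voxvol <- prod(spacing)
  cav_vox <- 4 / 3 * pi * prod(0.36 * grid_shape)
  need <- n_lesions * lesion_volume_range[2] * 1000 / voxvol
  if (n_lesions > 0 && need > 0.35 * cav_vox)
    stopf("requested lesion volume (%.1f mL max total) exceeds what the cavity can hold",
          n_lesions * lesion_volume_range[2])
  spec
}

# Separable Gaussian smoothing of a 3D array (small boxes only).
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    n <- d[ax]
    if (sigma[ax] <= 0 || n < 3) next
    u <- seq_len(n)
    K <- exp(-outer(u, u, "-")^2 / (2 * sigma[ax]^2))
    K <- K / rowSums(K)
    m <- matrix(aperm(a, c(ax, setdiff(1:3, ax))), n)
    m <- K %*% m
    a <- aperm(array(m, c(n, d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  a
}

#' Generate a synthetic head-CT phantom
#'
#' Builds the CT image plus its two ground-truth masks. Lesion shapes come
#' from thresholding a smoothed Gaussian random field superimposed on an
#' ellipsoidal falloff, which yields the irregular boundaries and internal
#' heterogeneity characteristic of real haematomas; the top-K field voxels
#' are taken so the mask voxel count matches the requested volume exactly.
#' The haemorrhage mask marks exactly the lesion voxels (pockets included);
#' the cavity mask marks the intracranial region and is disjoint from the
#' skull shell.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list of class \code{phantom} with elements \code{image}
#'   (\code{\link{ct_volume}}, HU), \code{cavity} and \code{ich}
#'   (\code{\link{label_volume}}), and \code{meta} (per-lesion target and
#'   achieved volumes in mL).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    d <- spec$grid_shape
    voxvol <- prod(spec$spacing)
    ctr <- (d + 1) / 2 + runif(3, -1, 1) * spec$cavity_centre_jitter * d
    semi <- 0.39 * d * (1 + runif(3, -1, 1) * spec$cavity_axes_jitter)
    # normalized squared ellipsoid radius on the full grid, by outer sums
    r2ax <- lapply(1:3, function(a) ((seq_len(d[a]) - ctr[a]) / semi[a])^2)
    r2 <- outer(outer(r2ax[[1]], r2ax[[2]], "+"), r2ax[[3]], "+")
    cavity <- r2 <= 1
    r2o <- outer(outer(((seq_len(d[1]) - ctr[1]) / (semi[1] + 3))^2,
                       ((seq_len(d[2]) - ctr[2]) / (semi[2] + 3))^2, "+"),
                 ((seq_len(d[3]) - ctr[3]) / (semi[3] + 3))^2, "+")
    skull <- (r2o <= 1) & !cavity

    hu <- array(-1000, d)
    hu[skull] <- spec$skull_hu
    hu[cavity] <- rnorm(sum(cavity), spec$parenchyma_hu[1], spec$parenchyma_hu[2])

    ich <- array(FALSE, d)
    meta <- list(target_ml = numeric(0), achieved_ml = numeric(0))
    eroded <- r2 <= 0.75^2     # lesions stay well inside the cavity
    for (l in seq_len(spec$n_lesions)) {
      target_ml <- runif(1, spec$lesion_volume_range[1], spec$lesion_volume_range[2])
      K <- max(1L, round(target_ml * 1000 / voxvol))
      # equivalent-sphere radius in mm -> anisotropic semi-axes in voxels
      r_mm <- (3 * target_ml * 1000 / (4 * pi))^(1 / 3)
      jit <- runif(3, 0.75, 1.35)
      jit <- jit / prod(jit)^(1 / 3)
      semi_vox <- r_mm * jit / spec$spacing
      # centre: a random voxel of the eroded cavity with box margin; an
      # unlucky centre (box clipped by earlier lesions or the cavity edge)
      # is redrawn a few times before the volume is declared infeasible
      half <- pmin(ceiling(semi_vox * 1.7) + 3, (d - 1) %/% 2)
      ok <- which(eroded)
      bd <- half * 2L + 1L
      for (attempt in 1:8) {
        co <- arrayInd(sample(ok, 1), d)
        co <- pmin(pmax(as.integer(co), half + 1L), d - half)
        rng <- lapply(1:3, function(a) (co[a] - half[a]):(co[a] + half[a]))
        ell <- outer(outer(((rng[[1]] - co[1]) / semi_vox[1])^2,
                           ((rng[[2]] - co[2]) / semi_vox[2])^2, "+"),
                     ((rng[[3]] - co[3]) / semi_vox[3])^2, "+")
        noise <- gauss_smooth3(array(rnorm(prod(bd)), bd), semi_vox / 3)
        noise <- (noise - mean(noise)) / (sd(noise) + 1e-12)
        field <- (1 - ell) + 0.45 * noise
        inside <- eroded[rng[[1]], rng[[2]], rng[[3]]] &
          !ich[rng[[1]], rng[[2]], rng[[3]]]
        field[!inside] <- -Inf
        if (sum(is.finite(field)) >= K) break
      }
      if (sum(is.finite(field)) < K)
        stopf("lesion %d: requested volume (%.2f mL) exceeds available cavity space",
              l, target_ml)
      sel <- field >= sort(field, decreasing = TRUE)[K]
      sel <- sel & is.finite(field)
      # smooth intra-lesion HU variation, clipped to lesion_hu_range
      lo <- spec$lesion_hu_range[1]; hi <- spec$lesion_hu_range[2]
      w <- hi - lo
      base <- runif(1, lo + 0.3 * w, hi - 0.3 * w)
      tex <- gauss_smooth3(array(rnorm(prod(bd)), bd), semi_vox / 4)
      tex <- (tex - mean(tex)) / (sd(tex) + 1e-12)
      huv <- pmin(pmax(base + 0.25 * w * tex[sel], lo), hi)
      sub <- ich[rng[[1]], rng[[2]], rng[[3]]]
      sub[sel] <- TRUE
      ich[rng[[1]], rng[[2]], rng[[3]]] <- sub
      hsub <- hu[rng[[1]], rng[[2]], rng[[3]]]
      hsub[sel] <- huv

      meta$target_ml <- c(meta$target_ml, target_ml)
      meta$achieved_ml <- c(meta$achieved_ml, sum(sel) * voxvol / 1000)

      # hypodense heterogeneity pockets: label stays lesion
      if (spec$heterogeneity > 0) {
        M <- round(spec$heterogeneity * sum(sel))
        if (M > 0) {
          pf <- gauss_smooth3(array(rnorm(prod(bd)), bd), semi_vox / 5)
          pf[!sel] <- -Inf
          psel <- pf >= sort(pf[sel], decreasing = TRUE)[M]
          psel <- psel & sel
          hsub[psel] <- runif(sum(psel), 18, 32)
        }
      }
      hu[rng[[1]], rng[[2]], rng[[3]]] <- hsub
      # linear streak artefact crossing the lesion in the axial plane
      if (spec$streak_amplitude > 0) {
        phi <- runif(1, 0, pi)
        zr <- range(which(apply(sel, 3, any)))
        gx <- matrix(rng[[1]], bd[1], bd[2])
        gy <- matrix(rep(rng[[2]], each = bd[1]), bd[1], bd[2])
        dist <- abs((gx - co[1]) * sin(phi) - (gy - co[2]) * cos(phi))
        bump <- spec$streak_amplitude * exp(-(dist / 1.2)^2)
        for (z in rng[[3]][zr[1]:zr[2]]) {
          in_cav <- cavity[rng[[1]], rng[[2]], z]
          sl <- hu[rng[[1]], rng[[2]], z]
          sl[in_cav] <- sl[in_cav] + bump[in_cav]
          hu[rng[[1]], rng[[2]], z] <- sl
        }
      }
    }
    if (spec$noise_std > 0) hu <- hu + rnorm(length(hu), 0, spec$noise_std)

    structure(list(
      image = ct_volume(hu, spec$spacing),
      cavity = label_volume(cavity, spec$spacing, role = "cranial_cavity"),
      ich = label_volume(ich, spec$spacing, role = "ich"),
      meta = meta, spec = spec), class = "phantom")
  })
}

#' Generate a reproducible cohort of phantoms
#'
#' Each case jitters the template's lesion count (+/- 1, floor 1 when the
#' template has lesions), lesion volume range (x0.8-1.25) and heterogeneity
#' (x0.5-1.5), with per-case seeds derived from \code{seed}.
#'
#' @param n number of phantoms (>= 1).
#' @param spec_template a \code{\link{phantom_spec}} used as the base.
#' @param seed cohort-level RNG seed.
#' @return List of \code{n} phantoms (see \code{\link{generate_phantom}}).
#' @export
phantom_cohort <- function(n, spec_template = phantom_spec(), seed = 1L) {
  if (!is_count(n)) stopf("phantom_cohort: n must be a count >= 1")
  seeds <- derive_seeds(seed, 3L * n)
  lapply(seq_len(n), function(i) {
    s <- spec_template
    with_seed(seeds[3L * i - 2L], {
      if (s$n_lesions > 0)
        s$n_lesions <- max(1L, s$n_lesions + sample(c(-1L, 0L, 1L), 1))
      s$lesion_volume_range <- s$lesion_volume_range * runif(1, 0.8, 1.25)
      s$heterogeneity <- min(0.5, s$heterogeneity * runif(1, 0.5, 1.5))
    })
    # keep the jittered request inside what the cavity can hold (same bound
    # as the phantom_spec feasibility check)
    cap <- 0.35 * 4 / 3 * pi * prod(0.36 * s$grid_shape) *
      prod(s$spacing) / 1000
    if (s$n_lesions > 0 && s$n_lesions * s$lesion_volume_range[2] > cap)
      s$lesion_volume_range <- s$lesion_volume_range *
        (cap / (s$n_lesions * s$lesion_volume_range[2]))
    s$seed <- seeds[3L * i]
    generate_phantom(s)
  })
}

#' Write a phantom to disk as NIfTI files plus a JSON sidecar
#'
#' Writes \code{<prefix>_image.nii.gz}, \code{<prefix>_cavity.nii.gz},
#' \code{<prefix>_ich.nii.gz} and \code{<prefix>_meta.json} (the generating
#' spec and true lesion volumes).
#'
#' @param ph a \code{phantom}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_phantom <- function(ph, dir, prefix = "phantom") {
  stopifnot(inherits(ph, "phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(prefix, "_image.nii.gz")),
             cavity = file.path(dir, paste0(prefix, "_cavity.nii.gz")),
             ich = file.path(dir, paste0(prefix, "_ich.nii.gz")),
             meta = file.path(dir, paste0(prefix, "_meta.json")))
  write_volume(ph$image, paths["image"])
  write_volume(ph$cavity, paths["cavity"])
  write_volume(ph$ich, paths["ich"])
  jsonlite::write_json(list(spec = unclass(ph$spec), meta = ph$meta),
                       paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
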