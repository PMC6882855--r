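#' Training configuration
#'
#' Defaults follow the reference training scheme: stochastic gradient
#' descent with learning rate 1e-3 and Nesterov momentum 0.9, 50000 training
#' patches, augmentation probability 0.5 with axial rotations in
#' [-15, 15] degrees, and 124^3 input tiles. \code{batch_size} defaults to a
#' single tile per update step. Reduced profiles for CPU-scale runs shrink
#' \code{n_patches}, \code{input_shape} and the network's
#' \code{base_filters} — not the optimization scheme.
#'
#' @param learning_rate SGD learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param n_patches total training patches.
#' @param augment_probability probability a sampled patch is augmented.
#' @param rotation_range degrees interval for axial-plane rotation.
#' @param batch_size tiles per parameter update.
#' @param seed RNG seed controlling sampling, augmentation, dropout and
#'   weight initialization.
#' @param validation_interval patches between validation evaluations.
#' @param patience validation evaluations without improvement before early
#'   stopping (default \code{Inf}: never stop early).
#' @param restore_best if \code{TRUE} and validation cases are supplied, the
#'   returned model carries the weights of the best validation evaluation
#'   rather than the last step — useful for short schedules whose endpoint
#'   is noisy, and the mechanism behind staged fine-tuning protocols.
#' @param input_shape network input tile shape (must be valid for the spec).
#' @return A \code{train_config} list.
#' @export
train_config <- function(learning_rate = 1e-3, momentum = 0.9,
                         n_patches = 50000L, augment_probability = 0.5,
                         rotation_range = c(-15, 15), batch_size = 1L,
                         seed = 1L, validation_interval = 1000L,
                         patience = Inf, restore_best = FALSE,
                         input_shape = c(124L, 124L, 124L)) {
  if (augment_probability < 0 || augment_probability > 1)
    stopf("augment_probability must be in [0, 1]")
  if (!is_count(n_patches)) stopf("n_patches must be a positive count")
  if (!is_count(batch_size)) stopf("batch_size must be a positive count")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 n_patches = as.integer(n_patches),
                 augment_probability = augment_probability,
                 rotation_range = as.numeric(rotation_range),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 validation_interval = as.integer(validation_interval),
                 patience = patience, restore_best = isTRUE(restore_best),
                 input_shape = as.integer(check_triple(input_shape, "input_shape"))),
            class = "train_config")
}

#' Sample a patch centre with balanced classes
#'
#' With probability 1/2 a uniformly random haemorrhage voxel, otherwise a
#' uniformly random cranial-cavity voxel outside the haemorrhage mask. If the
#' haemorrhage mask is empty every centre is background. Draws from the
#' current RNG stream.
#'
#' @param ich haemorrhage \code{\link{label_volume}}.
#' @param cavity cranial-cavity \code{\link{label_volume}} (must be
#'   non-empty).
#' @param force_class optional \code{"fg"} or \code{"bg"}: draw the centre
#'   from that class instead of tossing the coin. Used by \code{\link{train}}
#'   to realize the 50/50 balance as an exact alternating quota rather than
#'   per-patch coin flips (the coordinates within the class remain uniformly
#'   random either way).
#' @return Integer voxel coordinate (x, y, z).
#' @export
sample_centre <- function(ich, cavity, force_class = NULL) {
  stopifnot(inherits(ich, "label_volume"), inherits(cavity, "label_volume"))
  fg <- which(ich$data == 1)
  bg <- which(cavity$data == 1 & ich$data == 0)
  if (length(bg) == 0 && length(fg) == 0)
    stopf("sample_centre: empty cranial cavity")
  use_fg <- if (is.null(force_class)) runif(1) < 0.5 else force_class == "fg"
  use_fg <- use_fg && length(fg) > 0
  pool <- if (use_fg) fg else bg
  if (length(pool) == 0) pool <- c(fg, bg)
  as.integer(arrayInd(pool[sample.int(length(pool), 1L)], dim(ich$data)))
}

# Gather an axial-plane-transformed tile from a source volume.
# sx, sy: matrices (nx x ny) of fractional source coordinates shared by all
# slices; zs: source z index per tile slice. Out-of-volume samples are 0.
gather_plane <- function(data, sx, sy, zs, nearest) {
  d <- dim(data)
  nx <- nrow(sx); ny <- ncol(sx); nz <- length(zs)
  out <- array(0, c(nx, ny, nz))
  zok <- zs >= 1L & zs <= d[3]
  if (!any(zok)) return(out)
  if (nearest) {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    ix <- pmin(pmax(ix, 1), d[1]); iy <- pmin(pmax(iy, 1), d[2])
    lin <- ix + (iy - 1) * d[1]
    for (z in which(zok)) {
      v <- data[(zs[z] - 1) * d[1] * d[2] + lin]
      v[!ok] <- 0
      out[, , z] <- v
    }
  } else {
    ok <- sx >= 1 & sx <= d[1] & sy >= 1 & sy <= d[2]
    i0 <- pmin(pmax(floor(sx), 1), d[1] - 1); fx <- sx - i0
    j0 <- pmin(pmax(floor(sy), 1), d[2] - 1); fy <- sy - j0
    l00 <- i0 + (j0 - 1) * d[1]
    w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
    w01 <- (1 - fx) * fy; w11 <- fx * fy
    for (z in which(zok)) {
      off <- (zs[z] - 1) * d[1] * d[2]
      v <- w00 * data[off + l00] + w10 * data[off + l00 + 1] +
        w01 * data[off + l00 + d[1]] + w11 * data[off + l00 + d[1] + 1]
      v[!ok] <- 0
      out[, , z] <- v
    }
  }
  out
}

#' Extract a receptive-field-matched training patch
#'
#' Cuts a network-input-sized image tile and the concentric
#' output-shape-sized label tile around \code{centre}. Out-of-volume image
#' voxels are zero-filled (normalized air); out-of-volume label voxels are
#' background. An axial-plane rotation or left-right mirror can be applied at
#' extraction time: the sampling grid itself is transformed, so rotated
#' interior tiles contain no synthetic corner padding. Images are
#' interpolated bilinearly in-plane, labels by nearest neighbour.
#'
#' @param vol normalized \code{\link{ct_volume}}.
#' @param ich haemorrhage \code{\link{label_volume}} on the same grid.
#' @param centre voxel coordinate (x, y, z).
#' @param spec \code{\link{network_spec}} (fixes the label-tile shape and the
#'   44-voxel margin of the default 124 -> 36 geometry).
#' @param input_shape input tile shape (default from \code{spec}: 124^3 must
#'   be valid for it).
#' @param angle axial rotation in degrees (0 = none).
#' @param mirror logical; left-right mirror in the axial plane.
#' @return A \code{training_patch}: \code{image_tile}, \code{label_tile},
#'   \code{weight_tile} (NULL until \code{\link{make_weight_map}}),
#'   \code{centre}, \code{margin}, \code{augmented}.
#' @export
extract_patch <- function(vol, ich, centre, spec,
                          input_shape = c(124L, 124L, 124L),
                          angle = 0, mirror = FALSE) {
  stopifnot(inherits(vol, "ct_volume"), inherits(ich, "label_volume"),
            inherits(spec, "network_spec"))
  if (!vol$normalized)
    stopf("extract_patch: volume must be normalized (see normalize_hu)")
  d <- dim(vol$data)
  centre <- as.integer(check_triple(centre, "centre", positive = FALSE))
  if (any(centre < 1L) || any(centre > d))
    stopf("extract_patch: centre outside the volume")
  input_shape <- as.integer(check_triple(input_shape, "input_shape"))
  out_shape <- output_shape(spec, input_shape)
  margin <- (input_shape - out_shape)
  if (any(margin %% 2L != 0L))
    stopf("extract_patch: input/output difference must be even per axis")
  margin <- margin %/% 2L

  start_img <- centre - input_shape %/% 2L
  start_lab <- start_img + margin
  qx <- start_img[1] + seq_len(input_shape[1]) - 1L
  qy <- start_img[2] + seq_len(input_shape[2]) - 1L
  zs_img <- start_img[3] + seq_len(input_shape[3]) - 1L
  lx <- start_lab[1] + seq_len(out_shape[1]) - 1L
  ly <- start_lab[2] + seq_len(out_shape[2]) - 1L
  zs_lab <- start_lab[3] + seq_len(out_shape[3]) - 1L

  transform <- function(px, py) {
    if (mirror) px <- 2 * centre[1] - px
    if (angle != 0) {
      th <- angle * pi / 180
      ux <- px - centre[1]; uy <- py - centre[2]
      list(sx = outer(centre[1] + cos(th) * ux, -sin(th) * uy, "+"),
           sy = outer(sin(th) * ux, centre[2] + cos(th) * uy, "+"))
    } else {
      list(sx = matrix(px, length(px), length(py)),
           sy = matrix(rep(py, each = length(px)), length(px), length(py)))
    }
  }
  ti <- transform(qx, qy)
  tl <- transform(lx, ly)
  nearest_img <- (angle == 0)   # pure crop/mirror needs no interpolation
  image_tile <- gather_plane(vol$data, ti$sx, ti$sy, zs_img, nearest = nearest_img)
  label_tile <- gather_plane(ich$data, tl$sx, tl$sy, zs_lab, nearest = TRUE)

  structure(list(image_tile = image_tile, label_tile = label_tile,
                 weight_tile = NULL, centre = centre,
                 input_shape = input_shape, output_shape = out_shape,
                 margin = margin, augmented = (mirror || angle != 0),
                 angle = angle, mirror = mirror, spec = spec),
            class = "training_patch")
}

#' Class-balancing weight map for one label tile
#'
#' Let F be the foreground voxel count and N the tile size. If F = 0 (pure
#' background) or F > N/2, all weights are 1. Otherwise weight 1 is assigned
#' to every foreground voxel and to F background voxels sampled uniformly
#' without replacement, 0 elsewhere — so exactly 2F voxels contribute to the
#' loss, balanced between classes. Draws from the current RNG stream.
#'
#' @param label_tile binary 3D array.
#' @return \{0, 1\} array of the same shape.
#' @export
make_weight_map <- function(label_tile) {
  if (!all(label_tile %in% c(0, 1)))
    stopf("make_weight_map: label tile must be binary")
  N <- length(label_tile)
  F <- sum(label_tile)
  if (F == 0 || F > N / 2) return(array(1, dim(label_tile)))
  w <- array(0, dim(label_tile))
  w[label_tile == 1] <- 1
  bg <- which(label_tile == 0)
  w[bg[sample.int(length(bg), F)]] <- 1
  w
}

#' Augment a training patch
#'
#' With probability \code{cfg$augment_probability} the patch is transformed:
#' a fair choice between a left-right mirror in the axial plane and an axial
#' rotation by a uniform angle from \code{cfg$rotation_range}. The identical
#' transform is applied to image and label (bilinear / nearest-neighbour);
#' the weight map is rebuilt afterwards rather than warped, preserving the
#' exact 2F count law. When the source volumes are supplied the rotated
#' patch is re-extracted through a rotated sampling grid, avoiding synthetic
#' zero corners inside interior tiles.
#'
#' @param patch an unaugmented \code{training_patch}.
#' @param cfg a \code{\link{train_config}}.
#' @param vol,ich optional source volumes for re-extraction.
#' @return A \code{training_patch} (possibly unchanged), with
#'   \code{weight_tile} set.
#' @export
augment <- function(patch, cfg, vol = NULL, ich = NULL) {
  stopifnot(inherits(patch, "training_patch"), inherits(cfg, "train_config"))
  if (patch$augmented) stopf("augment: patch is already augmented")
  if (runif(1) < cfg$augment_probability) {
    if (runif(1) < 0.5) {            # mirror: exact axis flip, no resampling
      nx <- dim(patch$image_tile)[1]
      patch$image_tile <- patch$image_tile[nx:1, , , drop = FALSE]
      nl <- dim(patch$label_tile)[1]
      patch$label_tile <- patch$label_tile[nl:1, , , drop = FALSE]
      patch$mirror <- TRUE
    } else {
      ang <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
      if (!is.null(vol) && !is.null(ich)) {
        patch2 <- extract_patch(vol, ich, patch$centre, patch$spec,
                                input_shape = patch$input_shape, angle = ang)
        patch$image_tile <- patch2$image_tile
        patch$label_tile <- patch2$label_tile
      } else {
        patch$image_tile <- rotate_tile(patch$image_tile, ang, nearest = FALSE)
        patch$label_tile <- rotate_tile(patch$label_tile, ang, nearest = TRUE)
      }
      patch$angle <- ang
    }
    patch$augmented <- TRUE
  }
  patch$weight_tile <- make_weight_map(patch$label_tile)
  patch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# In-place axial rotation of a tile about its own centre (zero fill).
rotate_tile <- function(tile, angle, nearest) {
  d <- dim(tile)
  c1 <- (d[1] + 1) / 2; c2 <- (d[2] + 1) / 2
  th <- angle * pi / 180
  ux <- seq_len(d[1]) - c1; uy <- seq_len(d[2]) - c2
  sx <- outer(c1 + cos(th) * ux, -sin(th) * uy, "+")
  sy <- outer(sin(th) * ux, c2 + cos(th) * uy, "+")
  gather_plane(tile, sx, sy, seq_len(d[3]), nearest = nearest)
}

#' Weighted categorical cross-entropy
#'
#' \eqn{L = \sum_v w_v (-\log p_{true,v}) / \sum_v w_v}: voxels with zero
#' weight contribute nothing to the loss or its gradient.
#'
#' @param probs 4D array of per-voxel class probabilities (background, ICH).
#' @param label_tile binary 3D array of the same spatial shape.
#' @param weight_tile \{0, 1\} array of the same spatial shape.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probs, label_tile, weight_tile) {
  sw <- sum(weight_tile)
  if (sw == 0) stopf("weighted_cross_entropy: all weights are zero")
  p_true <- channel(probs, 2) * label_tile + channel(probs, 1) * (1 - label_tile)
  sum(weight_tile * -log(pmax(p_true, 1e-12))) / sw
}

# Fused softmax + weighted CE gradient w.r.t. logits.
ce_grad <- function(probs, label_tile, weight_tile) {
  sw <- sum(weight_tile)
  d <- dim(probs)
  dl <- array(0, d)
  dl[, , , 1] <- weight_tile * (channel(probs, 1) - (1 - label_tile)) / sw
  dl[, , , 2] <- weight_tile * (channel(probs, 2) - label_tile) / sw
  dl
}

#' Train the segmentation network
#'
#' Patch-based stochastic gradient descent with Nesterov momentum. Each
#' step samples a case uniformly, draws a class-balanced centre, extracts a
#' receptive-field-matched patch (with probability
#' \code{cfg$augment_probability} through a mirrored or rotated sampling
#' grid), builds the class-balancing weight map, and updates the weights
#' from the weighted cross-entropy gradient. Dropout is active at the lowest
#' scale. Fully reproducible from \code{cfg$seed}.
#'
#' If \code{validation} cases are given, the whole-volume median validation
#' DSC is computed every \code{cfg$validation_interval} patches; with finite
#' \code{cfg$patience} training stops early once the median DSC has not
#' improved for that many evaluations and the best weights are restored.
#'
#' @param cohort list of training cases; each a list (or phantom) with
#'   elements \code{image} (\code{\link{ct_volume}}), \code{cavity} and
#'   \code{ich} (\code{\link{label_volume}}).
#' @param spec a \code{\link{network_spec}}.
#' @param cfg a \code{\link{train_config}}; \code{cfg$input_shape} must be
#'   valid for \code{spec}.
#' @param validation optional list of held-out cases in the same format.
#' @param verbose print progress.
#' @return An \code{ich_checkpoint}: list with \code{model}, \code{log}
#'   (data frame of per-step loss and validation DSC) and \code{config}.
#' @export
train <- function(cohort, spec, cfg = train_config(), validation = NULL,
                  verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"))
  if (length(cohort) < 1L) stopf("train: need at least one training case")
  output_shape(spec, cfg$input_shape)   # errors early on invalid geometry
  prep <- function(cs) lapply(cs, function(case) {
    if (!case$image$normalized) case$image <- normalize_hu(case$image)
    case
  })
  cohort <- prep(cohort)
  if (!is.null(validation)) validation <- prep(validation)

  with_seed(cfg$seed, {
    model <- build_model(spec)
    vel <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
    mu <- cfg$momentum; lr <- cfg$learning_rate
    log_steps <- integer(0); log_loss <- numeric(0)
    val_steps <- integer(0); val_dsc <- numeric(0)
    best <- list(dsc = -Inf, params = NULL, since = 0L)
    acc <- NULL; acc_n <- 0L
    stop_early <- FALSE

    for (step in seq_len(cfg$n_patches)) {
      case <- cohort[[sample.int(length(cohort), 1L)]]
      # exact alternating 50/50 class quota (coordinates random within class)
      centre <- sample_centre(case$ich, case$cavity,
                              force_class = if (step %% 2L == 1L) "fg" else "bg")
      ang <- 0; mir <- FALSE
      if (runif(1) < cfg$augment_probability) {
        if (runif(1) < 0.5) mir <- TRUE
        else ang <- runif(1, cfg$rotation_range[1], cfg$rotation_range[2])
      }
      patch <- extract_patch(case$image, case$ich, centre, spec,
                             input_shape = cfg$input_shape,
                             angle = ang, mirror = mir)
      w <- make_weight_map(patch$label_tile)
      fwd <- net_forward(model, patch$image_tile, training = TRUE)
      loss <- weighted_cross_entropy(fwd$probs, patch$label_tile, w)
      grads <- net_backward(model, fwd$cache, ce_grad(fwd$probs, patch$label_tile, w))

      if (is.null(acc)) acc <- grads
      else for (nm in names(grads)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
      acc_n <- acc_n + 1L
      if (acc_n == cfg$batch_size || step == cfg$n_patches) {
        for (nm in names(model$params)) {
          g <- acc[[nm]] / acc_n
          vel[[nm]] <- mu * vel[[nm]] - lr * g
          model$params[[nm]] <- model$params[[nm]] + mu * vel[[nm]] - lr * g
        }
        acc <- NULL; acc_n <- 0L
      }
      log_steps <- c(log_steps, step); log_loss <- c(log_loss, loss)
      if (verbose && step %% 10L == 0L)
        message(sprintf("step %d  loss %.4f", step, loss))

      if (!is.null(validation) && step %% cfg$validation_interval == 0L) {
        dscs <- vapply(validation, function(vc) {
          pm <- predict_volume(vc$image, vc$cavity, model)
          seg <- postprocess(pm)
          if (sum(seg$data) == 0 || sum(vc$ich$data) == 0) return(0)
          dsc(seg, vc$ich)
        }, 0)
        mdsc <- median(dscs)
        val_steps <- c(val_steps, step); val_dsc <- c(val_dsc, mdsc)
        if (verbose) message(sprintf("step %d  validation median DSC %.3f", step, mdsc))
        if (mdsc > best$dsc) {
          best <- list(dsc = mdsc, params = model$params, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (is.finite(cfg$patience) && best$since >= cfg$patience) {
            stop_early <- TRUE
            break
          }
        }
      }
    }
    if ((stop_early || cfg$restore_best) && !is.null(best$params))
      model$params <- best$params

    log <- data.frame(step = log_steps, loss = log_loss)
    if (length(val_steps))
      log$val_dsc <- val_dsc[match(log$step, val_steps)]
    structure(list(model = model, log = log, config = cfg,
                   stopped_early = stop_early,
                   best_val_dsc = if (is.finite(best$dsc)) best$dsc else NA_real_),
              class = "ich_checkpoint")
  })
}

#' @export
print.ich_checkpoint <- function(x, ...) {
  cat(sprintf("<ich_checkpoint> %d training steps, final loss %.4f%s\n",
              nrow(x$log), tail(x$log$loss, 1),
              if (!is.na(x$best_val_dsc))
                sprintf(", best validation DSC %.3f", x$best_val_dsc) else ""))
  invisible(x)
}
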