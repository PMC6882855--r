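# Network construction, forward and backward passes.
#
# The heavy lifting (valid 3D convolution) is compiled code; pooling,
# upscaling, cropping and activations are vectorized R. The backward pass is
# written explicitly for the two-pathway architecture and is verified against
# finite differences in the test suite.

lrelu_fwd <- function(z, slope) pmax(z, 0) + slope * pmin(z, 0)
lrelu_bwd <- function(dout, pos, slope) .lrelu_bwd(dout, pos, slope)

maxpool_fwd <- function(x, f) .maxpool_fwd(x, as.integer(f))

maxpool_bwd <- function(dout, arg, f, in_dim)
  .maxpool_bwd(dout, arg, as.integer(f), as.integer(in_dim))

# Reference R implementations of the pooling pair; the compiled versions
# above must agree with these exactly (checked in the test suite).
maxpool_fwd_ref <- function(x, f) {
  d <- dim(x)
  od <- d[1:3] %/% f
  ix <- lapply(1:3, function(a) seq(1L, by = f[a], length.out = od[a]))
  best <- NULL; arg <- NULL
  cid <- 0L
  for (dz in 0:(f[3] - 1L)) for (dy in 0:(f[2] - 1L)) for (dx in 0:(f[1] - 1L)) {
    cid <- cid + 1L
    sub <- x[ix[[1]] + dx, ix[[2]] + dy, ix[[3]] + dz, , drop = FALSE]
    if (is.null(best)) {
      best <- sub
      arg <- array(1L, dim(sub))
    } else {
      upd <- sub > best       # strict: ties keep the first candidate
      arg[upd] <- cid
      best[upd] <- sub[upd]
    }
  }
  list(out = best, arg = arg)
}

maxpool_bwd_ref <- function(dout, arg, f, in_dim) {
  dx <- array(0, in_dim)
  od <- dim(dout)
  ix <- lapply(1:3, function(a) seq(1L, by = f[a], length.out = od[a]))
  cid <- 0L
  for (dz in 0:(f[3] - 1L)) for (dy in 0:(f[2] - 1L)) for (dx0 in 0:(f[1] - 1L)) {
    cid <- cid + 1L
    dx[ix[[1]] + dx0, ix[[2]] + dy, ix[[3]] + dz, ] <- dout * (arg == cid)
  }
  dx
}

# Upscaling by regional repetition of the underlying values.
upsample_fwd <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f[1]), rep(seq_len(d[2]), each = f[2]),
    rep(seq_len(d[3]), each = f[3]), , drop = FALSE]
}

upsample_bwd <- function(dout, f) {
  d <- dim(dout)
  od <- d[1:3] %/% f
  ix <- lapply(1:3, function(a) seq(1L, by = f[a], length.out = od[a]))
  acc <- array(0, c(od, d[4]))
  for (dz in 0:(f[3] - 1L)) for (dy in 0:(f[2] - 1L)) for (dx in 0:(f[1] - 1L))
    acc <- acc + dout[ix[[1]] + dx, ix[[2]] + dy, ix[[3]] + dz, , drop = FALSE]
  acc
}

# Centre crop to target spatial size; odd margins split floor (low side) /
# ceil (high side).
crop_offset <- function(big, small) (big - small) %/% 2L

centre_crop <- function(x, target) {
  d <- dim(x)
  lo <- crop_offset(d[1:3], target)
  x[lo[1] + seq_len(target[1]), lo[2] + seq_len(target[2]),
    lo[3] + seq_len(target[3]), , drop = FALSE]
}

# channel extraction that survives degenerate (extent-1) spatial axes
channel <- function(a, c) array(a[, , , c], dim(a)[1:3])

softmax4 <- function(logits) {
  C <- dim(logits)[4]
  m <- channel(logits, 1)
  if (C > 1) for (c in 2:C) m <- pmax(m, channel(logits, c))
  e <- exp(logits - as.vector(m))
  s <- array(0, dim(e)[1:3])
  for (c in seq_len(C)) s <- s + channel(e, c)
  e / as.vector(s)
}

he_init <- function(kernel, cin, cout) {
  array(rnorm(prod(kernel) * cin * cout, sd = sqrt(2 / (prod(kernel) * cin))),
        c(kernel, cin, cout))
}

#' Build the segmentation model
#'
#' Instantiates the network of \code{\link{network_spec}} with
#' He-initialized weights. Filter counts follow the contracting path
#' (first-unit convolutions \code{base_filters} then doubled within the
#' unit, doubling again per scale); the expanding path mirrors the channel
#' count of the same scale's contracting-path output; a final 1x1x1
#' convolution maps to the class logits.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param seed optional seed for reproducible initialization.
#' @param precision \code{"single"} (default, fast) or \code{"double"}
#'   (used by gradient checks).
#' @return An \code{ich_model}: list with \code{spec}, \code{params} (named
#'   list of \code{W}/\code{b} arrays) and \code{precision}.
#' @export
build_model <- function(spec, seed = NULL, precision = c("single", "double")) {
  stopifnot(inherits(spec, "network_spec"))
  precision <- match.arg(precision)
  init <- function() {
    df <- down_filters(spec)
    S <- spec$n_scales
    cpu <- spec$convs_per_unit
    params <- list()
    cin <- 1L
    for (s in seq_len(S)) {
      pre <- if (s == S) "b" else paste0("d", s)
      for (cc in seq_len(cpu)) {
        cout <- if (cc == 1L) df[[s]][1] else df[[s]][2]
        params[[paste0(pre, "c", cc, ".W")]] <- he_init(spec$kernel, cin, cout)
        params[[paste0(pre, "c", cc, ".b")]] <- rep(0, cout)
        cin <- cout
      }
    }
    up_in <- cin  # channels arriving from below (bottom output at first)
    for (s in rev(seq_len(S - 1L))) {
      cin <- up_in + df[[s]][2]   # concat: skip channels + upscaled channels
      cout <- df[[s]][2]          # mirror the scale's contracting-path output
      for (cc in seq_len(cpu)) {
        params[[paste0("u", s, "c", cc, ".W")]] <- he_init(spec$kernel, cin, cout)
        params[[paste0("u", s, "c", cc, ".b")]] <- rep(0, cout)
        cin <- cout
      }
      up_in <- cout
    }
    params[["fin.W"]] <- he_init(c(1L, 1L, 1L), up_in, spec$n_classes)
    params[["fin.b"]] <- rep(0, spec$n_classes)
    params
  }
  params <- if (is.null(seed)) init() else with_seed(seed, init())
  structure(list(spec = spec, params = params, precision = precision),
            class = "ich_model")
}

#' @export
print.ich_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<ich_model> %d scales, base %d filters, %s parameters (%s precision)\n",
              x$spec$n_scales, x$spec$base_filters, format(np, big.mark = ","),
              x$precision))
  invisible(x)
}

conv_lrelu_fwd <- function(x, W, b, slope, single, keep_ws = FALSE) {
  lr <- .conv3d_fwd(x, W, b, single, slope = slope, keep_ws = keep_ws)
  list(a = lr$a, x = x, pos = lr$pos, ws = lr$ws)
}

# Forward pass. Returns probs and (optionally) the cache needed by
# net_backward. Dropout is active only when training = TRUE and draws from
# the current RNG stream.
net_forward <- function(model, input, training = FALSE, keep_cache = training) {
  spec <- model$spec
  p <- model$params
  single <- model$precision == "single"
  S <- spec$n_scales
  cpu <- spec$convs_per_unit
  f <- pool_factor(spec)
  if (length(dim(input)) == 3L) dim(input) <- c(dim(input), 1L)
  # input validity check (errors name the offending stage)
  layer_plan(spec, dim(input)[1:3])

  cache <- list(down = vector("list", S - 1L), up = vector("list", S - 1L))
  x <- input
  for (s in seq_len(S - 1L)) {
    convs <- vector("list", cpu)
    for (cc in seq_len(cpu)) {
      cl <- conv_lrelu_fwd(x, p[[paste0("d", s, "c", cc, ".W")]],
                           p[[paste0("d", s, "c", cc, ".b")]],
                           spec$leaky_slope, single, keep_ws = FALSE)
      x <- cl$a
      convs[[cc]] <- if (keep_cache) cl[c("x", "pos", "ws")] else NULL
    }
    mp <- maxpool_fwd(x, f)
    cache$down[[s]] <- list(convs = convs, skip = x,
                            arg = if (keep_cache) mp$arg else NULL,
                            pre_pool_dim = dim(x))
    x <- mp$out
  }
  bconvs <- vector("list", cpu)
  for (cc in seq_len(cpu)) {
    cl <- conv_lrelu_fwd(x, p[[paste0("bc", cc, ".W")]],
                         p[[paste0("bc", cc, ".b")]], spec$leaky_slope, single,
                         keep_ws = FALSE)
    x <- cl$a
    bconvs[[cc]] <- if (keep_cache) cl[c("x", "pos", "ws")] else NULL
  }
  # dropout on the lowest-scale feature maps; training only (inverted
  # scaling keeps expectations equal)
  drop_mask <- NULL
  if (training && spec$dropout_rate > 0) {
    drop_mask <- array(rbinom(length(x), 1L, 1 - spec$dropout_rate),
                       dim(x)) / (1 - spec$dropout_rate)
    x <- x * drop_mask
  }
  cache$bottom <- list(convs = bconvs, drop_mask = drop_mask)
  for (s in rev(seq_len(S - 1L))) {
    u <- upsample_fwd(x, f)
    k <- centre_crop(cache$down[[s]]$skip, dim(u)[1:3])
    nk <- dim(k)[4]
    x <- array(c(k, u), c(dim(u)[1:3], nk + dim(u)[4]))
    convs <- vector("list", cpu)
    for (cc in seq_len(cpu)) {
      cl <- conv_lrelu_fwd(x, p[[paste0("u", s, "c", cc, ".W")]],
                           p[[paste0("u", s, "c", cc, ".b")]],
                           spec$leaky_slope, single, keep_ws = FALSE)
      x <- cl$a
      convs[[cc]] <- if (keep_cache) cl[c("x", "pos", "ws")] else NULL
    }
    cache$up[[s]] <- list(convs = convs, n_skip = nk, up_dim = dim(u))
  }
  logits <- .conv3d_fwd(x, p[["fin.W"]], p[["fin.b"]], single)
  probs <- softmax4(logits)
  if (!keep_cache) {
    cache <- NULL
  } else {
    cache$fin_x <- x
  }
  # free skip maps not needed by backward (they are cached inside convs)
  if (keep_cache) for (s in seq_len(S - 1L)) cache$down[[s]]$skip <- NULL
  list(probs = probs, logits = logits, cache = cache)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
net_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  p <- model$params
  single <- model$precision == "single"
  S <- spec$n_scales
  cpu <- spec$convs_per_unit
  f <- pool_factor(spec)
  grads <- list()

  g <- .conv3d_bwd(cache$fin_x, p[["fin.W"]], dlogits, TRUE, single)
  grads[["fin.W"]] <- g$dW
  grads[["fin.b"]] <- g$db
  dx <- g$dx

  dskip <- vector("list", S - 1L)
  for (s in seq_len(S - 1L)) {        # reverse of forward up path
    uc <- cache$up[[s]]
    for (cc in rev(seq_len(cpu))) {
      nm <- paste0("u", s, "c", cc)
      cl <- uc$convs[[cc]]
      dz <- lrelu_bwd(dx, cl$pos, spec$leaky_slope)
      g <- .conv3d_bwd(cl$x, p[[paste0(nm, ".W")]], dz, TRUE, single, ws = cl$ws)
      grads[[paste0(nm, ".W")]] <- g$dW
      grads[[paste0(nm, ".b")]] <- g$db
      dx <- g$dx
    }
    nk <- uc$n_skip
    dk <- dx[, , , seq_len(nk), drop = FALSE]
    du <- dx[, , , nk + seq_len(dim(dx)[4] - nk), drop = FALSE]
    # embed cropped-skip gradient back into the full skip map
    full <- cache$down[[s]]$pre_pool_dim
    lo <- crop_offset(full[1:3], dim(dk)[1:3])
    dsk <- array(0, full)
    dsk[lo[1] + seq_len(dim(dk)[1]), lo[2] + seq_len(dim(dk)[2]),
        lo[3] + seq_len(dim(dk)[3]), ] <- dk
    dskip[[s]] <- dsk
    dx <- upsample_bwd(du, f)
  }

  if (!is.null(cache$bottom$drop_mask)) dx <- dx * cache$bottom$drop_mask
  for (cc in rev(seq_len(cpu))) {
    nm <- paste0("bc", cc)
    cl <- cache$bottom$convs[[cc]]
    dz <- lrelu_bwd(dx, cl$pos, spec$leaky_slope)
    g <- .conv3d_bwd(cl$x, p[[paste0(nm, ".W")]], dz, TRUE, single, ws = cl$ws)
    grads[[paste0(nm, ".W")]] <- g$dW
    grads[[paste0(nm, ".b")]] <- g$db
    dx <- g$dx
  }

  for (s in rev(seq_len(S - 1L))) {
    dc <- cache$down[[s]]
    da <- maxpool_bwd(dx, dc$arg, f, dc$pre_pool_dim) + dskip[[s]]
    dx <- da
    for (cc in rev(seq_len(cpu))) {
      nm <- paste0("d", s, "c", cc)
      cl <- dc$convs[[cc]]
      dz <- lrelu_bwd(dx, cl$pos, spec$leaky_slope)
      need_dx <- !(s == 1L && cc == 1L)   # no gradient needed w.r.t. input
      g <- .conv3d_bwd(cl$x, p[[paste0(nm, ".W")]], dz, need_dx, single,
                       ws = cl$ws)
      grads[[paste0(nm, ".W")]] <- g$dW
      grads[[paste0(nm, ".b")]] <- g$db
      if (need_dx) dx <- g$dx
    }
  }
  grads
}

#' Run the model on one input tile
#'
#' Forward pass in evaluation mode (dropout inactive). The realized output
#' shape always equals \code{\link{output_shape}}'s prediction; per-voxel
#' class probabilities sum to 1.
#'
#' @param model an \code{ich_model}.
#' @param tile 3D array (normalized intensities) of a valid input shape.
#' @return 4D array: per-voxel class probabilities
#'   (background, ICH) of shape \code{c(output_shape(spec, dim(tile)),
#'   n_classes)}.
#' @export
forward_tile <- function(model, tile) {
  stopifnot(inherits(model, "ich_model"))
  net_forward(model, tile, training = FALSE, keep_cache = FALSE)$probs
}

#' Save a model checkpoint
#'
#' A single file holding the weights together with the architecture
#' description embedded as JSON, so prediction can reconstruct the model
#' without further configuration. An optional training log and resolved
#' config ride along.
#'
#' @param model an \code{ich_model}.
#' @param path output file.
#' @param log optional training log (data frame).
#' @param config optional resolved configuration list.
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(model, path, log = NULL, config = NULL) {
  stopifnot(inherits(model, "ich_model"))
  obj <- list(spec_json = as.character(jsonlite::toJSON(unclass(model$spec),
                                                        auto_unbox = TRUE)),
              params = model$params, precision = model$precision,
              log = log, config = config)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by \code{\link{save_checkpoint}}.
#' @return An \code{ich_model} with attributes \code{log} and \code{config}
#'   restored alongside.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  sj <- jsonlite::fromJSON(obj$spec_json)
  spec <- network_spec(n_scales = sj$n_scales, convs_per_unit = sj$convs_per_unit,
                       kernel = sj$kernel, pool = sj$pool,
                       pool_axes = sj$pool_axes, base_filters = sj$base_filters,
                       filter_doubling = sj$filter_doubling,
                       leaky_slope = sj$leaky_slope,
                       dropout_rate = sj$dropout_rate, n_classes = sj$n_classes)
  model <- structure(list(spec = spec, params = obj$params,
                          precision = obj$precision),
                     class = "ich_model")
  attr(model, "log") <- obj$log
  attr(model, "config") <- obj$config
  model
}
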