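#' Specify the two-pathway multi-scale 3D segmentation network
#'
#' The architecture is a 3D fully-convolutional encoder--decoder with valid
#' (unpadded) convolutions throughout. The first (contracting) pathway is a
#' repeated unit of two 3x3x3 convolutions followed by 2x2x2 max pooling,
#' repeated \code{n_scales - 1} times to give \code{n_scales} scales; the
#' number of filters doubles between the first and second convolution of each
#' unit. The second (integrative) pathway mirrors it: 2x2x2 upscaling by
#' regional repetition, concatenation with the centre-cropped feature map of
#' the same scale from the first pathway, then two 3x3x3 convolutions.
#' Activations are leaky ReLUs; a final 1x1x1 convolution and softmax produce
#' the 2-class per-voxel probability map. Dropout is applied at the lowest
#' scale during training.
#'
#' The anisotropic variant for thick-slice data (e.g. 5 mm axial spacing)
#' disables pooling and upscaling along z (\code{pool_axes = c(TRUE, TRUE,
#' FALSE)}): z extents are then reduced only by the valid convolutions.
#'
#' @param n_scales number of scales (default 4).
#' @param convs_per_unit convolutions per unit (default 2).
#' @param kernel per-axis kernel size (default 3x3x3).
#' @param pool per-axis pooling factor (default 2x2x2).
#' @param pool_axes logical triple; pooling/upscaling applied on that axis.
#' @param base_filters filters of the very first convolution (default 32;
#'   reduced profiles use 4).
#' @param filter_doubling double filters between the two convolutions of a
#'   unit (and per scale).
#' @param leaky_slope negative slope of the leaky ReLU (default 0.01).
#' @param dropout_rate dropout probability at the lowest scale (default 0.5,
#'   training only).
#' @param n_classes output classes (2: background, ICH).
#' @return A \code{network_spec} list.
#' @seealso \code{\link{output_shape}}, \code{\link{build_model}}
#' @export
network_spec <- function(n_scales = 4L, convs_per_unit = 2L,
                         kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L),
                         pool_axes = c(TRUE, TRUE, TRUE),
                         base_filters = 32L, filter_doubling = TRUE,
                         leaky_slope = 0.01, dropout_rate = 0.5,
                         n_classes = 2L) {
  if (!is_count(n_scales, 2L)) stopf("n_scales must be a count >= 2")
  if (!is_count(convs_per_unit)) stopf("convs_per_unit must be a count >= 1")
  kernel <- as.integer(check_triple(kernel, "kernel"))
  pool <- as.integer(check_triple(pool, "pool"))
  if (length(pool_axes) != 3L || !is.logical(pool_axes))
    stopf("pool_axes must be a logical triple")
  if (!is_count(base_filters)) stopf("base_filters must be a count >= 1")
  structure(list(n_scales = as.integer(n_scales),
                 convs_per_unit = as.integer(convs_per_unit),
                 kernel = kernel, pool = pool, pool_axes = pool_axes,
                 base_filters = as.integer(base_filters),
                 filter_doubling = isTRUE(filter_doubling),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes)),
            class = "network_spec")
}

#' Anisotropic network variant for thick-slice CT
#'
#' Convenience wrapper around \code{\link{network_spec}} with pooling and
#' upscaling disabled along z, matching data resampled to e.g.
#' 0.43 x 0.43 x 5 mm with input patches of 124 x 124 x 40 voxels.
#'
#' @param ... passed to \code{\link{network_spec}}.
#' @return A \code{network_spec}.
#' @export
anisotropic_spec <- function(...) {
  network_spec(pool_axes = c(TRUE, TRUE, FALSE), ...)
}

# Per-scale filter counts of the contracting path: list of length n_scales,
# each c(first_conv, second_conv).
down_filters <- function(spec) {
  lapply(seq_len(spec$n_scales), function(s) {
    f1 <- if (spec$filter_doubling) spec$base_filters * 2L^(s - 1L) else spec$base_filters
    f2 <- if (spec$filter_doubling) 2L * f1 else f1
    c(f1, f2)
  })
}

# Effective per-axis pool factor (1 on non-pooled axes).
pool_factor <- function(spec) ifelse(spec$pool_axes, spec$pool, 1L)

#' Per-layer stage plan with exact spatial sizes
#'
#' Walks every convolution, pooling and upscaling stage of the network and
#' records the per-axis spatial extent after each. Fails with the name of the
#' offending stage if any intermediate size is non-positive or a pre-pool
#' size is not divisible by the pool factor on a pooled axis.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param input_shape voxel triple.
#' @return Data frame with columns \code{stage}, \code{x}, \code{y}, \code{z}.
#' @export
layer_plan <- function(spec, input_shape) {
  stopifnot(inherits(spec, "network_spec"))
  sz <- as.integer(check_triple(input_shape, "input_shape"))
  f <- pool_factor(spec)
  red <- spec$kernel - 1L
  rows <- list(list(stage = "input", size = sz))
  push <- function(stage, size) rows[[length(rows) + 1L]] <<- list(stage = stage, size = size)
  conv <- function(stage, sz) {
    sz <- sz - red
    if (any(sz <= 0))
      stopf("invalid input size: stage %s would have extent %s", stage,
            paste(sz, collapse = "x"))
    push(stage, sz)
    sz
  }
  S <- spec$n_scales
  for (s in seq_len(S - 1L)) {
    for (cc in seq_len(spec$convs_per_unit))
      sz <- conv(sprintf("down%d.conv%d", s, cc), sz)
    if (any(sz %% f != 0))
      stopf("invalid input size: stage down%d.pool has indivisible extent %s (pool %s)",
            s, paste(sz, collapse = "x"), paste(f, collapse = "x"))
    sz <- sz %/% f
    push(sprintf("down%d.pool", s), sz)
  }
  for (cc in seq_len(spec$convs_per_unit))
    sz <- conv(sprintf("bottom.conv%d", cc), sz)
  for (s in rev(seq_len(S - 1L))) {
    sz <- sz * f
    push(sprintf("up%d.upscale", s), sz)
    for (cc in seq_len(spec$convs_per_unit))
      sz <- conv(sprintf("up%d.conv%d", s, cc), sz)
  }
  push("output", sz)
  do.call(rbind, lapply(rows, function(r)
    data.frame(stage = r$stage, x = r$size[1], y = r$size[2], z = r$size[3])))
}

#' Output tile shape for a given input tile shape
#'
#' Exact per-axis arithmetic of the valid-convolution architecture: e.g. the
#' default four-scale isotropic network maps 124x124x124 input tiles to
#' 36x36x36 output tiles, and the anisotropic variant maps 124x124x40 to
#' 36x36x12.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param input_shape voxel triple.
#' @return Integer triple of per-axis output extents.
#' @export
output_shape <- function(spec, input_shape) {
  pl <- layer_plan(spec, input_shape)
  as.integer(pl[nrow(pl), c("x", "y", "z")])
}

#' Enumerate valid input extents per axis
#'
#' An input extent is valid on an axis if every intermediate size stays
#' positive and every pre-pool size is divisible by the pool factor. The
#' validity of each axis is independent of the others. For the default
#' isotropic spec the valid extents are 92, 100, 108, ... (stride 8); on a
#' non-pooled axis of the anisotropic variant every extent large enough for
#' the stacked valid convolutions qualifies (>= 29 for the default depth).
#'
#' @param spec a \code{\link{network_spec}}.
#' @param max_side largest extent to consider.
#' @return Named list with integer vectors \code{x}, \code{y}, \code{z}.
#' @export
valid_input_shapes <- function(spec, max_side) {
  stopifnot(inherits(spec, "network_spec"))
  # per-axis independence: run the scan once per distinct pooling flag
  flags <- pool_factor(spec)
  res <- list()
  for (a in 1:3) {
    key <- as.character(flags[a])
    if (is.null(res[[key]])) {
      spec1 <- spec
      spec1$pool_axes <- rep(spec$pool_axes[a], 3)
      ok <- integer(0)
      for (e in seq_len(max_side))
        if (!inherits(try(layer_plan(spec1, rep(e, 3)), silent = TRUE), "try-error"))
          ok <- c(ok, e)
      res[[key]] <- ok
    }
  }
  list(x = res[[as.character(flags[1])]],
       y = res[[as.character(flags[2])]],
       z = res[[as.character(flags[3])]])
}
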