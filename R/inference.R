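#' Tiled whole-volume prediction
#'
#' Produces an ICH probability map for a whole CT volume by processing
#' consecutive input tiles. Output tiles pave the cranial cavity's bounding
#' box with stride equal to the network output shape (no overlap); each
#' input tile is centred over its output tile, zero-padding where it
#' overruns the volume. Probabilities outside the cavity mask are set to 0;
#' the coverage mask (voxels actually predicted) always contains the cavity.
#'
#' Tile extents are chosen per axis from the valid input sizes: the smallest
#' valid input whose output covers the bounding box in one tile, or — when
#' the box is larger than \code{max_input} allows — the size minimizing the
#' tile count times per-tile cost.
#'
#' @param vol normalized \code{\link{ct_volume}}.
#' @param cavity cranial-cavity \code{\link{label_volume}} on the same grid.
#' @param model an \code{ich_model}, \code{ich_checkpoint}, or path to a
#'   checkpoint file.
#' @param tile_shape optional explicit input tile shape (must be valid).
#' @param max_input per-axis cap for automatic tile selection.
#' @return A \code{probability_map}: list with \code{data} (ICH-class
#'   probabilities in [0, 1]), \code{spacing} and \code{coverage}.
#' @export
predict_volume <- function(vol, cavity, model, tile_shape = NULL,
                           max_input = 176L) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "ich_checkpoint")) model <- model$model
  stopifnot(inherits(model, "ich_model"), inherits(vol, "ct_volume"),
            inherits(cavity, "label_volume"))
  if (!vol$normalized)
    stopf("predict_volume: volume must be normalized (see normalize_hu)")
  d <- dim(vol$data)
  if (!identical(d, dim(cavity$data)) ||
      max(abs(vol$spacing - cavity$spacing)) > 1e-6)
    stopf("predict_volume: volume and cavity mask are on different grids")
  spec <- model$spec

  idx <- which(cavity$data == 1)
  if (length(idx) == 0) stopf("predict_volume: empty cavity mask")
  co <- arrayInd(idx, d)
  lo <- apply(co, 2, min); hi <- apply(co, 2, max)
  bbox <- hi - lo + 1L

  if (is.null(tile_shape)) {
    valid <- valid_input_shapes(spec, max_side = max_input)
    tile_shape <- integer(3)
    for (a in 1:3) {
      cand <- valid[[a]]
      if (length(cand) == 0)
        stopf("predict_volume: no valid tile extent on axis %d up to %d", a, max_input)
      out <- vapply(cand, function(e) {
        spec1 <- spec
        spec1$pool_axes <- rep(spec$pool_axes[a], 3)
        output_shape(spec1, rep(e, 3))[1]
      }, 0L)
      cost <- ceiling(bbox[a] / out) * cand
      best <- which(cost == min(cost))
      tile_shape[a] <- cand[best[length(best)]]   # tie -> larger output
    }
  } else {
    tile_shape <- as.integer(check_triple(tile_shape, "tile_shape"))
  }
  out_shape <- output_shape(spec, tile_shape)
  margin <- (tile_shape - out_shape) %/% 2L

  probs <- array(0, d)
  coverage <- array(FALSE, d)
  starts <- lapply(1:3, function(a)
    lo[a] + out_shape[a] * (0:(ceiling(bbox[a] / out_shape[a]) - 1L)))
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    o0 <- c(sx, sy, sz)
    i0 <- o0 - margin
    tile <- array(0, tile_shape)
    src_lo <- pmax(i0, 1L); src_hi <- pmin(i0 + tile_shape - 1L, d)
    dst_lo <- src_lo - i0 + 1L; dst_hi <- src_hi - i0 + 1L
    tile[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      vol$data[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
    p <- net_forward(model, tile, training = FALSE, keep_cache = FALSE)$probs
    keep_hi <- pmin(o0 + out_shape - 1L, d)
    n_keep <- keep_hi - o0 + 1L
    probs[o0[1]:keep_hi[1], o0[2]:keep_hi[2], o0[3]:keep_hi[3]] <-
      p[seq_len(n_keep[1]), seq_len(n_keep[2]), seq_len(n_keep[3]), 2]
    coverage[o0[1]:keep_hi[1], o0[2]:keep_hi[2], o0[3]:keep_hi[3]] <- TRUE
  }
  probs[cavity$data == 0] <- 0
  structure(list(data = probs, spacing = vol$spacing, coverage = coverage),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s voxels, %d covered, max p = %.3f\n",
              paste(dim(x$data), collapse = "x"), sum(x$coverage), max(x$data)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' 26-neighbourhood by default (all voxels sharing a face, edge or corner),
#' or 6-neighbourhood (faces only).
#'
#' @param mask binary 3D array.
#' @param connectivity 26 or 6.
#' @return Integer array: 0 background, components numbered from 1.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(mask)
  fg <- which(mask != 0)
  lab <- array(0L, d)
  if (length(fg) == 0) return(lab)
  co <- arrayInd(fg, d)
  # positive-direction neighbour offsets (half of the neighbourhood)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs %*% c(1L, 3L, 9L) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  key <- fg
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- co[, 1] + offs[r, 1] + (co[, 2] + offs[r, 2] - 1L) * d[1] +
      (co[, 3] + offs[r, 3] - 1L) * d[1] * d[2]
    inb <- co[, 1] + offs[r, 1] >= 1L & co[, 1] + offs[r, 1] <= d[1] &
      co[, 2] + offs[r, 2] >= 1L & co[, 2] + offs[r, 2] <= d[2] &
      co[, 3] + offs[r, 3] >= 1L & co[, 3] + offs[r, 3] <= d[3]
    m <- match(nb[inb], key)
    src <- which(inb)[!is.na(m)]
    if (length(src))
      edges <- rbind(edges, cbind(src, m[!is.na(m)]))
  }
  if (is.null(edges)) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::make_graph(as.vector(t(edges)), n = length(fg), directed = FALSE)
  lab[fg] <- igraph::components(g)$membership
  lab
}

#' Post-process a probability map into the final segmentation
#'
#' Thresholds the probability map at 0.5 (inclusive: ties go to foreground)
#' and removes all connected clusters smaller than 0.1 mL in volume
#' (strictly: a cluster of exactly 0.1 mL survives). Cluster volume is voxel
#' count times voxel volume; connectivity is 26-neighbourhood by default.
#' The operation is idempotent and monotone in the probabilities.
#'
#' @param probs a \code{probability_map}.
#' @param threshold probability threshold (default 0.5).
#' @param min_cluster_ml minimum surviving cluster volume in mL
#'   (default 0.1).
#' @param connectivity 26 or 6.
#' @return A prediction \code{\link{label_volume}}.
#' @export
postprocess <- function(probs, threshold = 0.5, min_cluster_ml = 0.1,
                        connectivity = 26L) {
  stopifnot(inherits(probs, "probability_map"))
  if (any(probs$spacing <= 0)) stopf("postprocess: non-positive spacing")
  mask <- probs$data >= threshold
  voxvol <- prod(probs$spacing)          # mm^3
  lab <- connected_components(mask, connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes * voxvol < min_cluster_ml * 1000 - 1e-9)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  label_volume(array(as.numeric(mask), dim(mask)), probs$spacing,
               role = "prediction")
}

#' Segmented volume in millilitres
#'
#' Voxel count times voxel volume, in mL — the clinical output of the
#' pipeline (total haemorrhage volume).
#'
#' @param mask a \code{\link{label_volume}}.
#' @return Volume in mL.
#' @export
segmentation_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "label_volume"))
  sum(mask$data) * prod(mask$spacing) / 1000
}
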