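# Independent oracles and small fixtures shared across the suite.
# Every oracle here is deliberately brute-force and separate from the code
# paths it checks.

# Layer-by-layer shape walk: an explicit list of every conv/pool/upscale with
# its size effect, written out stage by stage.
simulate_shapes <- function(input, n_scales = 4L,
                            pool_axes = c(TRUE, TRUE, TRUE),
                            convs_per_unit = 2L, kernel = 3L, pool = 2L) {
  sz <- as.integer(input)
  f <- ifelse(pool_axes, pool, 1L)
  shrink <- kernel - 1L
  for (s in seq_len(n_scales - 1L)) {
    for (cc in seq_len(convs_per_unit)) {
      sz <- sz - shrink
      if (any(sz <= 0)) stop("conv underflow (down)")
    }
    if (any(sz %% f != 0)) stop("indivisible pre-pool size")
    sz <- sz %/% f
  }
  for (cc in seq_len(convs_per_unit)) {
    sz <- sz - shrink
    if (any(sz <= 0)) stop("conv underflow (bottom)")
  }
  for (s in seq_len(n_scales - 1L)) {
    sz <- sz * f
    for (cc in seq_len(convs_per_unit)) {
      sz <- sz - shrink
      if (any(sz <= 0)) stop("conv underflow (up)")
    }
  }
  sz
}

# Brute-force surface extraction: explicit voxel loop, 6-neighbourhood,
# border counts as outside.
brute_surface <- function(m) {
  d <- dim(m)
  at <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1 || i > d[1] || j > d[2] || k > d[3]) 0 else m[i, j, k]
  }
  res <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (m[i, j, k] == 1) {
      nb <- c(at(i - 1, j, k), at(i + 1, j, k), at(i, j - 1, k),
              at(i, j + 1, k), at(i, j, k - 1), at(i, j, k + 1))
      if (any(nb == 0)) res <- rbind(res, c(i, j, k))
    }
  res
}

# O(n^2) all-pairs distance metrics between two masks (mm), the primary
# oracle for the distance-metric module.
brute_distance_metrics <- function(segm, refm, spacing) {
  S <- brute_surface(segm)
  R <- brute_surface(refm)
  mind <- function(A, B) {
    vapply(seq_len(nrow(A)), function(a) {
      best <- Inf
      for (b in seq_len(nrow(B))) {
        dd <- sqrt(sum(((A[a, ] - B[b, ]) * spacing)^2))
        if (dd < best) best <- dd
      }
      best
    }, 0)
  }
  dS <- mind(S, R)
  dR <- mind(R, S)
  q95 <- function(x) unname(quantile(x, 0.95, type = 7))
  c(hd_mm = max(max(dS), max(dR)),
    hd95_mm = max(q95(dS), q95(dR)),
    mhd_mm = max(mean(dS), mean(dR)),
    cmd_mm = mean(c(dS, dR)))
}

# Breadth-first flood fill connected components (26- or 6-neighbourhood).
brute_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  for (v in which(mask != 0)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(v, d)[1, ])
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] != 0 && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Small-grid phantom spec used throughout the unit tests (48^3 grid keeps
# generation and 2-scale networks fast; lesion volume scaled to the grid).
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(48L, 48L, 48L),
               lesion_volume_range = c(0.15, 0.4), seed = seed, ...)
}

# A 2-scale toy network spec: valid inputs are the even sizes >= 18,
# output extent = input - 16 on all axes.
toy_spec <- function(...) network_spec(n_scales = 2L, base_filters = 2L, ...)

# Deterministic box mask helper.
box_mask <- function(dim3, lo, hi, spacing = c(1, 1, 1),
                     role = "prediction") {
  m <- array(0, dim3)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  label_volume(m, spacing, role = role)
}

# Random blob label volume for metric property tests.
random_mask <- function(d = c(9L, 9L, 9L), p = 0.25, spacing = c(1, 1, 1),
                        role = "prediction") {
  m <- array(rbinom(prod(d), 1, p), d)
  if (sum(m) == 0) m[ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2)] <- 1
  label_volume(m, spacing, role = role)
}
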