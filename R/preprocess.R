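# Phase-contrast preprocessing: background-offset correction and temporal
# phase unwrapping. Both operate on the stored samples only; grid geometry,
# timing and masks are never altered.

#' Polynomial basis of total degree <= order in 3 scaled coordinates
#'
#' Returns the monomial design matrix x^i y^j z^k with i + j + k <= order
#' (35 monomials at order 4). Coordinates should be pre-scaled to `[-1, 1]`
#' per axis (see [grid_scaled_coords()]) for conditioning.
#'
#' @param X n x 3 matrix of scaled coordinates.
#' @param order maximum total degree.
#' @return n x m design matrix with exponent triples as an attribute.
#' @export
polynomial_basis <- function(X, order = 4) {
  stopifnot(ncol(X) == 3)
  ex <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  ex <- ex[rowSums(ex) <= order, , drop = FALSE]
  ex <- ex[order(rowSums(ex), ex$i, ex$j, ex$k), ]
  B <- matrix(1, nrow(X), nrow(ex))
  for (m in seq_len(nrow(ex)))
    B[, m] <- X[, 1]^ex$i[m] * X[, 2]^ex$j[m] * X[, 3]^ex$k[m]
  attr(B, "exponents") <- ex
  B
}

#' Voxel-center coordinates of a grid, scaled to `[-1, 1]` per axis
#'
#' @param grid_dim integer(3) grid size.
#' @param voxel_size voxel size (mm); affects nothing after scaling but kept
#'   for interface symmetry.
#' @return (prod(grid_dim)) x 3 matrix in array (column-major) voxel order.
#' @export
grid_scaled_coords <- function(grid_dim, voxel_size = 1) {
  sc <- function(n) if (n == 1) rep(0, 1) else 2 * (seq_len(n) - 1) / (n - 1) - 1
  g <- expand.grid(x = sc(grid_dim[1]), y = sc(grid_dim[2]), z = sc(grid_dim[3]))
  as.matrix(g)
}

#' Fit a polynomial background-offset model to static tissue
#'
#' Least-squares fit, per velocity component, of a full 3-D polynomial of
#' total degree <= `order` to the time-averaged velocity over static-tissue
#' voxels. One offset field per component is fitted (the background error of
#' a phase-contrast acquisition is static over the cycle).
#'
#' @param field a [velocity_field()].
#' @param static_mask logical 3-D mask of static tissue on the field grid.
#' @param order maximum total polynomial degree (default 4; 35 monomials).
#' @return A `vf_background_model`: coefficients (m x 3), order, per-component
#'   residual RMS over the static mask (m/s), grid dimensions.
#' @export
fit_background <- function(field, static_mask, order = 4) {
  d <- field_grid_dim(field)
  if (!identical(dim(static_mask), as.integer(d)) &&
      !identical(dim(static_mask), d))
    vf_stop("static mask grid does not match field grid", "vf_io_error")
  idx <- which(static_mask)
  n_mono <- choose(order + 3, 3)
  if (length(idx) < n_mono)
    vf_stop(sprintf(
      "only %d static voxels for %d monomials: enlarge the static mask or lower the order",
      length(idx), n_mono), "vf_rank_error")
  B_all <- polynomial_basis(grid_scaled_coords(d), order)
  B <- B_all[idx, , drop = FALSE]
  qrB <- qr(B)
  if (qrB$rank < n_mono)
    vf_stop("static mask does not span the polynomial basis (rank-deficient fit): enlarge the static mask or lower the order",
            "vf_rank_error")
  coeffs <- matrix(0, n_mono, 3)
  rms <- numeric(3)
  nt <- n_frames(field)
  for (ci in 1:3) {
    tavg <- rowMeans(matrix(field$values[, , , ci, ], prod(d), nt))
    y <- tavg[idx]
    coeffs[, ci] <- qr.coef(qrB, y)
    rms[ci] <- sqrt(mean((y - B %*% coeffs[, ci])^2))
  }
  structure(list(coeffs = coeffs, order = order, residual_rms = rms,
                 grid_dim = d, n_static = length(idx)),
            class = "vf_background_model")
}

#' Subtract a fitted background-offset model from a field
#'
#' Evaluates the polynomial at every voxel and subtracts the same offset from
#' every frame of the matching component.
#'
#' @param field a [velocity_field()].
#' @param model a `vf_background_model` from [fit_background()] on the same
#'   grid.
#' @return A corrected [velocity_field()].
#' @export
subtract_background <- function(field, model) {
  d <- field_grid_dim(field)
  if (!identical(as.integer(model$grid_dim), as.integer(d)))
    vf_stop("background model fitted on a different grid", "vf_config_error")
  B <- polynomial_basis(grid_scaled_coords(d), model$order)
  off <- B %*% model$coeffs
  values <- field$values
  for (ci in 1:3) {
    off_vol <- array(off[, ci], d)
    for (f in seq_len(n_frames(field)))
      values[, , , ci, f] <- values[, , , ci, f] - off_vol
  }
  velocity_field(values, field$voxel_size, field$frame_times,
                 field$cycle_duration, field$venc)
}

#' Temporally unwrap phase-aliased velocities
#'
#' Walks the frames of every voxel and component in time order; whenever the
#' jump between consecutive samples exceeds the VENC in magnitude, the later
#' sample is shifted by the correcting multiple of 2 VENC. Any physically
#' valid jump satisfies |dv| <= VENC only via aliasing, so the threshold
#' cannot fire on true data. Voxels needing more than `max_wraps` corrections
#' on a single jump are left untouched and flagged unreliable.
#'
#' @param field a [velocity_field()].
#' @param max_wraps cap on corrections per jump before a voxel is declared
#'   unreliable (default 3).
#' @return A list: `field` (corrected), `wrap_count` (samples corrected),
#'   `unreliable` (logical 3-D mask of capped voxels).
#' @export
unwrap_temporal <- function(field, max_wraps = 3L) {
  v <- venc_ms(field)
  d <- dim(field$values)
  nvox <- prod(d[1:3])
  nt <- d[5]
  values <- field$values
  wrap_count <- 0L
  unreliable <- array(FALSE, d[1:3])
  for (ci in 1:3) {
    m <- matrix(values[, , , ci, ], nvox, nt)
    orig <- m
    bad <- rep(FALSE, nvox)
    for (k in 2:nt) {
      dv <- m[, k] - m[, k - 1]
      w <- round(dv / (2 * v))
      w[abs(dv) <= v] <- 0
      over <- abs(w) > max_wraps
      bad <- bad | over
      w[over] <- 0
      corr <- w != 0
      if (any(corr)) {
        m[corr, k] <- m[corr, k] - 2 * v * w[corr]
        wrap_count <- wrap_count + sum(corr)
      }
    }
    m[bad, ] <- orig[bad, ]
    unreliable <- unreliable | array(bad, d[1:3])
    values[, , , ci, ] <- array(m, c(d[1:3], nt))
  }
  list(field = velocity_field(values, field$voxel_size, field$frame_times,
                              field$cycle_duration, field$venc),
       wrap_count = wrap_count, unreliable = unreliable)
}

#' Heuristic static-tissue detection
#'
#' Marks voxels whose temporal speed standard deviation falls below a
#' percentile threshold as static. A supplied static mask should always be
#' preferred; this helper only fills in when none is available.
#'
#' @param field a [velocity_field()].
#' @param percentile percentile of the temporal-SD distribution below which a
#'   voxel counts as static (default 10).
#' @param exclude optional logical mask (e.g. the ED mask, dilated) removed
#'   from the result.
#' @return Logical 3-D mask.
#' @export
auto_static_mask <- function(field, percentile = 10, exclude = NULL) {
  d <- dim(field$values)
  nvox <- prod(d[1:3])
  speed2 <- matrix(0, nvox, d[5])
  for (ci in 1:3)
    speed2 <- speed2 + matrix(field$values[, , , ci, ], nvox, d[5])^2
  sds <- apply(sqrt(speed2), 1, sd)
  mask <- array(sds <= quantile(sds, percentile / 100), d[1:3])
  if (!is.null(exclude)) mask <- mask & !exclude
  mask
}
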