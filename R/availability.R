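#' Circular focal kernel
#'
#' Builds the binary moving-window kernel used for focal statistics: cell
#' (i, j) of the `(2R+1) x (2R+1)` window is included iff the centre-to-centre
#' Euclidean distance to the window centre is at most `radius` metres, with
#' `R = floor(radius / cell_size)`. Distances are planar (projected grid); no
#' geodesic correction is applied. The kernel is symmetric under 90-degree
#' rotation and reflection and always contains its centre cell.
#'
#' @param radius Window radius in metres; must be at least `cell_size`
#'   (a smaller radius would degenerate to a single-cell window, which is
#'   rejected rather than silently allowed).
#' @param cell_size Cell edge length in metres.
#' @return Integer 0/1 matrix of odd dimension.
#' @examples
#' circular_kernel(250, 250)   # 5-cell "plus" kernel
#' sum(circular_kernel(10000, 250))
#' @export
circular_kernel <- function(radius, cell_size) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius))
    stop("`radius` must be a single finite number (metres)", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  if (radius < cell_size)
    stop(sprintf(
      "radius (%g m) is smaller than the cell size (%g m): the focal window would be a single cell",
      radius, cell_size), call. = FALSE)
  r <- floor(radius / cell_size)
  off <- -r:r
  d <- outer(off, off, function(i, j) sqrt(i^2 + j^2) * cell_size)
  k <- matrix(0L, 2L * r + 1L, 2L * r + 1L)
  k[d <= radius] <- 1L
  k
}

# Focal counts of a 0/1 matrix under a 0/1 kernel; cells outside the grid
# contribute nothing. method "fft" computes the cross-correlation in the
# frequency domain and rounds to the nearest integer (counts are integers, so
# rounding removes all floating-point drift); "direct" accumulates shifted
# copies of the matrix, one kernel offset at a time, in exact integer
# arithmetic.
focal_count <- function(mask01, kernel, method = c("fft", "direct")) {
  method <- match.arg(method)
  n <- nrow(mask01); m <- ncol(mask01)
  kr <- (nrow(kernel) - 1L) %/% 2L
  if (method == "fft") {
    P <- n + 2L * kr; Q <- m + 2L * kr
    A <- matrix(0, P, Q); A[seq_len(n), seq_len(m)] <- mask01
    K <- matrix(0, P, Q); K[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
    conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (P * Q)
    out <- conv[(kr + 1L):(kr + n), (kr + 1L):(kr + m), drop = FALSE]
    return(matrix(as.integer(round(out)), n, m))
  }
  acc <- matrix(0L, n, m)
  for (di in -kr:kr) {
    src_i <- max(1L, 1L + di):min(n, n + di)
    dst_i <- src_i - di
    for (dj in -kr:kr) {
      if (kernel[di + kr + 1L, dj + kr + 1L] == 0L) next
      src_j <- max(1L, 1L + dj):min(m, m + dj)
      dst_j <- src_j - dj
      acc[dst_i, dst_j] <- acc[dst_i, dst_j] + mask01[src_i, src_j]
    }
  }
  acc
}

#' Habitat availability within a migration distance
#'
#' For every water cell, computes the proportion `x` of the water area within
#' a species' migration distance that is predicted recruitment habitat: the
#' count of habitat cells inside the circular focal window, divided by the
#' count of water cells inside the window. Land cells and cells beyond the
#' grid edge are excluded from numerator and denominator alike, so `x` is
#' always a proportion of observable water and stays in `[0, 1]` even at grid
#' edges. Counts are exact integers by contract; the default FFT path rounds
#' its counts to the nearest integer before dividing, so the result equals a
#' brute-force per-cell count on any input.
#'
#' @param habitat Binary [raster_grid()]: 1 = recruitment habitat, 0 = water
#'   without habitat, `NA` = land/nodata. Habitat must lie on water.
#' @param water_mask [raster_grid()] with 1 for water, 0 or `NA` for land.
#' @param radius Migration distance in metres (e.g. 10000 for perch, 15000
#'   for pikeperch).
#' @param method `"fft"` (frequency-domain counting, default) or `"direct"`
#'   (shifted-copy accumulation); both give identical integer counts.
#' @return A [raster_grid()] of availability proportions with `NA` exactly
#'   where `water_mask` is land/nodata, and an added `radius_m` element.
#' @examples
#' w <- raster_grid(matrix(1, 8, 8), 250)
#' h <- raster_grid(matrix(rbinom(64, 1, 0.3), 8, 8), 250)
#' a <- habitat_availability(h, w, radius = 500)
#' range(a$values)
#' @export
habitat_availability <- function(habitat, water_mask, radius,
                                 method = c("fft", "direct")) {
  method <- match.arg(method)
  check_congruent(habitat, water_mask, c("habitat", "water_mask"))
  water <- !is.na(water_mask$values) & water_mask$values != 0
  hab <- habitat$values
  bad <- !is.na(hab) & hab != 0 & !water
  if (any(bad))
    stop(sum(bad), " habitat cells fall on land; habitat must be a subset of water",
         call. = FALSE)
  kernel <- circular_kernel(radius, habitat$cell_size)
  hab01 <- ifelse(!is.na(hab) & hab != 0 & water, 1L, 0L)
  n_hab <- focal_count(hab01, kernel, method)
  n_water <- focal_count(ifelse(water, 1L, 0L), kernel, method)
  x <- matrix(NA_real_, nrow(hab), ncol(hab))
  x[water] <- n_hab[water] / n_water[water]  # centre is water, so denom >= 1
  out <- raster_grid(x, habitat$cell_size)
  out$radius_m <- radius
  out
}
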