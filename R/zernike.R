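## Modal analysis of the pseudo-2D wavefront space on the unit disk.
##
## Crossed 1D modulators produce wavefronts of the separable form
## f(x, y) = g(x) + h(y). Restricted to polynomials up to order n on the unit
## disk this space is spanned by {1; x, y; x^2+y^2, x^2-y^2; ...; x^n+y^n,
## x^n-y^n}: 2n+1 modes, versus n(n+3)/2 for the full Zernike space.

#' Cartesian unit-disk integration grid
#'
#' Samples the unit disk on an `n x n` Cartesian grid. Pixels cut by the rim
#' receive a weight equal to their inside-area fraction (estimated by 16x16
#' subsampling); interior pixels have weight 1.
#'
#' @param n grid size per axis (default 512).
#' @return list with coordinate matrices `x`, `y`, weight matrix `w` and the
#'   scalar pixel area `da`.
#' @export
disk_grid <- function(n = 512) {
  xs <- (seq_len(n) - 0.5) / n * 2 - 1
  x <- matrix(xs, n, n)
  y <- t(x)
  px <- 2 / n
  r <- sqrt(x^2 + y^2)
  w <- matrix(0, n, n)
  w[r <= 1 - px] <- 1
  rim <- which(r > 1 - px & r < 1 + px)
  if (length(rim)) {
    sub <- (seq_len(16) - 0.5) / 16 - 0.5
    for (idx in rim) {
      cx <- x[idx]; cy <- y[idx]
      xx <- cx + sub * px
      yy <- cy + sub * px
      w[idx] <- mean(outer(xx^2, yy^2, `+`) <= 1)
    }
  }
  list(x = x, y = y, w = w, da = px^2)
}

disk_inner <- function(a, b, grid) sum(a * b * grid$w) * grid$da

#' Orthonormal pseudo-2D polynomial basis on the unit disk
#'
#' Gram-Schmidt orthonormalization (disk inner product, uniform weight) of
#' the separable monomial family `{1; x, y; x^2+y^2, x^2-y^2; ...}` ordered
#' by polynomial order, giving `2 * max_order + 1` modes including piston.
#' Order-1 and order-2 modes coincide with the Zernike modes of tilt, defocus
#' and vertical astigmatism; higher orders form the pseudo-coma (odd) and
#' pseudo-spherical / pseudo-astigmatism (even) groups.
#'
#' @param max_order highest polynomial order n (>= 1).
#' @param grid a [disk_grid()]; default 512 x 512.
#' @return object of class `ps2d_basis`: list of modes, each with `name`,
#'   `order`, `parity` (`"piston"`, `"tilt"`, `"symmetric"`,
#'   `"antisymmetric"`) and `values` (matrix on the disk grid, unit norm,
#'   zero outside the disk).
#' @export
build_ps2d_basis <- function(max_order, grid = disk_grid()) {
  if (max_order < 1) stop("max_order must be >= 1")
  x <- grid$x; y <- grid$y
  raw <- list(list(name = "piston", order = 0, parity = "piston",
                   values = matrix(1, nrow(x), ncol(x))))
  raw <- c(raw,
           list(list(name = "tilt_x", order = 1, parity = "tilt", values = x),
                list(name = "tilt_y", order = 1, parity = "tilt", values = y)))
  if (max_order >= 2) {
    for (k in 2:max_order) {
      nm <- if (k == 2) c("defocus", "vertical_astigmatism")
            else if (k %% 2 == 1) sprintf("ps_coma_%d_%s", k, c("sym", "antisym"))
            else sprintf(c("ps_spherical_%d", "ps_astigmatism_%d"), k)
      raw <- c(raw,
               list(list(name = nm[1], order = k, parity = "symmetric",
                         values = x^k + y^k),
                    list(name = nm[2], order = k, parity = "antisymmetric",
                         values = x^k - y^k)))
    }
  }
  modes <- list()
  for (m in raw) {
    v <- m$values
    for (p in modes) v <- v - disk_inner(v, p$values, grid) * p$values
    nrm <- sqrt(disk_inner(v, v, grid))
    if (nrm < 1e-12) stop("degenerate monomial family")
    m$values <- v / nrm * (grid$w > 0)
    modes <- c(modes, list(m))
  }
  structure(list(modes = modes, max_order = max_order, grid = grid),
            class = "ps2d_basis")
}

#' @export
print.ps2d_basis <- function(x, ...) {
  cat(sprintf("<ps2d_basis> %d modes up to order %d (grid %d^2)\n",
              length(x$modes), x$max_order, nrow(x$grid$x)))
  for (m in x$modes)
    cat(sprintf("  order %d %-13s %s\n", m$order, m$parity, m$name))
  invisible(x)
}

## Zernike radial polynomial R_n^m (m >= 0), standard closed form
zernike_radial <- function(n, m, r) {
  out <- 0
  for (k in 0:((n - m) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)) *
      r^(n - 2 * k)
  }
  out
}

## Zernike polynomial Z_n^m on the grid with unit-RMS (Noll) normalization
## over the disk; OSA sign convention: m > 0 cosine, m < 0 sine. Exact
## orthonormality on the discrete grid is restored later by a Loewdin step.
zernike_eval <- function(n, m, grid) {
  r <- sqrt(grid$x^2 + grid$y^2)
  th <- atan2(grid$y, grid$x)
  rad <- zernike_radial(n, abs(m), pmin(r, 1))
  ang <- if (m > 0) cos(m * th) else if (m < 0) sin(abs(m) * th) else 1
  nf <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  rad * ang * nf
}

zernike_index_table <- function(max_order) {
  idx <- do.call(rbind, lapply(0:max_order, function(n) {
    m <- seq(-n, n, by = 2)
    data.frame(n = n, m = m)
  }))
  idx
}

#' Zernike decomposition of a pseudo-2D mode
#'
#' Projects a disk-sampled mode onto the 2D Zernike polynomials up to
#' `max_zernike_order` using the numerical disk inner product. The Zernike
#' set is orthonormalized on the grid (symmetric Loewdin correction of the
#' analytic polynomials, which are already near-orthonormal), so Parseval
#' holds: for a unit-norm input, `sum(coefficients^2) + residual^2 = 1`.
#'
#' @param mode a mode from [build_ps2d_basis()] (or a matrix on the same
#'   grid).
#' @param max_zernike_order maximum radial degree.
#' @param grid the [disk_grid()] the mode is sampled on.
#' @return object of class `zernike_decomposition`: data.frame
#'   `coefficients` with columns `n`, `m`, `coefficient`, plus
#'   `residual`.
#' @export
zernike_decompose <- function(mode, max_zernike_order, grid = NULL) {
  if (is.list(mode) && !is.null(mode$values)) {
    values <- mode$values
  } else {
    values <- mode
  }
  if (is.null(grid)) stop("grid must be supplied (the grid the mode is sampled on)")
  if (nrow(values) != nrow(grid$x)) stop("mode and grid sizes differ")
  if (nrow(grid$x) < 16 * max_zernike_order)
    stop("grid too coarse for the requested Zernike order (resolution error)")
  idx <- zernike_index_table(max_zernike_order)
  nm <- nrow(idx)
  wv <- sqrt(grid$w * grid$da)
  z <- matrix(0, length(values), nm)
  for (j in seq_len(nm))
    z[, j] <- as.vector(zernike_eval(idx$n[j], idx$m[j], grid) * wv)
  # Loewdin orthonormalization on the grid: Z G^{-1/2}
  g <- crossprod(z)
  e <- eigen(g, symmetric = TRUE)
  ginvsqrt <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  zo <- z %*% ginvsqrt
  target_vec <- as.vector(values * wv)
  coef <- drop(crossprod(zo, target_vec))
  total <- sum(target_vec^2)
  residual <- sqrt(max(0, total - sum(coef^2)))
  structure(list(coefficients = data.frame(n = idx$n, m = idx$m, coefficient = coef),
                 residual = residual,
                 mode_name = if (is.list(mode)) mode$name else NULL),
            class = "zernike_decomposition")
}

#' @export
print.zernike_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<zernike_decomposition>%s residual %.3g\n",
              if (is.null(x$mode_name)) "" else paste0(" ", x$mode_name),
              x$residual))
  big <- x$coefficients[abs(x$coefficients$coefficient) > 1e-3, ]
  print(format(big, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Mode counts of the ps2D and Zernike spaces
#'
#' Number of orthogonal modes up to polynomial order n: `2n + 1` for the
#' pseudo-2D space (including piston) and `n(n + 3)/2` for the full Zernike
#' space (excluding piston).
#'
#' @param n polynomial order.
#' @return data.frame with `order`, `ps2d_modes`, `zernike_modes`.
#' @export
mode_counts <- function(n) {
  data.frame(order = n, ps2d_modes = 2 * n + 1, zernike_modes = n * (n + 3) / 2)
}
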