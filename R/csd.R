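# Spherical-spline surface Laplacian (current source density, CSD).
#
# A scalp potential map V sampled at electrodes is modeled as a spherical
# spline of order m:
#   s(E) = c0 + sum_i c_i g(cos(E, E_i)),
#   g(x) = (1/4pi) sum_{n>=1} (2n+1) / (n(n+1))^m P_n(x),
# with P_n the Legendre polynomials. The coefficients solve the regularized
# system (G + lambda I) c + c0 = V subject to sum(c) = 0. Because the
# surface Laplacian of P_n(cos theta) on the unit sphere is
# -n(n+1) P_n(cos theta), the Laplacian of the spline at electrode j is
# -sum_i c_i h(cos theta_ij) with
#   h(x) = (1/4pi) sum_{n>=1} (2n+1) / (n(n+1))^(m-1) P_n(x).
# CSD is reported with the usual sign convention (CSD = -Laplacian, sources
# positive), in arbitrary units of potential per squared sphere radius; the
# absolute scale cancels in baseline-normalized power.

# Legendre polynomials P_1..P_nmax at x, by the stable three-term recurrence
#' @noRd
legendre_terms <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pnm1 <- rep(1, length(x))   # P_0
  pn <- x                     # P_1
  out[, 1] <- pn
  for (n in 1:(nmax - 1)) {
    pnp1 <- ((2 * n + 1) * x * pn - n * pnm1) / (n + 1)
    out[, n + 1] <- pnp1
    pnm1 <- pn
    pn <- pnp1
  }
  out
}

#' @noRd
gh_series <- function(x, order_m, n_terms) {
  n <- seq_len(n_terms)
  P <- legendre_terms(x, n_terms)
  wg <- (2 * n + 1) / (n * (n + 1))^order_m / (4 * pi)
  wh <- (2 * n + 1) / (n * (n + 1))^(order_m - 1) / (4 * pi)
  list(g = drop(P %*% wg), h = drop(P %*% wh))
}

#' Build the spherical-spline basis for a montage
#'
#' Computes the electrode-by-electrode matrices `G` (g of the inter-electrode
#' angle cosines) and `H` (same with the Laplacian kernel h), the
#' regularized solve matrix, and the resulting linear CSD transform matrix.
#'
#' @param montage a `montage`.
#' @param order_m spline order (flexibility of the interpolating surface).
#' @param n_terms number of Legendre series terms.
#' @param lambda_reg Tikhonov regularization added to the diagonal of `G`.
#' @param channels electrode subset (default: the 64 scalp electrodes).
#' @return a `csd_basis`: `G`, `H`, `order_m`, `n_terms`, `lambda_reg`,
#'   `channels`, `transform` (matrix mapping potentials to CSD), and `solve_c`
#'   (matrix mapping potentials to spline coefficients c).
#' @export
build_csd_basis <- function(montage, order_m = 4, n_terms = 50,
                            lambda_reg = 1e-5, channels = montage$labels) {
  stopifnot(order_m >= 2, n_terms >= 2, length(channels) >= 3)
  P <- montage$pos[channels, , drop = FALSE]
  cosang <- P %*% t(P)
  cosang <- pmin(pmax(cosang, -1), 1)
  if (any(cosang[upper.tri(cosang)] > 1 - 1e-12))
    stop("duplicate electrode positions in montage")
  gh <- gh_series(as.vector(cosang), order_m, n_terms)
  n_e <- length(channels)
  G <- matrix(gh$g, n_e, n_e, dimnames = list(channels, channels))
  H <- matrix(gh$h, n_e, n_e, dimnames = list(channels, channels))

  # augmented system: [G + lambda I, 1; 1', 0] [c; c0] = [V; 0]
  A <- rbind(cbind(G + diag(lambda_reg, n_e), rep(1, n_e)),
             c(rep(1, n_e), 0))
  cond_est <- kappa(A, exact = FALSE)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop(sprintf("singular spline system (lambda = %g, condition estimate %.3g)",
                 lambda_reg, cond_est)))
  solve_c <- Ainv[seq_len(n_e), seq_len(n_e), drop = FALSE]  # V -> c
  # Laplacian of the spline is -H c (since the surface Laplacian of g is -h);
  # CSD uses the source-positive convention CSD = -Laplacian = +H c
  transform <- H %*% solve_c

  structure(
    list(G = G, H = H, order_m = order_m, n_terms = n_terms,
         lambda_reg = lambda_reg, channels = channels, pos = P,
         solve_c = solve_c, solve_c0 = Ainv[n_e + 1, seq_len(n_e)],
         transform = transform),
    class = "csd_basis"
  )
}

#' Evaluate the spline kernels g and h
#' @param x cosine of the angular distance, in [-1, 1].
#' @param order_m spline order; @param n_terms series terms.
#' @return list with `g` and `h` vectors.
#' @export
csd_kernels <- function(x, order_m = 4, n_terms = 50) {
  stopifnot(all(x >= -1), all(x <= 1))
  gh_series(x, order_m, n_terms)
}

#' Current-source-density transform of an epoch set
#'
#' Applies the precomputed linear spline transform per time sample. Output
#' is reference-free (adding a constant to all channels leaves it unchanged
#' up to regularization-level error) and linear in the input.
#'
#' @param epochs an `epoch_set` whose channels cover `basis$channels`.
#' @param basis a [build_csd_basis()] built for the same montage.
#' @return an `epoch_set` on `basis$channels` containing CSD values.
#' @export
csd_transform <- function(epochs, basis) {
  ch_idx <- match(basis$channels, epochs$channel_labels)
  if (anyNA(ch_idx))
    stop("epoch set lacks channels required by the CSD basis")
  d <- dim(epochs$data)
  n_e <- length(basis$channels)
  out <- epochs
  # flatten to channels x (trials*time) for one BLAS multiply
  x <- matrix(aperm(epochs$data[, ch_idx, , drop = FALSE], c(2, 1, 3)),
              nrow = n_e)
  y <- basis$transform %*% x
  out$data <- aperm(array(y, c(n_e, d[1], d[3])), c(2, 1, 3))
  out$channel_labels <- basis$channels
  out
}

#' Spherical-spline interpolation of a potential map
#'
#' Evaluates the fitted spline surface at arbitrary unit-sphere positions.
#' With `lambda_reg = 0` the surface reproduces the measured electrode
#' values.
#'
#' @param basis a `csd_basis`.
#' @param values potentials at `basis$channels` (vector).
#' @param query_positions matrix of unit-norm xyz rows, or electrode labels
#'   with `montage` given.
#' @param montage optional `montage` to resolve labels.
#' @return interpolated values at the query positions.
#' @export
interpolate_potential <- function(basis, values, query_positions,
                                  montage = NULL) {
  if (is.character(query_positions)) {
    stopifnot(!is.null(montage))
    query_positions <- montage$pos[query_positions, , drop = FALSE]
  }
  if (is.null(dim(query_positions)))
    query_positions <- matrix(query_positions, nrow = 1)
  nrm <- sqrt(rowSums(query_positions^2))
  stopifnot(all(abs(nrm - 1) < 1e-6))
  stopifnot(length(values) == length(basis$channels))
  cvec <- drop(basis$solve_c %*% values)
  c0 <- sum(basis$solve_c0 * values)
  E <- basis$pos
  cosang <- pmin(pmax(query_positions %*% t(E), -1), 1)
  gq <- matrix(gh_series(as.vector(cosang), basis$order_m, basis$n_terms)$g,
               nrow = nrow(query_positions))
  drop(c0 + gq %*% cvec)
}
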