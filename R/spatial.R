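## Spatial preprocessing: per-epoch linear detrending and the Perrin
## spherical-spline surface Laplacian re-reference.

#' Remove a least-squares straight line from every channel of every trial
#'
#' Fitted per channel-trial, so each output trace has (numerically) zero
#' mean and zero linear trend. Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return The detrended `epoch_set`.
#' @export
linear_detrend <- function(epochs) {
  d <- dim(epochs$data)
  if (d[3] < 2L) stop_invalid("need at least 2 samples per trial to detrend")
  x <- seq_len(d[3]) - (d[3] + 1) / 2       # centered time index
  sxx <- sum(x^2)
  out <- epochs
  for (i in seq_len(d[1])) {
    y <- epochs$data[i, , ]                  # channels x samples
    slope <- (y %*% x) / sxx
    out$data[i, , ] <- y - rowMeans(y) - tcrossprod(slope, x)
  }
  out
}

#' Spherical-spline parameters
#'
#' Constants of the spline system: `m` is the spline stiffness order,
#' `n_terms` the length of the Legendre series, `ridge` a diagonal
#' regularization added to the interpolation matrix. Defaults follow the
#' original formulation (m = 4) and common practice.
#'
#' @param m Stiffness order, integer >= 2 (default 4).
#' @param n_terms Legendre series length, >= 7 (default 50).
#' @param ridge Diagonal regularization, >= 0 (default 1e-5).
#' @return A `spline_params` list.
#' @export
spline_params <- function(m = 4, n_terms = 50, ridge = 1e-5) {
  if (m < 2) stop_invalid("`m` must be >= 2")
  if (n_terms < 7) stop_invalid("`n_terms` must be >= 7")
  if (ridge < 0) stop_invalid("`ridge` must be >= 0")
  structure(list(m = as.integer(m), n_terms = as.integer(n_terms), ridge = ridge),
            class = "spline_params")
}

## Legendre polynomials P_1..P_nmax at x (vector), via the three-term
## recurrence; returns a length(x) x nmax matrix.
legendre_terms <- function(x, nmax) {
  P <- matrix(0, length(x), nmax)
  P[, 1] <- x
  if (nmax >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  for (n in 2:(nmax - 1)) {
    if (n + 1 > nmax) break
    P[, n + 1] <- ((2 * n + 1) * x * P[, n] - n * P[, n - 1]) / (n + 1)
  }
  P
}

## g kernel: (1/4pi) sum (2n+1) / (n(n+1))^m P_n(x); h kernel uses the
## order-(m-1) weights. The surface Laplacian of P_n(cos theta) on the unit
## sphere is -n(n+1) P_n, so the Laplacian of the interpolant is -sum c_i h.
spline_kernels <- function(cosang, params) {
  n <- seq_len(params$n_terms)
  P <- legendre_terms(as.vector(cosang), params$n_terms)
  wg <- (2 * n + 1) / (n * (n + 1))^params$m
  wh <- (2 * n + 1) / (n * (n + 1))^(params$m - 1)
  g <- matrix(P %*% wg / (4 * pi), nrow = nrow(cosang))
  h <- matrix(P %*% wh / (4 * pi), nrow = nrow(cosang))
  list(g = g, h = h)
}

#' Surface-Laplacian transform matrix for a montage
#'
#' Solves the spherical-spline interpolation system (with the zero-sum
#' constraint on spline coefficients) symbolically: the returned matrix `T`
#' maps a vector of channel potentials to the surface Laplacian at the same
#' electrodes, so the operator is a single matrix multiply per time sample.
#' Sign convention: true differential operator (a focal positive potential
#' bump has a negative Laplacian at its peak); units are potential per
#' squared radian on the unit sphere.
#'
#' @param montage A [standard_montage()].
#' @param params A [spline_params()].
#' @return n x n transform matrix.
#' @export
laplacian_matrix <- function(montage, params = spline_params()) {
  pos <- montage$positions
  nch <- nrow(pos)
  cosang <- tcrossprod(pos)
  cosang[] <- pmin(1, pmax(-1, cosang))
  k <- spline_kernels(cosang, params)
  A <- rbind(cbind(k$g + diag(params$ridge, nch), rep(1, nch)),
             c(rep(1, nch), 0))
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop_invalid("singular spline interpolation matrix; increase `ridge` above 0")
  })
  ## c = Ainv[1:n, 1:n] %*% v (constraint row has zero right-hand side)
  T_ <- -k$h %*% Ainv[seq_len(nch), seq_len(nch)]
  dimnames(T_) <- list(montage$labels, montage$labels)
  T_
}

#' Spherical-spline surface Laplacian of an epoch set
#'
#' Re-references every time sample of every trial through the spline
#' Laplacian operator computed from the montage. Channel count and order are
#' unchanged. The operator is linear and invariant to a common offset across
#' channels (a spatially constant potential maps to ~0).
#'
#' @param epochs An `epoch_set`.
#' @param montage A [standard_montage()] covering all channels in `epochs`.
#' @param params A [spline_params()].
#' @return The re-referenced `epoch_set`.
#' @export
spherical_spline_laplacian <- function(epochs, montage = NULL,
                                       params = spline_params()) {
  if (is.null(montage)) montage <- standard_montage(epochs$channel_labels)
  missing_ch <- setdiff(epochs$channel_labels, montage$labels)
  if (length(missing_ch)) {
    stop_invalid(sprintf("montage does not cover channel(s): %s",
                         paste(missing_ch, collapse = ", ")))
  }
  ## restrict the montage to the epoch channels: the spline system is solved
  ## over exactly the electrodes whose potentials are observed
  mont_use <- structure(list(
    labels = epochs$channel_labels,
    positions = montage$positions[epochs$channel_labels, , drop = FALSE]
  ), class = "montage")
  T_ <- laplacian_matrix(mont_use, params)
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1])) {
    out$data[i, , ] <- T_ %*% epochs$data[i, , ]
  }
  out
}

#' Read a plain-text electrode coordinate file
#'
#' Format: one electrode per line, `label x y z`, whitespace-separated.
#' Positions are normalized to the unit sphere.
#'
#' @param path File path.
#' @return A `montage`.
#' @export
read_montage_file <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("label", "x", "y", "z"))
  pos <- as.matrix(df[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- df$label
  structure(list(labels = df$label, positions = pos), class = "montage")
}
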