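#' Probability product kernel between two MS/MS spectra
#'
#' Models each peak as a two-dimensional Gaussian in (m/z, intensity) with
#' standard deviations `sigma_m` (Daltons) and `sigma_i` (intensity units),
#' and integrates the product of the two spectrum densities:
#' \deqn{k(x, x') = \frac{1}{n_x n_{x'}} \frac{1}{4\pi\sigma_m\sigma_i}
#'   \sum_{\ell,\ell'} \exp\!\Big(-\frac{(m_\ell - m'_{\ell'})^2}{4\sigma_m^2}\Big)
#'   \exp\!\Big(-\frac{(i_\ell - i'_{\ell'})^2}{4\sigma_i^2}\Big)}
#' where \eqn{n_x} is the number of peaks in `x`. The value is strictly
#' positive and symmetric. By default each spectrum's intensities are rescaled
#' to maximum 1 before evaluation so that `sigma_i` is on a comparable scale
#' across spectra; set `rescale = FALSE` to use raw intensities.
#'
#' @param a,b [ms_spectrum()] objects.
#' @param params list or [ppk_params()] with positive elements `sigma_m`,
#'   `sigma_i`.
#' @param rescale rescale each spectrum's intensities to max 1 first.
#' @return scalar kernel value.
#' @export
ppk <- function(a, b, params, rescale = TRUE) {
  params <- ppk_params(params$sigma_m, params$sigma_i)
  pa <- a$peaks; pb <- b$peaks
  if (rescale) {
    pa[, 2L] <- rescale_to_unit_max(pa[, 2L])
    pb[, 2L] <- rescale_to_unit_max(pb[, 2L])
  }
  dm <- outer(pa[, 1L], pb[, 1L], "-")
  di <- outer(pa[, 2L], pb[, 2L], "-")
  s <- sum(exp(-dm^2 / (4 * params$sigma_m^2) - di^2 / (4 * params$sigma_i^2)))
  s / (nrow(pa) * nrow(pb)) / (4 * pi * params$sigma_m * params$sigma_i)
}

#' PPK parameters
#'
#' @param sigma_m,sigma_i strictly positive standard deviations on the
#'   mass-to-charge ratio (Daltons) and the intensity.
#' @export
ppk_params <- function(sigma_m, sigma_i) {
  if (!is.numeric(sigma_m) || length(sigma_m) != 1L || !is.finite(sigma_m) ||
      sigma_m <= 0) stopf("sigma_m must be a positive number")
  if (!is.numeric(sigma_i) || length(sigma_i) != 1L || !is.finite(sigma_i) ||
      sigma_i <= 0) stopf("sigma_i must be a positive number")
  structure(list(sigma_m = sigma_m, sigma_i = sigma_i), class = "ppk_params")
}

rescale_to_unit_max <- function(intensity) {
  m <- max(intensity)
  if (m > 0) intensity / m else intensity
}

#' Probability product kernel Gram matrix
#'
#' Computes all pairwise [ppk()] values between two spectrum collections in
#' one vectorized pass: peak lists are concatenated, the full peak-by-peak
#' Gaussian product matrix is formed, and per-spectrum-pair sums are obtained
#' by two grouped row sums. Entry `(i, j)` equals `ppk(rows[[i]], cols[[j]])`.
#'
#' @param rows,cols non-empty lists of [ms_spectrum()].
#' @param params [ppk_params()].
#' @param rescale as in [ppk()].
#' @return an uncentered, unnormalized [kernel_matrix()].
#' @export
ppk_matrix <- function(rows, cols = rows, params, rescale = TRUE) {
  params <- ppk_params(params$sigma_m, params$sigma_i)
  if (length(rows) == 0L || length(cols) == 0L) stopf("empty spectrum list")
  stack <- function(specs) {
    n <- vapply(specs, function(s) nrow(s$peaks), integer(1))
    mz <- unlist(lapply(specs, function(s) s$peaks[, 1L]), use.names = FALSE)
    it <- unlist(lapply(specs, function(s) {
      if (rescale) rescale_to_unit_max(s$peaks[, 2L]) else s$peaks[, 2L]
    }), use.names = FALSE)
    list(mz = mz, it = it, grp = rep(seq_along(specs), n), n = n,
         ids = vapply(specs, `[[`, character(1), "id"))
  }
  A <- stack(rows); B <- stack(cols)
  G <- exp(-outer(A$mz, B$mz, "-")^2 / (4 * params$sigma_m^2) -
             outer(A$it, B$it, "-")^2 / (4 * params$sigma_i^2))
  S <- rowsum(t(rowsum(G, A$grp, reorder = TRUE)), B$grp, reorder = TRUE)
  # S is now cols-by-rows of peak-pair sums
  K <- t(S) / outer(A$n, B$n) / (4 * pi * params$sigma_m * params$sigma_i)
  rownames(K) <- A$ids
  colnames(K) <- B$ids
  # exact symmetry for the self-Gram case, up to round-off
  kernel_matrix(K, row_ids = A$ids, col_ids = B$ids)
}
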