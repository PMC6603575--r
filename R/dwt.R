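# Periodized discrete wavelet transform and band energies.
#
# The band-energy features use a 4-level decomposition with the Daubechies
# 10 (db10, 20-tap) orthogonal filter pair. Periodization keeps the
# transform orthonormal, so the summed squared coefficients equal the
# squared signal energy; odd-length signals are zero-padded to even length
# at each level, which adds no energy and preserves that identity exactly.

# Daubechies-10 decomposition low-pass filter (orthonormal, 20 taps).
DB10_DEC_LO <- c(
  -1.3264202894521244e-05, 9.3588670320069592e-05, -1.1646685512928545e-04,
  -6.8585669495971162e-04, 1.9924052951850561e-03, 1.3953517470529011e-03,
  -1.0733175483330575e-02, 3.6065535669561697e-03, 3.3212674059341002e-02,
  -2.9457536821875813e-02, -7.1394147166397082e-02, 9.3057364603572348e-02,
  1.2736934033579325e-01, -1.9594627437737705e-01, -2.4984642432731538e-01,
  2.8117234366057747e-01, 6.8845903945360354e-01, 5.2720118893172563e-01,
  1.8817680007769150e-01, 2.6670057900555554e-02
)
# Quadrature-mirror high-pass counterpart.
DB10_DEC_HI <- rev(DB10_DEC_LO) * rep(c(-1, 1), length.out = 20L)

# One level of the periodized DWT. Returns list(cA, cD), each of length
# ceiling(length(x) / 2).
dwt_step_periodized <- function(x, lo = DB10_DEC_LO, hi = DB10_DEC_HI) {
  if (length(x) %% 2L == 1L) x <- c(x, 0)
  N <- length(x)
  L <- length(lo)
  half <- N %/% 2L
  # circular filtering, downsampled with the half-filter phase offset
  idx <- outer(2L * (seq_len(half) - 1L) + L %/% 2L, 0:(L - 1L), `-`) %% N + 1L
  xm <- matrix(x[idx], nrow = half)
  list(cA = drop(xm %*% lo), cD = drop(xm %*% hi))
}

#' Multi-level periodized db10 wavelet decomposition
#'
#' Decomposes a signal into detail coefficients `D1..Dlevels` and the final
#' approximation `Alevels` using the orthonormal db10 filter bank with
#' periodized boundaries (odd lengths zero-padded per level).
#'
#' @param values Numeric signal.
#' @param levels Number of decomposition levels (default 4).
#' @return Named list of coefficient vectors `d1`, ..., `d<levels>`,
#'   `a<levels>`.
#' @keywords internal
dwt_periodized <- function(values, levels = 4L) {
  if (!is.numeric(values) || length(values) < 2L^levels) {
    abort_bad_input(sprintf(
      "signal too short for a %d-level decomposition (need >= %d samples)",
      levels, 2L^levels))
  }
  if (any(!is.finite(values))) abort_bad_input("signal must be finite")
  out <- list()
  a <- values
  for (lev in seq_len(levels)) {
    st <- dwt_step_periodized(a)
    out[[paste0("d", lev)]] <- st$cD
    a <- st$cA
  }
  out[[paste0("a", levels)]] <- a
  out
}

#' Wavelet band energies
#'
#' Absolute and relative band energies of a 4-level db10 decomposition: for
#' each detail band D1..D4 and the approximation band A4, the absolute
#' energy is the sum of squared coefficients, the total energy is the sum of
#' the five absolute energies, and each relative energy is the band's share
#' of the total. With the periodized orthonormal transform the total energy
#' equals the squared signal energy. For an all-zero signal every relative
#' energy is defined as 0.
#'
#' @param values Numeric signal (at least `2^levels` samples; windows are
#'   151 samples in the smartphone pipeline).
#' @param wavelet_name Filter family; only `"db10"` is provided.
#' @param levels Decomposition depth (default 4).
#' @return A list of class `wavelet_energy_set` with elements `e_abs`
#'   (named numeric, `d1..d4`, `a4`), `e_rel` (same names) and `e_total`.
#' @examples
#' w <- wavelet_energy_features(sin(seq(0, 10, length.out = 151)))
#' sum(w$e_rel) # 1
#' @export
wavelet_energy_features <- function(values, wavelet_name = "db10", levels = 4L) {
  if (!identical(wavelet_name, "db10")) {
    abort_bad_input("only the db10 wavelet is supported")
  }
  coefs <- dwt_periodized(values, levels)
  e_abs <- vapply(coefs, function(v) sum(v^2), numeric(1))
  # order: d1..dL then aL (matches the decomposition tree)
  e_total <- sum(e_abs)
  e_rel <- if (e_total > 0) e_abs / e_total else e_abs * 0
  structure(list(e_abs = e_abs, e_rel = e_rel, e_total = e_total),
            class = "wavelet_energy_set")
}
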