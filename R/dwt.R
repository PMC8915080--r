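# Multilevel periodized orthogonal discrete wavelet transform.
#
# The WD augmentation needs an invertible multilevel DWT with perfect
# reconstruction. Filters are orthonormal, so with periodic (circular)
# boundary handling and an even signal length the single-level analysis
# operator is orthogonal and synthesis is its transpose. Signals are
# zero-padded to a multiple of 2^J (and to >= filter length at the deepest
# level) before analysis and truncated after synthesis, which keeps the
# round trip exact to machine precision.

# Orthonormal decomposition low-pass filters; high-pass and reconstruction
# filters follow from the quadrature-mirror relations.
WAVELET_BANK <- list(
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  db2 = c(-0.12940952255092145, 0.22414386804185735, 0.836516303737469,
          0.48296291314469025),
  db4 = c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
)

wavelet_filters <- function(wavelet) {
  lo <- WAVELET_BANK[[wavelet]]
  if (is.null(lo)) stopf("unknown wavelet '%s'", wavelet)
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(dec_lo = lo, dec_hi = hi, length = L)
}

# One analysis level on an even-length vector with circular extension:
# a_k = sum_m lo[m] x[(2k + m) mod n]  (k = 0 .. n/2 - 1), likewise d_k.
dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(flt$length)) {
    idx <- ((2L * (seq_len(half) - 1L) + (m - 1L)) %% n) + 1L
    a <- a + flt$dec_lo[m] * x[idx]
    d <- d + flt$dec_hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# Transpose (exact inverse) of dwt_step. Within one filter tap the target
# indices are distinct (stride-2 shifts mod n), so plain indexed addition
# accumulates correctly.
idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  for (m in seq_len(flt$length)) {
    idx <- ((2L * (seq_len(half) - 1L) + (m - 1L)) %% n) + 1L
    x[idx] <- x[idx] + flt$dec_lo[m] * a + flt$dec_hi[m] * d
  }
  x
}

#' Multilevel periodized DWT of a vector
#'
#' Decomposes `x` to depth `level`, zero-padding to the working length
#' `2^level * max(ceiling(n / 2^level), filter_length)` first. Returns detail
#' coefficients `d1` (finest) .. `d<level>` and the final approximation `a`.
#' The transform is orthogonal, so [wave_reconstruct()] inverts it exactly
#' and zero-padding round-trips to the original samples.
#'
#' @param x Numeric vector.
#' @param wavelet One of `"sym4"`, `"db2"`, `"db4"`.
#' @param level Decomposition depth (>= 1). Limited, as is conventional, to
#'   `floor(log2(n / (filter_length - 1)))`.
#' @return A list with `a`, `d` (list of detail vectors, finest first), the
#'   original length `n`, `wavelet` and `level`.
#' @export
wave_decompose <- function(x, wavelet = "sym4", level = 3L) {
  flt <- wavelet_filters(wavelet)
  n <- length(x)
  if (!is_count(level)) stopf("'level' must be a positive integer")
  max_level <- floor(log2(n / (flt$length - 1)))
  if (level > max_level)
    stopf("sequence of length %d supports at most %d decomposition level(s) for %s",
          n, max(max_level, 0), wavelet)
  work_n <- 2L^level * max(ceiling(n / 2L^level), flt$length)
  xp <- c(x, numeric(work_n - n))
  d <- vector("list", level)
  a <- xp
  for (l in seq_len(level)) {
    st <- dwt_step(a, flt)
    a <- st$a
    d[[l]] <- st$d
  }
  list(a = a, d = d, n = n, wavelet = wavelet, level = level)
}

#' @rdname wave_decompose
#' @param dec A decomposition produced by [wave_decompose()] (detail
#'   coefficients may have been modified).
#' @export
wave_reconstruct <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$a
  for (l in rev(seq_len(dec$level))) a <- idwt_step(a, dec$d[[l]], flt)
  a[seq_len(dec$n)]
}
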