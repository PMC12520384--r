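# Scrambled Sobol' low-discrepancy sequences.
#
# Direction numbers are the Joe--Kuo D(6) set for dimensions up to 10, which
# covers every parameter space used by the package (the two virtual-population
# presets have 9 and 10 sampled dimensions; perturbation boxes have 4).
# Scrambling combines a random lower-triangular linear matrix scramble of the
# direction numbers with a random digital shift, both drawn deterministically
# from the supplied seed, so scrambled points keep the digital-net structure
# while being seed-reproducible.

# Joe-Kuo primitive polynomials (degree s, interior coefficients a) and
# initial direction integers m for dimensions 2..10; dimension 1 is the
# van der Corput sequence in base 2.
.sobol_dirdata <- list(
  list(s = 1L, a = 0L,  m = c(1L)),
  list(s = 2L, a = 1L,  m = c(1L, 3L)),
  list(s = 3L, a = 1L,  m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L,  m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L,  m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L,  m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L,  m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L,  m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L,  m = c(1L, 1L, 7L, 11L, 19L))
)

.SOBOL_BITS <- 31L

# 31 direction integers v_k = m_k * 2^(31-k) for one dimension
.sobol_directions <- function(dim) {
  nb <- .SOBOL_BITS
  m <- integer(nb)
  if (dim == 1L) {
    m[] <- 1L
  } else {
    dd <- .sobol_dirdata[[dim - 1L]]
    s <- dd$s
    m[seq_len(s)] <- dd$m
    if (nb > s) {
      for (k in (s + 1L):nb) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        for (i in seq_len(s - 1L)) {
          ai <- bitwAnd(bitwShiftR(dd$a, s - 1L - i), 1L)
          if (ai == 1L) mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
        }
        m[k] <- mk
      }
    }
  }
  bitwShiftL(m, nb - seq_len(nb))
}

# parity of the number of set bits in a 31-bit integer
.bit_parity <- function(x) {
  x <- bitwXor(x, bitwShiftR(x, 16L))
  x <- bitwXor(x, bitwShiftR(x, 8L))
  x <- bitwXor(x, bitwShiftR(x, 4L))
  x <- bitwXor(x, bitwShiftR(x, 2L))
  x <- bitwXor(x, bitwShiftR(x, 1L))
  bitwAnd(x, 1L)
}

# apply a random lower-triangular GF(2) matrix (unit diagonal) to each
# direction integer of one dimension
.lms_scramble <- function(v) {
  nb <- .SOBOL_BITS
  # rows[r] holds the r-th row of the scrambling matrix packed as an integer;
  # bit (nb - r) is the diagonal, higher bits (more significant) are free.
  rows <- integer(nb)
  for (r in seq_len(nb)) {
    diag_bit <- bitwShiftL(1L, nb - r)
    free <- 0L
    if (r > 1L) {
      # random bits in positions nb-1 .. nb-r+1 (columns left of the diagonal)
      rb <- sample(c(0L, 1L), r - 1L, replace = TRUE)
      for (j in seq_len(r - 1L)) {
        if (rb[j] == 1L) free <- bitwOr(free, bitwShiftL(1L, nb - j))
      }
    }
    rows[r] <- bitwOr(diag_bit, free)
  }
  vapply(v, function(vk) {
    out <- 0L
    for (r in seq_len(nb)) {
      if (.bit_parity(bitwAnd(rows[r], vk)) == 1L) {
        out <- bitwOr(out, bitwShiftL(1L, nb - r))
      }
    }
    out
  }, integer(1))
}

#' Scrambled Sobol' points in the unit hypercube
#'
#' Generates `n` quasi-random points in `[0, 1)^d` from a Sobol' sequence,
#' optionally randomized by a linear matrix scramble plus digital shift.
#' Given the same `seed` the point set is fully reproducible.
#'
#' @param n Number of points (power-of-two sizes give the best uniformity).
#' @param d Dimension, at most 10.
#' @param seed Integer seed controlling the scrambling.
#' @param scramble Logical; unscrambled points are the raw Sobol' sequence
#'   (first point at the origin).
#' @return An `n x d` numeric matrix with entries in `[0, 1)`.
#' @examples
#' u <- sobol_points(128, 2, seed = 1)
#' colMeans(u)  # close to 0.5
#' @export
sobol_points <- function(n, d, seed = 1L, scramble = TRUE) {
  stopifnot(n >= 1, d >= 1)
  if (d > 10L) {
    stop("sobol_points supports at most 10 dimensions")
  }
  n <- as.integer(n)
  d <- as.integer(d)
  V <- vapply(seq_len(d), .sobol_directions, integer(.SOBOL_BITS))
  shift <- integer(d)
  if (scramble) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    for (j in seq_len(d)) {
      V[, j] <- .lms_scramble(V[, j])
      bits <- sample(c(0L, 1L), .SOBOL_BITS, replace = TRUE)
      s <- 0L
      for (b in seq_len(.SOBOL_BITS)) {
        if (bits[b] == 1L) s <- bitwOr(s, bitwShiftL(1L, b - 1L))
      }
      shift[j] <- s
    }
  }
  out <- matrix(0L, n, d)
  state <- integer(d)
  out[1, ] <- state
  if (n > 1L) {
    for (i in 2:n) {
      # Gray-code index: position of lowest zero bit of i - 2
      k <- i - 2L
      c <- 1L
      while (bitwAnd(k, 1L) == 1L) {
        k <- bitwShiftR(k, 1L)
        c <- c + 1L
      }
      state <- bitwXor(state, V[c, ])
      out[i, ] <- state
    }
  }
  if (scramble) out <- matrix(bitwXor(as.vector(out), rep(shift, each = n)), n, d)
  out / 2^.SOBOL_BITS
}
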