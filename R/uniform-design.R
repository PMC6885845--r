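# Good-lattice-point uniform arrays and the uniform-design operators:
# the subspace swarm initializer and the quantized crossover.

# The sigma table for the good-lattice-point construction: for each prime
# level count q, disjoint factor-count ranges and the generator sigma to use.
# Factor counts above the largest tabulated range are clamped to it (the
# construction stays level-balanced for any exponent when q is prime).
sigma_table <- list(
  "5"  = list(list(range = 2:4, sigma = 2L)),
  "7"  = list(list(range = 2:6, sigma = 3L)),
  "11" = list(list(range = 2:10, sigma = 7L)),
  "13" = list(list(range = 2L, sigma = 5L),
              list(range = 3L, sigma = 4L),
              list(range = 4:12, sigma = 6L)),
  "17" = list(list(range = 2:16, sigma = 10L)),
  "19" = list(list(range = 2:3, sigma = 8L),
              list(range = 4:18, sigma = 14L)),
  "23" = list(list(range = c(2L, 13:14, 20:22), sigma = 7L),
              list(range = 8:12, sigma = 15L),
              list(range = c(3:7, 15:19), sigma = 17L)),
  "29" = list(list(range = 2L, sigma = 12L),
              list(range = 3L, sigma = 9L),
              list(range = 4:7, sigma = 16L),
              list(range = c(8:12, 16:24), sigma = 8L),
              list(range = 13:15, sigma = 14L),
              list(range = 25:28, sigma = 18L)),
  "31" = list(list(range = c(2L, 5:12, 20:30), sigma = 12L),
              list(range = c(3:4, 13:19), sigma = 22L))
)

#' Supported level counts for uniform arrays
#'
#' The prime level counts q for which a generator sigma is tabulated.
#'
#' @return Integer vector of primes.
#' @export
ud_levels <- function() as.integer(names(sigma_table))

#' Look up the uniform-array generator sigma
#'
#' Returns the generator \eqn{\sigma} for a `q`-level uniform array with `n`
#' factors. Factor counts above the tabulated maximum (`q - 1`) are clamped
#' to it, so high-dimensional arrays reuse the generator of the widest
#' tabulated range.
#'
#' @param q Prime level count; one of [ud_levels()].
#' @param n Number of factors, at least 2.
#' @return Integer sigma.
#' @examples
#' sigma_lookup(5, 3)   # 2
#' sigma_lookup(13, 2)  # 5
#' @export
sigma_lookup <- function(q, n) {
  rows <- sigma_table[[as.character(q)]]
  if (is.null(rows)) {
    stop("unsupported level count q = ", q,
         "; supported: ", paste(ud_levels(), collapse = ", "))
  }
  if (n < 2L) stop("factor count n must be at least 2")
  n <- min(as.integer(n), as.integer(q) - 1L)
  for (row in rows) {
    if (n %in% row$range) return(row$sigma)
  }
  stop("no sigma tabulated for q = ", q, ", n = ", n)  # unreachable: ranges cover 2..q-1
}

#' Construct a good-lattice-point uniform array
#'
#' Builds the q x n level matrix \eqn{U(n, q)} with
#' \eqn{U_{l_1 l_2} = (l_1 \cdot \sigma^{l_2 - 1} \bmod q) + 1} for
#' \eqn{l_1 = 1..q}, \eqn{l_2 = 1..n}. Powers of sigma are reduced modulo q
#' iteratively, so arbitrarily many factors are supported without overflow.
#' Because q is prime, multiplication by any nonzero residue is a bijection
#' of \eqn{\{1..q\}}: every column is a permutation of the q levels. The
#' first column is always `(2, 3, ..., q, 1)` since \eqn{\sigma^0 = 1}.
#'
#' @param n Number of factors (columns), at least 1.
#' @param q Prime level count; one of [ud_levels()].
#' @return Object of class `uniform_array`: list with `q`, `n`, `sigma`, and
#'   the `levels` matrix.
#' @examples
#' uniform_array(2, 5)$levels
#' @export
uniform_array <- function(n, q) {
  n <- as.integer(n)
  q <- as.integer(q)
  if (n < 1L) stop("factor count n must be at least 1")
  sigma <- sigma_lookup(q, max(2L, n))
  levels <- matrix(0L, q, n)
  pow <- 1L
  for (j in seq_len(n)) {
    levels[, j] <- ((seq_len(q) * pow) %% q) + 1L
    pow <- (pow * sigma) %% q
  }
  structure(list(q = q, n = n, sigma = sigma, levels = levels),
            class = "uniform_array")
}

#' @export
print.uniform_array <- function(x, ...) {
  cat(sprintf("uniform array U(%d, %d), sigma = %d\n", x$n, x$q, x$sigma))
  print(x$levels)
  invisible(x)
}

# Map a uniform array onto a box: row l1 of the result is the l1-th design
# point, with levels 1 and q on the box faces.
array_to_points <- function(levels, lower, upper) {
  q <- nrow(levels)
  d <- ncol(levels)
  lo <- matrix(lower, q, d, byrow = TRUE)
  span <- matrix(upper - lower, q, d, byrow = TRUE)
  lo + (levels - 1L) / (q - 1L) * span
}

# Internal: the S * Q0 candidate design points of the subspace initializer
# as one matrix (used both by ud_initialize and by the optimizer's batched
# evaluation path).
ud_candidates <- function(d, S, Q0, lower, upper) {
  levels <- uniform_array(d, Q0)$levels
  nbits <- as.integer(round(log2(S)))
  cand <- vector("list", S)
  for (s in seq_len(S) - 1L) {
    lo <- lower
    up <- upper
    if (nbits > 0L) {
      for (b in seq_len(nbits)) {
        dim_b <- ((b - 1L) %% d) + 1L
        mid <- (lo[dim_b] + up[dim_b]) / 2
        if (bitwAnd(s, bitwShiftL(1L, b - 1L)) == 0L) {
          up[dim_b] <- mid
        } else {
          lo[dim_b] <- mid
        }
      }
    }
    cand[[s + 1L]] <- array_to_points(levels, lo, up)
  }
  do.call(rbind, cand)
}

#' Uniform-design swarm initialization
#'
#' Builds an initial swarm whose particles are scattered evenly over the
#' search box. The box is bisected into `S` sub-boxes (recursive halving
#' along the leading dimensions, cycling when the dimension is smaller than
#' `log2(S)`); in each sub-box the `Q0`-level uniform array over `d` factors
#' places `Q0` candidate points, levels 1 and `Q0` hitting the sub-box faces.
#' All `S * Q0` candidates are scored with `fitness` and the best `npop` are
#' returned. The procedure is fully deterministic for a deterministic
#' evaluator.
#'
#' @param d Search-space dimension.
#' @param S Number of sub-boxes; a power of two.
#' @param Q0 Candidates per sub-box; a prime in [ud_levels()].
#' @param npop Swarm size; requires `S * Q0 >= npop`.
#' @param lower,upper Box bounds, length-d numeric vectors.
#' @param fitness Function mapping a length-d position vector to a scalar
#'   score (larger is better).
#' @return List with `positions` (npop x d matrix, best first), `fitness`
#'   (their scores), and `n_candidates` (`S * Q0`).
#' @export
ud_initialize <- function(d, S, Q0, npop, lower = rep(0, d),
                          upper = rep(1, d), fitness) {
  d <- as.integer(d)
  S <- as.integer(S)
  if (S < 1L || bitwAnd(S, S - 1L) != 0L) stop("S must be a power of two")
  if (S * Q0 < npop) {
    stop(sprintf("configuration error: S * Q0 = %d < npop = %d", S * Q0, npop))
  }
  if (length(lower) != d || length(upper) != d || any(lower > upper)) {
    stop("invalid bounds")
  }
  cand <- ud_candidates(d, S, Q0, lower, upper)
  scores <- apply(cand, 1L, fitness)
  keep <- order(scores, decreasing = TRUE)[seq_len(npop)]
  list(positions = cand[keep, , drop = FALSE], fitness = scores[keep],
       n_candidates = nrow(cand))
}

#' Uniform-design crossover
#'
#' Quantizes the box spanned by two parent vectors into `Q1` equally spaced
#' levels per dimension (ascending from the componentwise minimum to the
#' maximum) and selects `Q1` offspring through the `Q1`-level uniform array:
#' offspring `l1` takes level \eqn{U_{l_1, i}} in dimension i. The operator
#' is deterministic, symmetric in its parents, and every offspring lies
#' inside the parents' box; identical parents reproduce themselves.
#'
#' @param parent1,parent2 Numeric vectors of equal length d.
#' @param Q1 Offspring count; a prime in [ud_levels()].
#' @return Q1 x d matrix, one offspring per row.
#' @examples
#' ud_crossover(rep(0, 1), rep(1, 1), 5)
#' @export
ud_crossover <- function(parent1, parent2, Q1) {
  d <- length(parent1)
  if (length(parent2) != d) stop("dimension mismatch between parents")
  levels <- uniform_array(d, Q1)$levels
  ud_offspring(parent1, parent2, levels)
}

# Internal: crossover with a precomputed level matrix (hot path).
ud_offspring <- function(parent1, parent2, levels) {
  lo <- pmin(parent1, parent2)
  hi <- pmax(parent1, parent2)
  off <- array_to_points(levels, lo, hi)
  # guard offspring against rounding outside the parents' box
  q <- nrow(levels)
  lo_m <- matrix(lo, q, length(lo), byrow = TRUE)
  hi_m <- matrix(hi, q, length(hi), byrow = TRUE)
  pmin(pmax(off, lo_m), hi_m)
}
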