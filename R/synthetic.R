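# Planted-partition generator for correlation-like connectivity matrices.
# Gives every stage of the pipeline a ground truth without any download:
# block-structured symmetric weights in [0, 1], optionally re-encoded as
# Fisher z values so the preprocessing chain can be round-trip tested.

#' Specification of a planted-partition connectome
#'
#' Within-block weights are drawn from Normal(`w_in_mean`, `w_in_sd`) and
#' between-block weights from Normal(`w_out_mean`, `w_out_sd`), both clipped
#' to \[0, 1\]. The defaults (0.7 / 0.1 means, sd 0.05) emulate a strongly
#' modular correlation matrix: thresholding at theta = 0.2 removes nearly
#' all between-block weight while leaving blocks intact.
#'
#' @param block_sizes Integer vector of community sizes (each >= 1).
#' @param w_in_mean,w_in_sd Within-block weight distribution; mean in \[0, 1\].
#' @param w_out_mean,w_out_sd Between-block weight distribution.
#' @param seed Optional integer seed for reproducible draws.
#' @return Object of class `planted_spec`.
#' @export
planted_spec <- function(block_sizes, w_in_mean = 0.7, w_in_sd = 0.05,
                         w_out_mean = 0.1, w_out_sd = 0.05, seed = NULL) {
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) < 1L || any(block_sizes < 1L)) {
    stop("block sizes must be positive integers")
  }
  if (sum(block_sizes) < 2L) stop("total size must be at least 2")
  for (m in c(w_in_mean, w_out_mean)) {
    if (m < 0 || m > 1) stop("weight means must lie in [0, 1]")
  }
  if (w_in_sd < 0 || w_out_sd < 0) stop("weight sds must be nonnegative")
  structure(list(block_sizes = block_sizes,
                 w_in_mean = w_in_mean, w_in_sd = w_in_sd,
                 w_out_mean = w_out_mean, w_out_sd = w_out_sd,
                 seed = seed),
            class = "planted_spec")
}

#' Generate a planted-partition correlation-like matrix
#'
#' Draws a symmetric weight matrix with zero diagonal whose upper-triangle
#' entries follow the within/between-block distributions of `spec`, clipped
#' to \[0, 1\], and returns it as a [weighted_graph()] together with the
#' planted [partition()] (canonical 0-based labels). Reproducible for a
#' fixed `spec$seed`.
#'
#' @param spec A [planted_spec()].
#' @return List with `graph` and `partition`.
#' @export
generate_planted_pcm <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- sum(spec$block_sizes)
  labels0 <- rep(seq_along(spec$block_sizes) - 1L, spec$block_sizes)
  same <- outer(labels0, labels0, `==`)
  iu <- upper.tri(same)
  n_edge <- sum(iu)
  is_in <- same[iu]
  w <- stats::rnorm(n_edge,
                    mean = ifelse(is_in, spec$w_in_mean, spec$w_out_mean),
                    sd = ifelse(is_in, spec$w_in_sd, spec$w_out_sd))
  w <- pmin(pmax(w, 0), 1)
  a <- matrix(0, n, n)
  a[iu] <- w
  a <- a + t(a)
  list(graph = weighted_graph(a), partition = partition(labels0))
}

#' Generate a Fisher z-encoded planted connectivity matrix
#'
#' Applies the forward Fisher z-transform `artanh(x)` entrywise to the
#' planted weight matrix of `spec` (entries are clipped to 0.999 first so
#' the transform stays finite) and returns it as a raw
#' [connectivity_matrix()]. Running [preprocess_cm()] with
#' `apply_reverse_z = TRUE` recovers the thresholded planted matrix, making
#' the whole preprocessing chain round-trip testable. The matching ground
#' truth is `generate_planted_pcm(spec)` with the same seed.
#'
#' @param spec A [planted_spec()].
#' @return A [connectivity_matrix()] of z values.
#' @export
generate_z_cm <- function(spec) {
  planted <- generate_planted_pcm(spec)
  connectivity_matrix(atanh(pmin(planted$graph$adjacency, 0.999)))
}
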