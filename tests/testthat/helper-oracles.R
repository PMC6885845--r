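# Independent oracles and fixture builders.  These never call the package's
# fast paths: modularity and conductance are computed by direct summation
# over ordered vertex pairs, and the optimizer oracle enumerates every set
# partition of a small vertex set.

# Direct evaluation of Q = (1/2m) sum_ij (a_ij - k_i k_j / 2m) delta(i, j)
# over all ordered pairs including i == j.
brute_modularity <- function(A, labels0) {
  n <- nrow(A)
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels0[i] == labels0[j]) {
        q <- q + A[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# Direct conductance: average over nonempty clusters of
# cut(C) / min(vol(C), vol(complement)); 0/0 scores 0; K' = 1 scores 0.
brute_conductance <- function(A, labels0) {
  k <- rowSums(A)
  m2 <- sum(k)
  ids <- unique(labels0)
  if (length(ids) == 1L) return(0)
  phis <- vapply(ids, function(c) {
    inside <- labels0 == c
    cutw <- sum(A[inside, !inside, drop = FALSE])
    vol <- sum(k[inside])
    denom <- min(vol, m2 - vol)
    if (denom > 0) cutw / denom else 0
  }, numeric(1))
  mean(phis)
}

# All set partitions of n elements as restricted-growth strings (0-based),
# one partition per list element.
all_set_partitions <- function(n) {
  parts <- list(0L)
  if (n == 1L) return(parts)
  for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(0:(max(p) + 1L), function(v) c(p, v))
    }), recursive = FALSE)
  }
  parts
}

# Exhaustive maximum modularity over every set partition (independent of the
# package's optimizer and of its modularity fast path).
exhaustive_max_modularity <- function(A) {
  best <- -Inf
  for (p in all_set_partitions(nrow(A))) {
    q <- brute_modularity(A, p)
    if (q > best) best <- q
  }
  best
}

# Seeded random symmetric weighted graph: each edge present with probability
# p, weights uniform on [0.2, 1] (so thresholding at 0.2 keeps them all).
random_weighted_graph <- function(n, p = 0.6, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    iu <- which(upper.tri(A))
    present <- stats::runif(length(iu)) < p
    A[iu[present]] <- stats::runif(sum(present), 0.2, 1)
    A <- A + t(A)
    if (sum(A) > 0) return(weighted_graph(A))
  }
}

random_partition <- function(n, K) {
  partition(sample.int(K, n, replace = TRUE) - 1L, K = K)
}

two_edge_graph <- function() {
  weighted_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                       c(0, 0, 0, 1), c(0, 0, 1, 0)))
}

four_cycle_graph <- function() {
  weighted_graph(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                       c(0, 1, 0, 1), c(1, 0, 1, 0)))
}

two_triangles_graph <- function() {
  A <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  weighted_graph(A)
}

# A thresholded planted-partition benchmark graph plus its ground truth.
planted_benchmark <- function(block_sizes = c(12, 12, 12), seed = 1,
                              w_out_mean = 0.1, w_out_sd = 0.05,
                              theta = 0.2) {
  sp <- planted_spec(block_sizes, w_out_mean = w_out_mean,
                     w_out_sd = w_out_sd, seed = seed)
  pl <- generate_planted_pcm(sp)
  a <- pl$graph$adjacency
  a[a < theta] <- 0
  list(graph = weighted_graph(a), partition = pl$partition)
}
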