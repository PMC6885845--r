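# Partition-quality metrics: modularity (pairwise and trace forms),
# conductance, and normalized mutual information.

# Internal fast path shared with the optimizer: modularity from 1-based
# labels.  Groups the adjacency twice with rowsum(); within[c,c] is the sum
# of a_ij over ordered pairs inside community c (the zero diagonal only
# contributes through the null-model term).
modularity_from_labels <- function(lab, A, degrees, m2) {
  within <- rowsum(t(rowsum(A, lab)), lab)
  vol <- rowsum(degrees, lab)[, 1L]
  sum(diag(within)) / m2 - sum(vol^2) / (m2 * m2)
}

conductance_from_labels <- function(lab, A, degrees, m2) {
  vol <- rowsum(degrees, lab)[, 1L]
  if (length(vol) == 1L) return(0)
  within <- diag(rowsum(t(rowsum(A, lab)), lab))
  cutw <- vol - within
  denom <- pmin(vol, m2 - vol)
  phi <- ifelse(denom > 0, cutw / denom, 0)
  mean(pmin(pmax(phi, 0), 1))  # guard rounding at the phi = 1 boundary
}

check_graph_partition <- function(graph, p) {
  if (!inherits(graph, "weighted_graph")) stop("graph must be a weighted_graph")
  p <- as_partition(p)
  if (p$n != graph$n) stop("partition length must equal vertex count")
  if (graph$total_weight <= 0) stop("empty graph: total edge weight is zero")
  p
}

#' Modularity of a partition
#'
#' Newman's weighted modularity
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left( a_{ij} - \frac{k_i k_j}{2m} \right)
#'   \delta(i, j),}
#' where the sum runs over all ordered vertex pairs (including \eqn{i = j};
#' the diagonal is zero after preprocessing, so it contributes only through
#' the null-model term), \eqn{k_i} is the weighted degree, and \eqn{m} the
#' total edge weight. \eqn{Q \in [-1, 1)}; the single-community partition
#' scores exactly 0.
#'
#' @param graph A [weighted_graph()].
#' @param p A [partition()] or 0-based label vector.
#' @return Scalar modularity Q.
#' @examples
#' g <- weighted_graph(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
#'                           c(0, 0, 0, 1), c(0, 0, 1, 0)))
#' modularity_q(g, c(0, 0, 1, 1))  # 0.5
#' @export
modularity_q <- function(graph, p) {
  p <- check_graph_partition(graph, p)
  modularity_from_labels(p$labels + 1L, graph$adjacency, graph$degrees,
                         2 * graph$total_weight)
}

#' Modularity matrix
#'
#' The matrix \eqn{B_{ij} = a_{ij} - k_i k_j / (2m)}. It is symmetric and
#' every row sums to zero, since \eqn{\sum_j a_{ij} = k_i} and
#' \eqn{\sum_j k_j = 2m}.
#'
#' @param graph A [weighted_graph()].
#' @return N x N numeric matrix.
#' @export
modularity_matrix <- function(graph) {
  if (graph$total_weight <= 0) stop("empty graph: total edge weight is zero")
  k <- graph$degrees
  graph$adjacency - outer(k, k) / (2 * graph$total_weight)
}

#' Modularity via the trace form
#'
#' Computes \eqn{Q = \frac{1}{2m} \mathrm{Trace}(X^T B X)} with the 0/1
#' assignment matrix X (`x_ih = 1` iff vertex i is in community h) and the
#' modularity matrix B. Algebraically identical to [modularity_q()]; kept as
#' an independent route for cross-checking.
#'
#' @inheritParams modularity_q
#' @export
modularity_trace <- function(graph, p) {
  p <- check_graph_partition(graph, p)
  B <- modularity_matrix(graph)
  X <- matrix(0, graph$n, p$K)
  X[cbind(seq_len(graph$n), p$labels + 1L)] <- 1
  sum(diag(t(X) %*% B %*% X)) / (2 * graph$total_weight)
}

#' Conductance of a partition
#'
#' For a cluster C, \eqn{\phi(C) = \mathrm{cut}(C) / \min(\mathrm{vol}(C),
#' \mathrm{vol}(\bar C))} with \eqn{\mathrm{cut}(C) = \sum_{i \in C, j \notin
#' C} a_{ij}} and \eqn{\mathrm{vol}(C) = \sum_{i \in C} k_i}. The partition
#' score is the average of \eqn{\phi} over the nonempty clusters; clusters
#' with zero volume contribute 0 (0/0 convention) and the single-cluster
#' partition scores 0 by convention. Lower is better; the result lies in
#' \[0, 1\].
#'
#' @inheritParams modularity_q
#' @return Scalar conductance in \[0, 1\].
#' @export
conductance <- function(graph, p) {
  p <- check_graph_partition(graph, p)
  conductance_from_labels(p$labels + 1L, graph$adjacency, graph$degrees,
                          2 * graph$total_weight)
}

#' Normalized mutual information between two partitions
#'
#' NMI with geometric-mean normalization:
#' \eqn{I(P, Q) / \sqrt{H(P) H(Q)}}. Equals 1 iff the partitions are
#' identical up to a relabelling of communities. When exactly one side has a
#' single community (zero entropy) the score is 0; when both do, the
#' partitions coincide and the score is 1.
#'
#' @param p,q Partitions (or 0-based label vectors) over the same vertices.
#' @return Scalar in \[0, 1\].
#' @export
nmi <- function(p, q) {
  p <- as_partition(p)
  q <- as_partition(q)
  if (p$n != q$n) stop("partitions must have equal length")
  joint <- table(p$labels, q$labels) / p$n
  px <- rowSums(joint)
  py <- colSums(joint)
  hx <- -sum(px * log(px))
  hy <- -sum(py * log(py))
  if (hx == 0 && hy == 0) return(1)
  if (hx == 0 || hy == 0) return(0)
  expected <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / expected[nz]))
  max(0, min(1, mi / sqrt(hx * hy)))
}
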