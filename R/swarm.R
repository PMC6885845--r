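# The UPSO community-detection optimizer and its uniform-design-free PSO
# ablation.  A particle's position is the concatenation of K community
# centroids, each a length-N vector in [0, 1]; a position decodes to a
# partition by assigning every vertex to the centroid nearest (in Euclidean
# distance) to its adjacency row.  Fitness is the modularity of the decoded
# partition.

#' Optimizer configuration
#'
#' Collects every tunable of the UPSO/PSO optimizers with their standard
#' values: swarm size `npop` = 100, iteration cap `tmax` = 100, linearly
#' decreasing inertia between `wmax` = 1 and `wmin` = 0.1, acceleration
#' coefficients `c1 = c2 = c3` = 2, `S` = 4 sub-boxes and `Q0` = 31 design
#' points per sub-box for the uniform-design initializer (`S * Q0` must be at
#' least `npop`), `Q1` = 5 offspring per crossover parent pair, edge
#' threshold `theta` = 0.2, community-count sweep `kmin .. kmax` (by default
#' `kmax = min(N, 20)`; set it to N for the exhaustive sweep), and a stall
#' terminator that stops a run once the global best has not improved for
#' `ceil(stall_fraction * tmax)` consecutive iterations.
#'
#' @param npop Swarm size.
#' @param tmax Maximum number of iterations per fixed-K run.
#' @param wmin,wmax Inertia-weight range.
#' @param c1,c2,c3 Acceleration coefficients of the personal-best,
#'   global-best, and centroid attractors.
#' @param S Sub-box count for initialization; a power of two.
#' @param Q0 Design points per sub-box; a prime in [ud_levels()].
#' @param Q1 Offspring per crossover; a prime in [ud_levels()].
#' @param theta Edge threshold used by preprocessing helpers.
#' @param kmin,kmax Community-count sweep bounds (`NULL` kmax defers to
#'   `min(N, 20)` at run time).
#' @param stall_fraction Fraction of `tmax` without improvement that
#'   terminates a run; in (0, 1\].
#' @param seed Optional integer seed applied at the start of a run.
#' @param r_per_dimension If `TRUE`, the stochastic factors r1, r2, r3 of the
#'   velocity update are drawn per dimension instead of per particle.
#' @return Object of class `upso_config`.
#' @export
upso_config <- function(npop = 100L, tmax = 100L, wmin = 0.1, wmax = 1,
                        c1 = 2, c2 = 2, c3 = 2, S = 4L, Q0 = 31L, Q1 = 5L,
                        theta = 0.2, kmin = 1L, kmax = NULL,
                        stall_fraction = 0.3, seed = NULL,
                        r_per_dimension = FALSE) {
  S <- as.integer(S)
  if (S < 1L || bitwAnd(S, S - 1L) != 0L) stop("S must be a power of two")
  if (!(Q0 %in% ud_levels())) stop("Q0 must be one of ", paste(ud_levels(), collapse = ", "))
  if (!(Q1 %in% ud_levels())) stop("Q1 must be one of ", paste(ud_levels(), collapse = ", "))
  if (S * Q0 < npop) {
    stop(sprintf("configuration error: S * Q0 = %d < npop = %d", S * Q0, npop))
  }
  if (wmin < 0 || wmin > wmax) stop("require 0 <= wmin <= wmax")
  if (kmin < 1L) stop("kmin must be at least 1")
  if (!is.null(kmax) && kmax < kmin) stop("kmax must be >= kmin")
  if (stall_fraction <= 0 || stall_fraction > 1) {
    stop("stall_fraction must be in (0, 1]")
  }
  structure(list(npop = as.integer(npop), tmax = as.integer(tmax),
                 wmin = wmin, wmax = wmax, c1 = c1, c2 = c2, c3 = c3,
                 S = S, Q0 = as.integer(Q0), Q1 = as.integer(Q1),
                 theta = theta, kmin = as.integer(kmin),
                 kmax = if (is.null(kmax)) NULL else as.integer(kmax),
                 stall_fraction = stall_fraction, seed = seed,
                 r_per_dimension = isTRUE(r_per_dimension)),
            class = "upso_config")
}

# Internal: nearest-centroid labels (1-based) for a position vector.
# Drops the per-vertex constant ||a_i||^2, which does not change the argmin;
# ties go to the lowest community index.
decode_labels <- function(position, A, K, n) {
  C <- matrix(position, nrow = K, ncol = n, byrow = TRUE)
  d2 <- matrix(rowSums(C * C), nrow = n, ncol = K, byrow = TRUE) -
    2 * (A %*% t(C))
  max.col(-d2, ties.method = "first")
}

#' Decode a particle position into a partition
#'
#' Splits the length `K * N` position vector into K centroids and assigns
#' every vertex to the centroid with the smallest Euclidean distance to its
#' adjacency row; ties are broken toward the lowest community index.
#' Communities may decode empty; the partition's `effective_K` reports how
#' many are used.
#'
#' @param position Numeric vector of length `K * graph$n`.
#' @param graph A [weighted_graph()].
#' @param K Number of centroids encoded in `position`.
#' @return A [partition()] with declared count K.
#' @export
decode_position <- function(position, graph, K) {
  if (length(position) != K * graph$n) {
    stop(sprintf("position length %d != K * N = %d",
                 length(position), K * graph$n))
  }
  lab <- decode_labels(position, graph$adjacency, K, graph$n)
  partition(lab - 1L, K = K)
}

#' Fitness of a particle position
#'
#' The modularity of the decoded partition, returned together with the
#' partition so callers never decode twice.
#'
#' @inheritParams decode_position
#' @return List with `Q` and `partition`.
#' @export
position_fitness <- function(position, graph, K) {
  p <- decode_position(position, graph, K)
  list(Q = modularity_q(graph, p), partition = p)
}

# Internal: centroid matrix (K x n) from 1-based labels; empty communities
# keep their rows of `prev` (a K x n matrix).
centroids_from_labels <- function(lab, A, K, prev) {
  C <- prev
  counts <- tabulate(lab, nbins = K)
  present <- which(counts > 0L)
  sums <- rowsum(A, lab)  # rows ordered by sorted unique label
  C[present, ] <- sums / counts[present]
  C
}

#' Community centroid update
#'
#' Replaces each community's centroid by the arithmetic mean of its members'
#' adjacency rows. Empty communities retain their rows of `previous` (or 0
#' when no previous centroids are supplied).
#'
#' @param p A [partition()] with declared count K.
#' @param graph A [weighted_graph()].
#' @param previous Optional K x N matrix of current centroids.
#' @return K x N matrix of updated centroids.
#' @export
centroid_update <- function(p, graph, previous = NULL) {
  p <- as_partition(p)
  K <- p$K
  if (p$n != graph$n) stop("partition length must equal vertex count")
  if (is.null(previous)) {
    previous <- matrix(0, K, graph$n)
  } else {
    previous <- as.matrix(previous)
    if (nrow(previous) != K || ncol(previous) != graph$n) {
      stop("previous centroids must be a K x N matrix")
    }
  }
  centroids_from_labels(p$labels + 1L, graph$adjacency, K, previous)
}

#' Regulate a particle toward its community centroids
#'
#' Builds the candidate position KC whose centroids are the means of the
#' currently decoded communities (empty communities keep their existing
#' centroid), and accepts it only on strict fitness improvement. The
#' candidate is returned either way, because the velocity update uses KC as
#' its third attractor.
#'
#' @inheritParams decode_position
#' @return List with `position`, `Q`, `partition` (post-regulation state),
#'   `kc`, `kc_Q`, and `accepted`.
#' @export
regulate_particle <- function(position, graph, K) {
  fit <- position_fitness(position, graph, K)
  prev <- matrix(position, K, graph$n, byrow = TRUE)
  C <- centroid_update(fit$partition, graph, previous = prev)
  kc <- as.vector(t(C))
  kc_fit <- position_fitness(kc, graph, K)
  if (kc_fit$Q > fit$Q) {
    list(position = kc, Q = kc_fit$Q, partition = kc_fit$partition,
         kc = kc, kc_Q = kc_fit$Q, accepted = TRUE)
  } else {
    list(position = position, Q = fit$Q, partition = fit$partition,
         kc = kc, kc_Q = kc_fit$Q, accepted = FALSE)
  }
}

#' Linearly decreasing inertia weight
#'
#' \eqn{\omega(t) = w_{max} - t (w_{max} - w_{min}) / t_{max}}: full inertia
#' at the first iteration, `wmin` at the last.
#'
#' @param t Current iteration, `0 <= t <= tmax`.
#' @param tmax Maximum iteration count (> 0).
#' @param wmin,wmax Inertia range.
#' @export
inertia_weight <- function(t, tmax, wmin = 0.1, wmax = 1) {
  if (tmax <= 0) stop("tmax must be positive")
  wmax - t * (wmax - wmin) / tmax
}

#' Velocity and position update
#'
#' The three-attractor velocity rule
#' \deqn{s' = \omega s + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)
#'       + c_3 r_3 (KC - x),}
#' with r1, r2, r3 drawn uniformly on (0, 1) — one scalar each per call, or
#' per dimension with `r_per_dimension` — followed by `x' = x + s'`.
#' Velocities are clamped to \[-1, 1\] and positions to \[0, 1\]
#' componentwise, keeping centroids inside the weight range.
#'
#' @param position,velocity,pbest,gbest,kc Numeric vectors of equal length.
#' @param w Inertia weight.
#' @param c1,c2,c3 Acceleration coefficients.
#' @param r Optional fixed stochastic factors (length 3, or a list of three
#'   length-d vectors) for reproducing a single update; drawn when `NULL`.
#' @param r_per_dimension Draw r per dimension instead of per particle.
#' @return List with updated `position` and `velocity`.
#' @export
update_velocity_position <- function(position, velocity, pbest, gbest, kc,
                                     w, c1 = 2, c2 = 2, c3 = 2, r = NULL,
                                     r_per_dimension = FALSE) {
  d <- length(position)
  if (length(velocity) != d || length(pbest) != d || length(gbest) != d ||
      length(kc) != d) {
    stop("length mismatch among position, velocity and attractors")
  }
  if (is.null(r)) {
    r <- if (r_per_dimension) {
      list(stats::runif(d), stats::runif(d), stats::runif(d))
    } else {
      as.list(stats::runif(3L))
    }
  } else if (!is.list(r)) {
    r <- as.list(r)
  }
  v <- w * velocity + c1 * r[[1L]] * (pbest - position) +
    c2 * r[[2L]] * (gbest - position) + c3 * r[[3L]] * (kc - position)
  v <- pmin(pmax(v, -1), 1)
  x <- pmin(pmax(position + v, 0), 1)
  list(position = x, velocity = v)
}

# The fixed-K swarm engine shared by UPSO (use_ud = TRUE) and the PSO
# ablation (uniform-random initialization, no crossover).  Whole phases —
# the temporary initial swarm, the moved swarm, the centroid candidates,
# and the crossover offspring — are decoded and scored in single batched
# linear-algebra calls; the crossover's generating global best is the one
# at the start of the phase (synchronous variant), while best-replacement
# bookkeeping stays sequential.
run_swarm_fixed_k <- function(graph, K, config, use_ud) {
  n <- graph$n
  d <- K * n
  A <- graph$adjacency
  degrees <- graph$degrees
  m2 <- 2 * graph$total_weight
  if (m2 <= 0) stop("empty graph: total edge weight is zero")
  npop <- config$npop
  tmax <- config$tmax
  stall_limit <- ceiling(config$stall_fraction * tmax)

  # Sparse view of the (symmetric) adjacency for the modularity kernel.
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  eu <- ut[, 1L]
  ev <- ut[, 2L]
  ew <- A[ut]

  # Decode and score a whole batch of positions (rows of P).
  batch_eval <- function(P) {
    m <- nrow(P)
    M <- matrix(as.vector(t(P)), ncol = n, byrow = TRUE)  # (m*K) x n centroids
    sc <- rowSums(M * M) - 2 * tcrossprod(M, A)           # score[c, v]
    LABS <- matrix(0L, m, n)
    FV <- numeric(m)
    for (i in seq_len(m)) {
      block <- sc[((i - 1L) * K + 1L):(i * K), , drop = FALSE]
      lab <- max.col(-t(block), ties.method = "first")
      within <- 2 * sum(ew[lab[eu] == lab[ev]])
      vol <- rowsum(degrees, lab)[, 1L]
      LABS[i, ] <- lab
      FV[i] <- within / m2 - sum(vol * vol) / (m2 * m2)
    }
    list(F = FV, LAB = LABS)
  }

  # Centroid-regulation phase: candidate KC per particle, accepted only on
  # strict improvement; KC is kept either way as the third velocity
  # attractor.
  regulate_phase <- function(X, FQ, LAB) {
    KC <- X
    for (i in seq_len(npop)) {
      KC[i, ] <- as.vector(t(centroids_from_labels(
        LAB[i, ], A, K, matrix(X[i, ], K, n, byrow = TRUE))))
    }
    kc_eval <- batch_eval(KC)
    acc <- kc_eval$F > FQ
    if (any(acc)) {
      X[acc, ] <- KC[acc, , drop = FALSE]
      FQ[acc] <- kc_eval$F[acc]
      LAB[acc, ] <- kc_eval$LAB[acc, , drop = FALSE]
    }
    list(X = X, FQ = FQ, LAB = LAB, KC = KC)
  }

  # Initialization: uniform-design candidates scored and truncated to the
  # swarm size, or a uniform-random swarm for the ablation.
  if (use_ud) {
    if (config$S * config$Q0 < npop) {
      stop(sprintf("configuration error: S * Q0 = %d < npop = %d",
                   config$S * config$Q0, npop))
    }
    cand <- ud_candidates(d, config$S, config$Q0, rep(0, d), rep(1, d))
    ce <- batch_eval(cand)
    keep <- order(ce$F, decreasing = TRUE)[seq_len(npop)]
    X <- cand[keep, , drop = FALSE]
    FQ <- ce$F[keep]
    LAB <- ce$LAB[keep, , drop = FALSE]
  } else {
    X <- matrix(stats::runif(npop * d), npop, d)
    xe <- batch_eval(X)
    FQ <- xe$F
    LAB <- xe$LAB
  }

  reg <- regulate_phase(X, FQ, LAB)
  X <- reg$X; FQ <- reg$FQ; LAB <- reg$LAB; KC <- reg$KC

  # Velocities and personal bests start at the particle positions.
  V <- X
  Pb <- X
  Fpb <- FQ
  gi <- which.max(Fpb)
  G <- Pb[gi, ]
  Gf <- Fpb[gi]
  Glab <- LAB[gi, ]

  Uq1 <- if (use_ud) uniform_array(d, config$Q1)$levels
  Q1 <- config$Q1
  trace <- numeric(0L)
  t <- 0L
  t_no <- 0L
  cause <- "max_iterations"

  repeat {
    t <- t + 1L
    if (t > tmax) { cause <- "max_iterations"; break }
    if (t_no >= stall_limit) { cause <- "stall"; break }

    w <- inertia_weight(t, tmax, config$wmin, config$wmax)
    if (config$r_per_dimension) {
      r1 <- matrix(stats::runif(npop * d), npop, d)
      r2 <- matrix(stats::runif(npop * d), npop, d)
      r3 <- matrix(stats::runif(npop * d), npop, d)
    } else {
      r1 <- stats::runif(npop)
      r2 <- stats::runif(npop)
      r3 <- stats::runif(npop)
    }
    Gm <- matrix(G, npop, d, byrow = TRUE)
    V <- w * V + config$c1 * r1 * (Pb - X) + config$c2 * r2 * (Gm - X) +
      config$c3 * r3 * (KC - X)
    V[V > 1] <- 1
    V[V < -1] <- -1
    X <- X + V
    X[X > 1] <- 1
    X[X < 0] <- 0

    prev_gf <- Gf

    # Fitness and centroid regulation.
    xe <- batch_eval(X)
    reg <- regulate_phase(X, xe$F, xe$LAB)
    X <- reg$X; FQ <- reg$FQ; LAB <- reg$LAB; KC <- reg$KC

    # Personal and global best updates (strict improvement only).
    imp <- FQ > Fpb
    if (any(imp)) {
      Pb[imp, ] <- X[imp, , drop = FALSE]
      Fpb[imp] <- FQ[imp]
    }
    bi <- which.max(Fpb)
    if (Fpb[bi] > Gf) {
      Gf <- Fpb[bi]
      G <- Pb[bi, ]
      Glab <- LAB[bi, ]
    }

    # Uniform-design crossover with the personal and global bests.
    if (use_ud) {
      OFF <- matrix(0, npop * 2L * Q1, d)
      for (i in seq_len(npop)) {
        OFF[((i - 1L) * 2L * Q1 + 1L):(i * 2L * Q1), ] <-
          rbind(ud_offspring(X[i, ], Pb[i, ], Uq1),
                ud_offspring(X[i, ], G, Uq1))
      }
      oe <- batch_eval(OFF)
      for (i in seq_len(npop)) {
        rows <- ((i - 1L) * 2L * Q1 + 1L):(i * 2L * Q1)
        bo <- rows[which.max(oe$F[rows])]
        if (oe$F[bo] > Fpb[i]) {
          X[i, ] <- OFF[bo, ]
          FQ[i] <- oe$F[bo]
          LAB[i, ] <- oe$LAB[bo, ]
          Pb[i, ] <- OFF[bo, ]
          Fpb[i] <- oe$F[bo]
        }
        if (oe$F[bo] > Gf) {
          Gf <- oe$F[bo]
          G <- OFF[bo, ]
          Glab <- oe$LAB[bo, ]
        }
      }
    }

    trace <- c(trace, Gf)
    if (Gf - prev_gf <= 1e-12) t_no <- t_no + 1L else t_no <- 0L
  }

  list(best_Q = Gf, partition = partition(Glab - 1L, K = K), position = G,
       trace = trace, iterations = t - 1L, termination = cause)
}

#' Run the optimizer for a fixed community count
#'
#' One swarm run with K centroids per particle: uniform-design
#' initialization, centroid regulation, velocity/position updates with the
#' three-attractor rule, strict personal/global best updates, and the
#' uniform-design crossover, until either `t > tmax` or the global best has
#' stalled for `ceil(stall_fraction * tmax)` consecutive iterations
#' (improvement below 1e-12 counts as stalled). The global-best trace is
#' nondecreasing by construction.
#'
#' @param graph A [weighted_graph()].
#' @param K Community count, `1 <= K <= graph$n`.
#' @param config An [upso_config()].
#' @param seed Optional seed for this run (otherwise the current RNG state
#'   is used).
#' @param method `"upso"` (default) or `"pso"` (random initialization, no
#'   crossover).
#' @return List with `best_Q`, `partition`, `position`, per-iteration
#'   `trace`, `iterations`, and `termination` (`"max_iterations"` or
#'   `"stall"`).
#' @export
run_upso_fixed_k <- function(graph, K, config = upso_config(), seed = NULL,
                             method = c("upso", "pso")) {
  method <- match.arg(method)
  K <- as.integer(K)
  if (K < 1L || K > graph$n) stop("invalid K: must be in 1..N")
  if (!is.null(seed)) set.seed(seed)
  run_swarm_fixed_k(graph, K, config, use_ud = identical(method, "upso"))
}

run_sweep <- function(graph, config, use_ud, method_name) {
  if (!inherits(graph, "weighted_graph")) stop("graph must be a weighted_graph")
  if (!is.null(config$seed)) set.seed(config$seed)
  kmin <- config$kmin
  kmax <- if (is.null(config$kmax)) min(graph$n, 20L) else config$kmax
  if (kmax < kmin) stop("kmax must be >= kmin")
  if (kmax > graph$n) stop("kmax must not exceed the vertex count")
  ks <- kmin:kmax
  per_k <- stats::setNames(rep(NA_real_, length(ks)), as.character(ks))
  traces <- stats::setNames(vector("list", length(ks)), as.character(ks))
  terminations <- stats::setNames(character(length(ks)), as.character(ks))
  best <- NULL
  for (idx in seq_along(ks)) {
    res <- run_swarm_fixed_k(graph, ks[idx], config, use_ud)
    per_k[idx] <- res$best_Q
    traces[[idx]] <- res$trace
    terminations[idx] <- res$termination
    if (is.null(best) || res$best_Q > best$best_Q) {
      best <- res
      best$K <- ks[idx]
    }
  }
  structure(list(best_partition = best$partition,
                 best_Q = best$best_Q,
                 best_conductance = conductance(graph, best$partition),
                 chosen_K = best$partition$effective_K,
                 swept_K = best$K,
                 per_K_history = per_k,
                 gbest_trace = traces,
                 terminations = terminations,
                 method = method_name,
                 seed = config$seed),
            class = "community_result")
}

#' Detect community modules with UPSO
#'
#' Sweeps the community count K from `kmin` to `kmax`, runs the fixed-K
#' optimizer for each, and returns the best solution over the sweep together
#' with its conductance and the per-K history. `chosen_K` is the number of
#' nonempty communities in the winning partition (decoding may leave some of
#' the K centroids empty, so the sweep self-prunes).
#'
#' @param graph A [weighted_graph()].
#' @param config An [upso_config()]; `config$seed`, when set, makes the whole
#'   sweep reproducible.
#' @return Object of class `community_result` with `best_partition`,
#'   `best_Q`, `best_conductance`, `chosen_K`, `per_K_history`,
#'   `gbest_trace` (per-K iteration traces), `terminations`, `method`,
#'   `seed`.
#' @seealso [run_pso()] for the ablation without uniform design.
#' @export
run_upso <- function(graph, config = upso_config()) {
  run_sweep(graph, config, use_ud = TRUE, method_name = "upso")
}

#' Detect community modules with plain PSO (ablation)
#'
#' Identical to [run_upso()] except that the swarm is initialized uniformly
#' at random in \[0, 1\]^(K N) and the uniform-design crossover step is
#' skipped. Comparing the two isolates the contribution of the uniform
#' design.
#'
#' @inheritParams run_upso
#' @export
run_pso <- function(graph, config = upso_config()) {
  run_sweep(graph, config, use_ud = FALSE, method_name = "pso")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("%s community detection\n", toupper(x$method)))
  cat(sprintf("  best modularity Q = %.4f (K swept = %s, effective K = %d)\n",
              x$best_Q, x$swept_K, x$chosen_K))
  cat(sprintf("  conductance       = %.4f\n", x$best_conductance))
  invisible(x)
}
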