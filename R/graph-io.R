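# Connectivity matrices, weighted graphs, partitions, and their file formats.
#
# All vertex and community identifiers are 0-based in files and in the
# public API, matching the edge-list / partition text formats.

#' Connectivity matrix
#'
#' A raw square connectivity matrix (CM) as distributed for functional brain
#' networks: entries may be Fisher z-transformed correlations and may be
#' negative. Entries must be finite; non-finite values are rejected so that
#' downstream transforms are total.
#'
#' @param values Square numeric matrix.
#' @param labels Optional character vector of region (ROI) names, one per row.
#' @return An object of class `connectivity_matrix` with elements `values`
#'   and `labels`.
#' @examples
#' cm <- connectivity_matrix(matrix(c(0, 0.5, 0.5, 0), 2, 2))
#' @export
connectivity_matrix <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("parse error: connectivity matrix entries must be numeric")
  }
  if (nrow(values) != ncol(values)) {
    stop(sprintf("shape error: matrix must be square, got %d x %d",
                 nrow(values), ncol(values)))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values)) {
      stop("labels length must equal matrix dimension")
    }
  }
  structure(list(values = unname(values), labels = labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity matrix: %d x %d%s\n", nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

# Extract the numeric matrix from a connectivity_matrix or plain matrix.
cm_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

cm_labels <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$labels else NULL
}

# Rebuild a connectivity_matrix with new values, preserving labels and
# returning a plain matrix when the input was one.
cm_like <- function(x, values) {
  if (inherits(x, "connectivity_matrix")) {
    connectivity_matrix(values, x$labels)
  } else {
    values
  }
}

#' Weighted undirected graph
#'
#' The validated container on which community detection operates: a symmetric,
#' nonnegative adjacency matrix with zero diagonal, together with the weighted
#' degrees \eqn{k_i = \sum_j a_{ij}} and the total edge weight
#' \eqn{m = \sum_i k_i / 2}.
#'
#' @param adjacency Square numeric matrix; symmetric to within 1e-9,
#'   nonnegative, zero diagonal.
#' @param labels Optional vertex names.
#' @return Object of class `weighted_graph` with elements `n`, `adjacency`,
#'   `labels`, `degrees`, `total_weight`.
#' @export
weighted_graph <- function(adjacency, labels = NULL) {
  a <- unname(as.matrix(adjacency))
  if (nrow(a) != ncol(a)) stop("shape error: adjacency must be square")
  if (!all(is.finite(a))) stop("adjacency entries must be finite")
  if (max(abs(a - t(a))) > 1e-9) {
    stop("adjacency must be symmetric (tolerance 1e-9)")
  }
  if (any(a < 0)) stop("adjacency entries must be nonnegative")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be exactly zero")
  a <- (a + t(a)) / 2  # remove sub-tolerance asymmetry
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(a)) stop("labels length must equal vertex count")
  }
  degrees <- rowSums(a)
  structure(list(n = nrow(a), adjacency = a, labels = labels,
                 degrees = degrees, total_weight = sum(degrees) / 2),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted graph: %d vertices, total edge weight m = %.4f\n",
              x$n, x$total_weight))
  invisible(x)
}

#' Vertex partition into communities
#'
#' Per-vertex community labels in `0 .. K-1`. `K` is the declared community
#' count (communities may be empty); `effective_K` counts nonempty ones.
#'
#' @param labels Integer vector of 0-based community ids.
#' @param K Declared community count; defaults to `max(labels) + 1`.
#' @return Object of class `partition` with `labels`, `K`, `effective_K`, `n`.
#' @export
partition <- function(labels, K = NULL) {
  labels <- as.integer(round(as.numeric(labels)))
  if (length(labels) < 1L) stop("partition must cover at least one vertex")
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("community ids must be nonnegative integers")
  }
  if (is.null(K)) K <- max(labels) + 1L
  K <- as.integer(K)
  if (any(labels >= K)) stop("every label must be < K")
  structure(list(labels = labels, K = K,
                 effective_K = length(unique(labels)),
                 n = length(labels)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d vertices, K = %d (%d nonempty)\n",
              x$n, x$K, x$effective_K))
  invisible(x)
}

#' Coerce to a partition
#'
#' @param x A `partition` or a vector of 0-based labels.
#' @param K Optional declared community count.
#' @export
as_partition <- function(x, K = NULL) {
  if (inherits(x, "partition")) x else partition(x, K)
}

# Internal: 1-based labels for rowsum()-style grouping.
lab1 <- function(p) as_partition(p)$labels + 1L

detect_delimiter <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t"
  else if (grepl(",", line, fixed = TRUE)) ","
  else ""
}

tokenize_lines <- function(lines, delimiter) {
  if (identical(delimiter, "")) {
    strsplit(trimws(lines), "[ \t]+")
  } else {
    lapply(strsplit(lines, delimiter, fixed = TRUE), trimws)
  }
}

#' Read a square connectivity matrix from delimited text
#'
#' Accepts comma-, tab-, or whitespace-delimited text. The delimiter is
#' auto-detected from the first line unless given (precedence: tab, then
#' comma, then whitespace). An optional header row plus leading label column
#' of region names is detected when the first field is non-numeric, or forced
#' with `has_labels`.
#'
#' @param path Path to the text file.
#' @param delimiter `NULL` (auto), `","`, `"\t"` or `""` (whitespace).
#' @param has_labels `NA` (auto), `TRUE` or `FALSE`.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, delimiter = NULL, has_labels = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty file")
  if (is.null(delimiter)) delimiter <- detect_delimiter(lines[[1L]])
  tok <- tokenize_lines(lines, delimiter)
  if (is.na(has_labels)) {
    has_labels <- is.na(suppressWarnings(as.numeric(tok[[1L]][1L])))
  }
  labels <- NULL
  if (has_labels) {
    if (length(tok) < 2L) stop("parse error: labelled matrix needs a body")
    body <- tok[-1L]
    labels <- vapply(body, `[[`, character(1L), 1L)
    body <- lapply(body, `[`, -1L)
    row_offset <- 1L
    col_offset <- 1L
  } else {
    body <- tok
    row_offset <- 0L
    col_offset <- 0L
  }
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    stop("shape error: rows have differing numbers of fields")
  }
  n_row <- length(body)
  n_col <- widths[[1L]]
  if (n_row != n_col) {
    stop(sprintf("shape error: matrix must be square, got %d x %d",
                 n_row, n_col))
  }
  values <- matrix(NA_real_, n_row, n_col)
  for (i in seq_len(n_row)) {
    v <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("parse error at row %d, column %d",
                   i + row_offset, j + col_offset))
    }
    values[i, ] <- v
  }
  connectivity_matrix(values, labels)
}

#' Write a connectivity matrix (or adjacency) to delimited text
#'
#' @param cm A `connectivity_matrix`, `weighted_graph`, or plain matrix.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @export
write_connectivity_matrix <- function(cm, path, delimiter = "\t") {
  if (inherits(cm, "weighted_graph")) {
    values <- cm$adjacency
    labels <- cm$labels
  } else {
    values <- cm_values(cm)
    labels <- cm_labels(cm)
  }
  if (is.null(labels)) {
    utils::write.table(values, path, sep = delimiter, row.names = FALSE,
                       col.names = FALSE)
  } else {
    out <- cbind(labels, format(values, trim = TRUE, scientific = FALSE))
    header <- paste(c("", labels), collapse = delimiter)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(out, con, sep = delimiter, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Reverse Fisher z-transform
#'
#' Maps each entry x to \eqn{(e^{2x}-1)/(e^{2x}+1) = \tanh(x)}, turning
#' z-transformed correlations back into Pearson correlations in (-1, 1).
#' The transform is total and entrywise; `reverse_z_transform` is the exact
#' inverse of `artanh` on (-1, 1).
#'
#' @param cm Connectivity matrix (or plain matrix).
#' @return Same type as the input with transformed entries.
#' @export
reverse_z_transform <- function(cm) {
  cm_like(cm, tanh(cm_values(cm)))
}

#' Clamp negative entries to zero
#'
#' Negative correlations carry no edge weight in the nonnegative network
#' model; they are set to 0, all other entries are unchanged. Idempotent.
#'
#' @param cm Connectivity matrix (or plain matrix).
#' @export
clamp_negative <- function(cm) {
  v <- cm_values(cm)
  v[v < 0] <- 0
  cm_like(cm, v)
}

#' Threshold weak edges
#'
#' Entries strictly below `theta` are set to 0; entries equal to or above
#' `theta` are kept (the comparison is `x < theta`, so the boundary value
#' survives). Idempotent for any fixed `theta`.
#'
#' @param cm Connectivity matrix (or plain matrix).
#' @param theta Nonnegative threshold; 0 leaves a nonnegative matrix
#'   unchanged.
#' @export
threshold_edges <- function(cm, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0) {
    stop("theta must be a single nonnegative number")
  }
  v <- cm_values(cm)
  v[v < theta] <- 0
  cm_like(cm, v)
}

#' Preprocess a raw connectivity matrix into a weighted graph
#'
#' The full preprocessing chain for correlation-based connectivity data:
#' optional reverse Fisher z-transform, clamping of negative correlations to
#' zero, zeroing of the diagonal (no self-loops), symmetrization by averaging
#' (inputs with asymmetry beyond 1e-6 are rejected), and edge thresholding
#' at `theta`. The result is a valid [weighted_graph()] whose entries lie in
#' \[0, 1\] for correlation-type inputs.
#'
#' @param cm A [connectivity_matrix()] or plain square matrix.
#' @param apply_reverse_z Apply [reverse_z_transform()] first?
#' @param theta Edge-weight threshold, default 0.2.
#' @return A [weighted_graph()]; an error is raised if thresholding removes
#'   every edge ("empty graph").
#' @export
preprocess_cm <- function(cm, apply_reverse_z = FALSE, theta = 0.2) {
  labels <- cm_labels(cm)
  v <- cm_values(cm)
  if (nrow(v) != ncol(v)) stop("shape error: matrix must be square")
  if (!all(is.finite(v))) stop("non-finite entries in connectivity matrix")
  if (apply_reverse_z) v <- tanh(v)
  v[v < 0] <- 0
  diag(v) <- 0
  if (max(abs(v - t(v))) > 1e-6) {
    stop("asymmetric input: |a_ij - a_ji| exceeds 1e-6")
  }
  v <- (v + t(v)) / 2
  v[v < theta] <- 0
  if (sum(v) <= 0) stop("empty graph: no edges survive thresholding")
  weighted_graph(v, labels)
}

#' Read / write vertex partitions
#'
#' Partition files are two-column delimited text: 0-based vertex id and
#' 0-based community id, one row per vertex. Every vertex `0 .. N-1` must
#' appear exactly once. Non-contiguous community ids are relabelled to
#' canonical `0 .. K-1` form (by sorted original id) with a warning.
#'
#' @param path Path to the partition file.
#' @return A [partition()].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error: empty partition file")
  tok <- tokenize_lines(lines, detect_delimiter(lines[[1L]]))
  if (any(lengths(tok) != 2L)) {
    stop("parse error: partition rows must have exactly two fields")
  }
  vert <- suppressWarnings(as.integer(vapply(tok, `[[`, character(1L), 1L)))
  comm <- suppressWarnings(as.integer(vapply(tok, `[[`, character(1L), 2L)))
  if (anyNA(vert) || anyNA(comm)) stop("parse error: non-integer field")
  if (any(comm < 0L)) stop("negative community id")
  if (anyDuplicated(vert)) {
    stop("duplicate vertex id: ", vert[duplicated(vert)][1L])
  }
  n <- length(vert)
  missing <- setdiff(0:(n - 1L), vert)
  if (length(missing) > 0L) stop("missing vertex id: ", missing[1L])
  comm <- comm[order(vert)]
  ids <- sort(unique(comm))
  if (!identical(ids, seq_along(ids) - 1L)) {
    warning("non-contiguous community ids; relabelled to 0..K-1")
    comm <- match(comm, ids) - 1L
  }
  partition(comm)
}

#' @rdname read_partition
#' @param p A [partition()] (or 0-based label vector).
#' @export
write_partition <- function(p, path) {
  p <- as_partition(p)
  utils::write.table(cbind(seq_len(p$n) - 1L, p$labels), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write weighted edge lists
#'
#' Edge lists are three-column delimited text `u v w` with 0-based vertex
#' ids; each undirected edge appears once. `read_edge_list` fills both
#' triangles of the adjacency matrix.
#'
#' @param path Path to the edge-list file.
#' @param n Vertex count; defaults to `max(id) + 1`.
#' @return A [weighted_graph()].
#' @export
read_edge_list <- function(path, n = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("u", "v", "w"))
  u <- as.integer(df$u); v <- as.integer(df$v); w <- as.numeric(df$w)
  if (any(u < 0L) || any(v < 0L)) stop("negative vertex id")
  if (any(u == v)) stop("self-loops are not allowed")
  if (is.null(n)) n <- max(u, v) + 1L
  a <- matrix(0, n, n)
  a[cbind(u + 1L, v + 1L)] <- w
  a[cbind(v + 1L, u + 1L)] <- w
  weighted_graph(a)
}

#' @rdname read_edge_list
#' @param graph A [weighted_graph()].
#' @export
write_edge_list <- function(graph, path) {
  a <- graph$adjacency
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(u = idx[, 1L] - 1L, v = idx[, 2L] - 1L, w = a[idx]),
    path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
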