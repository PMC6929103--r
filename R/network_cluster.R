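# Profile-similarity networks and affinity-propagation clustering.
#
# Distance matrices (TES scale, [0, 2]) become similarity networks via the
# conversion w = 2 - D; RRHO grids contribute a scalar edge weight (the
# grid maximum of the signed log10 p map). Affinity propagation groups
# profiles without a preset cluster count by exemplar-based message
# passing on s = -D.

#' Build a thresholded profile-similarity network
#'
#' In `distance` mode edge weights are `2 - D` (so TES-scale distances in
#' `[0, 2]` map to similarities in `[0, 2]`); in `similarity` mode the
#' input values are used as weights directly (e.g. RRHO-derived signed
#' log10 p weights). An undirected edge is retained iff its weight is at
#' least `threshold`; raising the threshold can only remove edges, which
#' is how the network's complexity is tuned.
#'
#' @param d A `distance_matrix` or square symmetric numeric matrix with
#'   dimnames.
#' @param threshold Minimum edge weight retained; must be non-negative in
#'   distance mode.
#' @param mode `"distance"` (convert via `2 - D`) or `"similarity"` (use
#'   values as-is).
#' @return An object of class `profile_network`: list with `nodes`,
#'   `edges` (data frame `from`, `to`, `weight`; each unordered pair at
#'   most once, no self-loops), `threshold` and `mode`.
#' @export
build_network <- function(d, threshold = 0,
                          mode = c("distance", "similarity")) {
  mode <- match.arg(mode)
  v <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  if (nrow(v) != ncol(v))
    stop("input must be square", call. = FALSE)
  if (max(abs(v - t(v))) > 1e-8)
    stop("input must be symmetric", call. = FALSE)
  if (mode == "distance" && threshold < 0)
    stop("'threshold' must be non-negative in distance mode", call. = FALSE)
  nms <- rownames(v)
  if (is.null(nms)) nms <- paste0("p", seq_len(nrow(v)))
  w <- if (mode == "distance") 2 - v else v
  idx <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = nms[idx[, 1L]], to = nms[idx[, 2L]],
                      weight = w[idx], stringsAsFactors = FALSE)
  structure(list(nodes = nms, edges = edges,
                 threshold = threshold, mode = mode),
            class = "profile_network")
}

#' @export
print.profile_network <- function(x, ...) {
  cat("profile_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$mode, " mode, threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Scalar edge weight from an RRHO grid
#'
#' Summarizes an RRHO map as the maximum signed log10 p over the grid —
#' the strongest co-regulation signal between the pair. Anti-correlated
#' pairs can yield non-positive weights, which positive thresholds then
#' drop from the network.
#'
#' @param grid An `rrho_grid`.
#' @return A single number.
#' @export
rrho_edge_weight <- function(grid) {
  stopifnot(inherits(grid, "rrho_grid"))
  max(grid$values)
}

#' Affinity-propagation clustering of profiles
#'
#' Frey-Dueck message passing on the similarity `s = -D`, with the
#' preference (self-similarity) defaulting to the median off-diagonal
#' similarity. Exemplars emerge from the data; the cluster count is not
#' preset. The implementation is fully deterministic: no random jitter is
#' added, and convergence is declared when the exemplar set is unchanged
#' for `conv_iter` consecutive iterations.
#'
#' @param d A `distance_matrix` or square symmetric numeric matrix.
#' @param damping Message damping factor in `[0.5, 1)`; default 0.9.
#' @param max_iter Maximum number of iterations; default 1000.
#' @param preference Self-similarity; larger values yield more clusters.
#'   Default: median of the off-diagonal similarities.
#' @param conv_iter Iterations of exemplar stability required; default 100.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (named integer vector: profile -> cluster id), `exemplars` (cluster
#'   id -> profile name), `converged` and `iterations`. On
#'   non-convergence a warning is issued and the labels reflect the final
#'   message state (all `NA` if no exemplar ever emerged).
#' @export
affinity_propagation <- function(d, damping = 0.9, max_iter = 1000L,
                                 preference = NULL, conv_iter = 100L) {
  v <- if (inherits(d, "distance_matrix")) d$values else as.matrix(d)
  if (nrow(v) != ncol(v))
    stop("input must be square", call. = FALSE)
  if (max(abs(v - t(v))) > 1e-8)
    stop("input must be symmetric", call. = FALSE)
  if (damping < 0.5 || damping >= 1)
    stop("'damping' must lie in [0.5, 1)", call. = FALSE)
  n <- nrow(v)
  nms <- rownames(v)
  if (is.null(nms)) nms <- paste0("p", seq_len(n))
  if (n == 1L) {
    return(structure(list(labels = stats::setNames(1L, nms),
                          exemplars = stats::setNames(nms, "1"),
                          converged = TRUE, iterations = 0L),
                     class = "cluster_assignment"))
  }
  off <- v[upper.tri(v) | lower.tri(v)]
  if (max(abs(off)) < .Machine$double.eps * n) {
    # constant similarity: message passing is degenerate; all profiles
    # are interchangeable and form a single cluster
    return(structure(list(labels = stats::setNames(rep(1L, n), nms),
                          exemplars = stats::setNames(nms[1L], "1"),
                          converged = TRUE, iterations = 0L),
                     class = "cluster_assignment"))
  }
  S <- -v
  if (is.null(preference)) preference <- stats::median(-off)
  # deterministic symmetry breaking: exactly interchangeable profiles would
  # deadlock the message passing (the usual cure is random jitter); a tiny
  # index-ordered offset on the preference picks the earlier profile as
  # exemplar without affecting generic inputs
  eps <- 1e-9 * (max(S) - min(S) + 1)
  diag(S) <- preference + eps * (n - seq_len(n)) / n
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  idx <- seq_len(n)
  ex_prev <- logical(n)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    top1_col <- max.col(AS, ties.method = "first")
    top1 <- AS[cbind(idx, top1_col)]
    AS[cbind(idx, top1_col)] <- -Inf
    top2 <- apply(AS, 1L, max)
    Rnew <- S - top1
    Rnew[cbind(idx, top1_col)] <- S[cbind(idx, top1_col)] - top2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp, 0)
    diag(Anew) <- cs - diag(R)
    A <- damping * A + (1 - damping) * Anew
    ex <- diag(R) + diag(A) > 0
    if (any(ex) && identical(ex, ex_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    ex_prev <- ex
  }
  ex_idx <- which(diag(R) + diag(A) > 0)
  if (!length(ex_idx)) {
    warning("affinity propagation did not identify any exemplar after ",
            it, " iterations; returning NA labels")
    return(structure(list(labels = stats::setNames(rep(NA_integer_, n), nms),
                          exemplars = stats::setNames(character(0),
                                                      character(0)),
                          converged = FALSE, iterations = it),
                     class = "cluster_assignment"))
  }
  if (!converged)
    warning("affinity propagation did not converge within ", max_iter,
            " iterations; labels reflect the final message state")
  assign_to <- ex_idx[max.col(S[, ex_idx, drop = FALSE],
                              ties.method = "first")]
  assign_to[ex_idx] <- ex_idx  # exemplars belong to their own cluster
  labels <- match(assign_to, ex_idx)
  structure(list(labels = stats::setNames(as.integer(labels), nms),
                 exemplars = stats::setNames(nms[ex_idx],
                                             seq_along(ex_idx)),
                 converged = converged, iterations = it),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- length(x$exemplars)
  cat("cluster_assignment: ", k, " cluster(s)",
      if (!x$converged) " [not converged]", "\n", sep = "")
  for (cid in names(x$exemplars)) {
    members <- names(x$labels)[x$labels == as.integer(cid)]
    cat("  ", cid, " (exemplar ", x$exemplars[[cid]], "): ",
        paste(members, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a profile network to GraphML or an edge list
#'
#' GraphML is written via igraph with a `weight` edge attribute; the edge
#' list is a three-column TSV (`from`, `to`, `weight`). Both formats
#' round-trip the node set, edge set and weights.
#'
#' @param net A `profile_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(net, "profile_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
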