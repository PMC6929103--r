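# GSEA-style enrichment-score distances between ranked profiles.
#
# A signature of length s is the pair (p, q) of the s top-ranked and s
# bottom-ranked genes of a profile. The enrichment score (ES) of a gene set
# within another profile is the extremal value of an unweighted
# Kolmogorov-Smirnov running sum (+1/s per member, -1/(N-s) per
# non-member); the total enrichment score TES = 1 - (ES_p - ES_q)/2 is a
# directed dissimilarity in [0, 2]: 0 for identical orderings, 2 for full
# reversal. The running sum is evaluated on the integer numerator
# h*N - i*s (over the common denominator s*(N-s)), so ES and TES are exact:
# TES(x, x) is 0 to the last bit, not merely within rounding.

#' Extract the top/bottom signature of a ranked profile
#'
#' @param x A [ranked_profile()].
#' @param s Signature length; `1 <= s <= floor(N/2)` so that the top and
#'   bottom gene lists cannot overlap.
#' @return An object of class `signature`: list with `s`, `top` (genes
#'   ranked 1..s, in rank order), `bottom` (genes ranked N-s+1..N, in rank
#'   order) and `source` (the profile name).
#' @export
extract_signature <- function(x, s) {
  stopifnot(inherits(x, "ranked_profile"))
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L || s > x$n %/% 2L)
    stop("'s' must be an integer in 1..floor(N/2) (N = ", x$n, ")",
         call. = FALSE)
  genes_in_order <- names(sort(x$ranks))
  structure(list(s = s,
                 top = genes_in_order[seq_len(s)],
                 bottom = genes_in_order[seq.int(x$n - s + 1L, x$n)],
                 source = x$name),
            class = "signature")
}

# Integer-numerator running sum: member step +1/s, non-member -1/(N-s),
# both over the common denominator s*(N-s). Returns the numerators
# h*N - i*s for i = 1..N; the walk ends at exactly 0.
.es_path <- function(member, n, s) {
  h <- cumsum(member)
  h * n - seq_len(n) * s
}

#' Unweighted KS enrichment score of a gene set in a ranked profile
#'
#' Walks down the ranked list of `y`, adding `1/s` when the gene belongs to
#' `genes` and subtracting `1/(N-s)` otherwise; the ES is the running-sum
#' deviation of maximum absolute value (positive taken on exact ties).
#' ES = +1 iff all members occupy the top s ranks; -1 iff they occupy the
#' bottom s ranks.
#'
#' @param genes Character vector of member gene ids (the set), all present
#'   in the universe of `y`; `1 <= length(genes) < N`.
#' @param y A [ranked_profile()].
#' @return ES in `[-1, 1]`.
#' @export
enrichment_score <- function(genes, y) {
  stopifnot(inherits(y, "ranked_profile"))
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene id in the gene set", call. = FALSE)
  s <- length(genes)
  if (s < 1L || s >= y$n)
    stop("gene-set size must satisfy 1 <= s < N", call. = FALSE)
  missing <- setdiff(genes, names(y$ranks))
  if (length(missing))
    stop("gene(s) not in the profile universe: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  member <- names(sort(y$ranks)) %in% genes
  num <- .es_path(member, y$n, s)
  mx <- max(num)
  mn <- min(num)
  ext <- if (mx >= -mn) mx else mn
  ext / (s * (y$n - s))
}

#' Total enrichment score between two ranked profiles
#'
#' TES of `x` with respect to `y`: the top and bottom signatures of `x` are
#' scored against the ordering of `y` and combined as
#' `TES = 1 - (ES_y(p) - ES_y(q)) / 2`. TES is 0 when the profiles order
#' genes identically and 2 when one is the full reversal of the other; it
#' is directed (TES(x, y) need not equal TES(y, x)).
#'
#' @param x,y [ranked_profile()]s over the same gene universe.
#' @param s Signature length; the default 250 follows the prototype-ranked-
#'   list convention and is clipped to `floor(N/2)` (with a message) when
#'   the universe is too small for disjoint signatures.
#' @return An object of class `enrichment_result`: list with `ES_top`,
#'   `ES_bottom` (both in `[-1, 1]`), `TES` (in `[0, 2]`) and `s`.
#' @export
tes <- function(x, y, s = 250L) {
  stopifnot(inherits(x, "ranked_profile"), inherits(y, "ranked_profile"))
  if (!identical(names(x$ranks), names(y$ranks)))
    stop("profiles do not share the same gene universe", call. = FALSE)
  s <- as.integer(s)
  if (length(s) != 1L || is.na(s) || s < 1L)
    stop("'s' must be a positive integer", call. = FALSE)
  smax <- x$n %/% 2L
  if (s > smax) {
    message("signature length ", s, " clipped to floor(N/2) = ", smax)
    s <- smax
  }
  sig <- extract_signature(x, s)
  es_p <- enrichment_score(sig$top, y)
  es_q <- enrichment_score(sig$bottom, y)
  structure(list(ES_top = es_p, ES_bottom = es_q,
                 TES = 1 - (es_p - es_q) / 2, s = s),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result (s = %d): ES_top = %.4f, ES_bottom = %.4f, TES = %.4f\n",
              x$s, x$ES_top, x$ES_bottom, x$TES))
  invisible(x)
}

#' Pairwise enrichment-score distance matrix
#'
#' Computes all directed TES values between the profiles of a ranked matrix
#' and symmetrizes them: `avg` takes `(TES(x,y) + TES(y,x)) / 2`, `max`
#' takes `min(TES(x,y), TES(y,x))` (the stricter of the two directions;
#' a pair is distant only if both directed scores are). Entries lie in
#' `[0, 2]` with a zero diagonal.
#'
#' @param m A [ranked_matrix()] with at least two profiles.
#' @param s Signature length passed to [tes()].
#' @param method `"avg"` or `"max"`.
#' @return An object of class `distance_matrix`: list with `names`,
#'   `values` (symmetric numeric matrix with dimnames), `method` and `s`.
#' @export
distance_matrix <- function(m, s = 250L, method = c("avg", "max")) {
  stopifnot(inherits(m, "ranked_matrix"))
  method <- match.arg(method)
  nms <- profile_names(m)
  k <- length(nms)
  if (k < 2L)
    stop("at least two profiles are required", call. = FALSE)
  profs <- lapply(nms, function(nm) get_profile(m, nm))
  s_used <- min(as.integer(s), profs[[1L]]$n %/% 2L)
  D <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      t_ij <- suppressMessages(tes(profs[[i]], profs[[j]], s = s))$TES
      t_ji <- suppressMessages(tes(profs[[j]], profs[[i]], s = s))$TES
      D[i, j] <- D[j, i] <- switch(method,
                                   avg = (t_ij + t_ji) / 2,
                                   max = min(t_ij, t_ji))
    }
  }
  structure(list(names = nms, values = D, method = method, s = s_used),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$method, ", s = ", x$s, "): ",
      length(x$names), " profiles\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Write / read a distance matrix as TSV
#'
#' Square tab-separated table with profile names as the header row and
#' first column.
#'
#' @param d A `distance_matrix` (or any square symmetric matrix for
#'   `write_`).
#' @param path File path.
#' @param method,s Metadata restored on read (the TSV itself stores only
#'   the values).
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns a `distance_matrix`.
#' @export
write_distance_matrix <- function(d, path) {
  v <- if (inherits(d, "distance_matrix")) d$values else d
  out <- data.frame(name = rownames(v), v, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, method = "avg", s = NA_integer_) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  v <- as.matrix(tab)
  if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
    stop("not a square named distance matrix: ", path, call. = FALSE)
  if (max(abs(v - t(v))) > 1e-8)
    stop("distance matrix is not symmetric: ", path, call. = FALSE)
  structure(list(names = rownames(v), values = v, method = method, s = s),
            class = "distance_matrix")
}
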