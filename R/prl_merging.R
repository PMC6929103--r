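# Prototype ranked list (PRL) construction: iterative closest-pair merging
# of ranked profiles under Spearman's footrule, with the Borda mean rule.

#' Spearman's footrule distance between two ranked profiles
#'
#' The L1 distance between the two rank vectors over a shared universe:
#' `D(x, y) = sum_i |R(i, x) - R(i, y)|`. It is a metric on permutations with
#' maximum value `floor(N^2 / 2)` attained by the full reversal.
#'
#' @param x,y [ranked_profile()]s over the same gene universe.
#' @return A non-negative integer; 0 iff the two orderings are identical.
#' @export
footrule_distance <- function(x, y) {
  stopifnot(inherits(x, "ranked_profile"), inherits(y, "ranked_profile"))
  if (!identical(names(x$ranks), names(y$ranks)))
    stop("profiles do not share the same gene universe", call. = FALSE)
  sum(abs(x$ranks - y$ranks))
}

#' Merge two ranked profiles with the Borda mean rule
#'
#' Each gene's score is the mean of its two ranks; genes are re-ranked by
#' ascending score, ties broken by lexicographic gene id, producing integer
#' ranks again (so the footrule between merged lists stays integer valued).
#'
#' @param x,y [ranked_profile()]s over the same gene universe.
#' @param name Label for the merged profile; default `"(<x>+<y>)"`.
#' @return A [ranked_profile()].
#' @export
borda_merge <- function(x, y, name = NULL) {
  stopifnot(inherits(x, "ranked_profile"), inherits(y, "ranked_profile"))
  if (!identical(names(x$ranks), names(y$ranks)))
    stop("profiles do not share the same gene universe", call. = FALSE)
  if (is.null(name)) name <- paste0("(", x$name, "+", y$name, ")")
  score <- (x$ranks + y$ranks) / 2
  genes <- names(x$ranks)
  ord <- order(score, genes)
  r <- integer(length(genes))
  r[ord] <- seq_along(genes)
  ranked_profile(stats::setNames(r, genes), name = name)
}

#' Build a prototype ranked list by iterative closest-pair merging
#'
#' Repeatedly computes all pairwise footrule distances among the current
#' profiles, merges the closest pair with [borda_merge()], replaces the pair
#' by the merged profile, and iterates until a single profile — the
#' prototype ranked list (PRL) — remains. Distances are recomputed after
#' every merge. Ties on the minimum distance are broken by the
#' lexicographically smallest sorted name pair, so the procedure is
#' deterministic.
#'
#' @param m A [ranked_matrix()] of replicate profiles for one biological
#'   state (use [intersect_profiles()] first if universes differ).
#' @return An object of class `merge_trace`: a list with `steps` (data frame
#'   of `step`, `left`, `right`, `footrule`, one row per merge) and `prl`
#'   (the final [ranked_profile()]).
#' @export
build_prl <- function(m) {
  if (!inherits(m, "ranked_matrix"))
    stop("'m' must be a ranked_matrix", call. = FALSE)
  pool <- lapply(profile_names(m), function(nm) get_profile(m, nm))
  steps <- data.frame(step = integer(), left = character(),
                      right = character(), footrule = numeric(),
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(pool) > 1L) {
    k <- length(pool)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        d <- footrule_distance(pool[[i]], pool[[j]])
        pair <- sort(c(pool[[i]]$name, pool[[j]]$name))
        if (is.null(best) || d < best$d ||
            (d == best$d && (pair[1L] < best$pair[1L] ||
                             (pair[1L] == best$pair[1L] &&
                              pair[2L] < best$pair[2L])))) {
          best <- list(i = i, j = j, d = d, pair = pair)
        }
      }
    }
    a <- pool[[best$i]]; b <- pool[[best$j]]
    if (a$name != best$pair[1L]) { tmp <- a; a <- b; b <- tmp }
    merged <- borda_merge(a, b)
    step <- step + 1L
    steps <- rbind(steps, data.frame(step = step, left = a$name,
                                     right = b$name, footrule = best$d,
                                     stringsAsFactors = FALSE))
    pool <- c(pool[-c(best$i, best$j)], list(merged))
  }
  structure(list(steps = steps, prl = pool[[1L]]), class = "merge_trace")
}

#' @export
print.merge_trace <- function(x, ...) {
  cat("merge_trace: ", nrow(x$steps), " merge step(s) -> PRL '",
      x$prl$name, "' (", x$prl$n, " genes)\n", sep = "")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Write a merge trace as TSV
#' @param trace A `merge_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_merge_trace <- function(trace, path) {
  stopifnot(inherits(trace, "merge_trace"))
  utils::write.table(trace$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
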