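# Input/output and construction of ranked expression profiles.
#
# A differential-expression profile maps gene ids to log2 fold changes; a
# ranked profile is the total ordering it induces (rank 1 = most
# upregulated). All downstream statistics (footrule, RRHO, TES) operate on
# ranked profiles over a shared gene universe.

#' Construct a differential-expression profile
#'
#' A `de_profile` holds one contrast's log2 fold changes keyed by gene id,
#' with optional p-values. Gene ids must be unique and fold changes finite;
#' no identifier mapping or probe collapsing is performed — matching is
#' exact, case-sensitive string equality.
#'
#' @param entries Named numeric vector: gene id -> log2 fold change.
#' @param name Profile label (free text).
#' @param pvalues Optional named numeric vector of p-values in (0, 1];
#'   names must be a subset of `names(entries)`.
#' @return An object of class `de_profile`.
#' @examples
#' de_profile(c(A = 2.5, B = -1.0, C = 0.3), name = "contrast1")
#' @export
de_profile <- function(entries, name = "profile", pvalues = NULL) {
  if (!is.numeric(entries) || length(entries) < 1L)
    stop("'entries' must be a non-empty named numeric vector", call. = FALSE)
  genes <- names(entries)
  if (is.null(genes) || any(is.na(genes)) || any(!nzchar(genes)))
    stop("every fold-change entry needs a non-empty gene id", call. = FALSE)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(entries))) {
    bad <- genes[!is.finite(entries)]
    stop("non-finite fold change for gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(pvalues)) {
    if (is.null(names(pvalues)) || !all(names(pvalues) %in% genes))
      stop("p-value names must be gene ids present in 'entries'", call. = FALSE)
    if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(name = as.character(name)[1L],
                 entries = entries,
                 pvalues = pvalues),
            class = "de_profile")
}

#' Read a differential-expression table
#'
#' Parses a tab-separated table with a header row into a [de_profile()].
#' Column names are configurable; defaults are `gene` and `log2fc`.
#' Duplicated gene ids and non-numeric or missing fold changes are errors
#' (the offending row is named), never silently dropped.
#'
#' @param path Path to a TSV file with a header row.
#' @param gene_col,fc_col Names of the gene-id and log2 fold-change columns.
#' @param p_col Optional name of a p-value column.
#' @param name Profile label; defaults to the file name without extension.
#' @return A `de_profile`.
#' @export
read_de_profile <- function(path, gene_col = "gene", fc_col = "log2fc",
                            p_col = NULL, name = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) < 1L)
    stop("no data rows in ", path, call. = FALSE)
  for (col in c(gene_col, fc_col, p_col))
    if (!col %in% names(tab))
      stop("missing column '", col, "' in ", path, call. = FALSE)
  genes <- tab[[gene_col]]
  fc_raw <- tab[[fc_col]]
  fc <- suppressWarnings(as.numeric(fc_raw))
  bad <- which(!is.finite(fc))
  if (length(bad))
    stop("non-numeric fold change '", fc_raw[bad[1L]], "' at row ", bad[1L],
         " (gene ", genes[bad[1L]], ")", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene id: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  names(fc) <- genes
  pv <- NULL
  if (!is.null(p_col)) {
    pv <- suppressWarnings(as.numeric(tab[[p_col]]))
    names(pv) <- genes
    pv <- pv[is.finite(pv)]
  }
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  de_profile(fc, name = name, pvalues = pv)
}

#' Construct a ranked profile
#'
#' A `ranked_profile` is a bijection between a gene universe of size N and
#' the ranks 1..N. Rank 1 is the most upregulated gene, rank N the most
#' downregulated. Entries are stored in lexicographic gene-id order so that
#' structurally equal profiles compare identical.
#'
#' @param ranks Named integer vector: gene id -> rank; must be exactly a
#'   permutation of `1:length(ranks)`.
#' @param name Profile label.
#' @return An object of class `ranked_profile` with fields `name`, `ranks`
#'   and universe size `n`.
#' @export
ranked_profile <- function(ranks, name = "profile") {
  genes <- names(ranks)
  if (is.null(genes) || any(is.na(genes)) || any(!nzchar(genes)))
    stop("ranks must be named by gene id", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene id: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  n <- length(ranks)
  r <- suppressWarnings(as.integer(ranks))
  if (any(is.na(r)) || any(r != ranks))
    stop("ranks must be integers", call. = FALSE)
  if (!identical(sort(r), seq_len(n)))
    stop("ranks are not a permutation of 1..", n, call. = FALSE)
  names(r) <- genes
  r <- r[order(genes)]
  structure(list(name = as.character(name)[1L], ranks = r, n = n),
            class = "ranked_profile")
}

#' @export
print.ranked_profile <- function(x, ...) {
  cat("ranked_profile '", x$name, "': ", x$n, " genes\n", sep = "")
  top <- names(sort(x$ranks))[seq_len(min(5L, x$n))]
  cat("  top ranks: ", paste(top, collapse = ", "),
      if (x$n > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
print.de_profile <- function(x, ...) {
  cat("de_profile '", x$name, "': ", length(x$entries), " genes",
      if (!is.null(x$pvalues)) ", with p-values" else "", "\n", sep = "")
  invisible(x)
}

#' Convert fold changes to a ranked profile
#'
#' Sorts a differential-expression profile in descending fold-change order
#' and assigns 1-based ranks: rank 1 = largest log2 fold change. Ties are
#' broken by lexicographic gene id, so the output is deterministic and
#' platform independent. Because only the ordering matters, the result is
#' invariant under any strictly monotone transform of the fold changes.
#'
#' @param x A [de_profile()] (a `ranked_profile` passes through unchanged).
#' @return A [ranked_profile()].
#' @examples
#' to_ranked_profile(de_profile(c(A = 2.5, B = -1.0, C = 0.3)))
#' @export
to_ranked_profile <- function(x) {
  if (inherits(x, "ranked_profile")) return(x)
  if (!inherits(x, "de_profile"))
    stop("'x' must be a de_profile or ranked_profile", call. = FALSE)
  n <- length(x$entries)
  ord <- order(-x$entries, names(x$entries))
  r <- integer(n)
  r[ord] <- seq_len(n)
  names(r) <- names(x$entries)
  ranked_profile(r, name = x$name)
}

#' Coerce to a ranked profile
#' @param x A `de_profile` or `ranked_profile`.
#' @return A `ranked_profile`.
#' @export
as_ranked_profile <- function(x) to_ranked_profile(x)

#' Construct a ranked matrix from profiles sharing one universe
#'
#' @param profiles List of [ranked_profile()]s over an identical gene
#'   universe, with unique names.
#' @return An object of class `ranked_matrix`: an integer rank matrix with
#'   genes (sorted universe) in rows and profiles in columns.
#' @export
ranked_matrix <- function(profiles) {
  if (!length(profiles))
    stop("at least one profile is required", call. = FALSE)
  profiles <- lapply(profiles, as_ranked_profile)
  nms <- vapply(profiles, function(p) p$name, character(1L))
  if (anyDuplicated(nms))
    stop("profile names must be unique: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  universe <- names(profiles[[1L]]$ranks)
  for (p in profiles[-1L])
    if (!identical(names(p$ranks), universe))
      stop("profiles do not share the same gene universe", call. = FALSE)
  ranks <- vapply(profiles, function(p) p$ranks, integer(length(universe)))
  dimnames(ranks) <- list(universe, nms)
  structure(list(universe = universe, ranks = ranks), class = "ranked_matrix")
}

#' @export
print.ranked_matrix <- function(x, ...) {
  cat("ranked_matrix: ", length(x$universe), " genes x ",
      ncol(x$ranks), " profiles (",
      paste(utils::head(colnames(x$ranks), 4L), collapse = ", "),
      if (ncol(x$ranks) > 4L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Profile names of a ranked matrix
#' @param m A `ranked_matrix`.
#' @return Character vector of profile labels.
#' @export
profile_names <- function(m) colnames(m$ranks)

#' Extract one profile from a ranked matrix
#' @param m A `ranked_matrix`.
#' @param name Profile label (or column index).
#' @return A [ranked_profile()].
#' @export
get_profile <- function(m, name) {
  if (is.numeric(name)) name <- colnames(m$ranks)[name]
  if (!name %in% colnames(m$ranks))
    stop("no profile named '", name, "'", call. = FALSE)
  ranked_profile(m$ranks[, name], name = name)
}

#' Intersect profiles onto a common gene universe
#'
#' Restricts each profile to the intersection of all gene sets and
#' re-compacts its ranks to `1..|universe|`, preserving each profile's
#' internal ordering. This is the standard preparation step before comparing
#' profiles from platforms that measure different gene sets.
#'
#' @param profiles List of two or more [ranked_profile()]s or
#'   [de_profile()]s (the latter are ranked first).
#' @return A [ranked_matrix()] over the common universe.
#' @export
intersect_profiles <- function(profiles) {
  if (length(profiles) < 2L)
    stop("at least two profiles are required", call. = FALSE)
  profiles <- lapply(profiles, as_ranked_profile)
  universe <- Reduce(intersect, lapply(profiles, function(p) names(p$ranks)))
  if (!length(universe))
    stop("empty intersection of gene universes", call. = FALSE)
  universe <- sort(universe)
  rescaled <- lapply(profiles, function(p) {
    r <- p$ranks[universe]
    ranked_profile(stats::setNames(as.integer(rank(r)), universe),
                   name = p$name)
  })
  ranked_matrix(rescaled)
}

#' Write / read a ranked matrix as TSV
#'
#' The on-disk format is a tab-separated table with a header row: first
#' column `gene`, one integer rank column per profile. `read_ranked_matrix`
#' validates that every profile column is a permutation of `1..N`;
#' `read_ranked_matrix(write_ranked_matrix(m, f))` is the identity.
#'
#' @param m A `ranked_matrix`.
#' @param path Output (or input) file path.
#' @return `write_ranked_matrix` returns `path` invisibly;
#'   `read_ranked_matrix` returns a `ranked_matrix`.
#' @export
write_ranked_matrix <- function(m, path) {
  if (!inherits(m, "ranked_matrix"))
    stop("'m' must be a ranked_matrix", call. = FALSE)
  out <- data.frame(gene = m$universe, m$ranks,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_matrix
#' @export
read_ranked_matrix <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    stop("empty file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) < 1L || ncol(tab) < 2L)
    stop("malformed ranked matrix in ", path,
         ": need a gene column plus at least one profile column",
         call. = FALSE)
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in ", path, call. = FALSE)
  profs <- lapply(names(tab)[-1L], function(cn) {
    r <- suppressWarnings(as.integer(tab[[cn]]))
    if (any(is.na(r)) || !identical(sort(r), seq_len(nrow(tab))))
      stop("column '", cn, "' is not a permutation of 1..", nrow(tab),
           call. = FALSE)
    ranked_profile(stats::setNames(r, genes), name = cn)
  })
  ranked_matrix(profs)
}
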