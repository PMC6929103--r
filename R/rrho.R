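# Rank-rank hypergeometric overlap (RRHO) maps.
#
# For two ranked profiles over the same N genes, cutoffs n and k step down
# both lists; each (n, k) pixel holds the signed -log10 hypergeometric tail
# probability of the observed overlap u between the two top segments:
# positive when u exceeds its expectation nk/N (over-tail), negative when it
# falls short (under-tail). Tails are computed in log space so that the
# astronomically small p-values of transcriptome-scale lists stay finite.

#' Default RRHO bin step size
#'
#' `ceiling(sqrt(N))`, so the number of pixels along each axis scales like
#' `sqrt(N)` and the total pixel count like N.
#'
#' @param n Universe size (number of genes), >= 1.
#' @return Integer step size, >= 1.
#' @export
default_step_size <- function(n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 1)
  max(1L, as.integer(ceiling(sqrt(n))))
}

#' Signed log10 hypergeometric tail probability
#'
#' Given a universe of `N` genes, top cutoffs `n` and `k` in the two lists
#' and an observed overlap `u`, returns `-log10 P(U >= u)` when the overlap
#' is at least its expectation `n*k/N` (enrichment, positive sign), and
#' `+log10 P(U <= u)` otherwise (depletion, negative sign). At exact
#' equality with the expectation the over-tail is used. The hypergeometric
#' pmf is `h(u; N, n, k) = C(k, u) C(N-k, n-u) / C(N, n)`; tails come from
#' [stats::phyper()] with `log.p = TRUE` (log-gamma based), so values far
#' below double underflow remain finite.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param N Universe size.
#' @param n,k Rank cutoffs in list 1 and list 2 (0..N).
#' @param u Overlap count; must satisfy `max(0, n+k-N) <= u <= min(n, k)`.
#' @return Signed log10 value(s); positive = more overlap than expected.
#' @examples
#' signed_log_p(10, 5, 5, 5)  #  log10(252): perfect overlap of two halves
#' signed_log_p(10, 5, 5, 0)  # -log10(252): perfect avoidance
#' @export
signed_log_p <- function(N, n, k, u) {
  len <- max(length(N), length(n), length(k), length(u))
  N <- rep_len(N, len); n <- rep_len(n, len)
  k <- rep_len(k, len); u <- rep_len(u, len)
  if (any(n < 0 | n > N | k < 0 | k > N))
    stop("cutoffs must satisfy 0 <= n, k <= N", call. = FALSE)
  if (any(u < pmax(0, n + k - N) | u > pmin(n, k)))
    stop("overlap u outside [max(0, n+k-N), min(n, k)]", call. = FALSE)
  over <- u * N >= n * k  # integer comparison: u >= E[U] = nk/N
  lp_over <- stats::phyper(u - 1, k, N - k, n, lower.tail = FALSE,
                           log.p = TRUE)
  lp_under <- stats::phyper(u, k, N - k, n, lower.tail = TRUE, log.p = TRUE)
  ifelse(over, -lp_over, lp_under) / log(10)
}

#' Rank-rank hypergeometric overlap map
#'
#' Steps cutoffs `n = step, 2*step, ...` down profile `x` and
#' `k = step, 2*step, ...` down profile `y`; pixel (i, j) records the
#' overlap `u = |top-n_i(x) intersect top-k_j(y)|` and its
#' [signed_log_p()] value. Trailing genes beyond the last full step do not
#' get a bin of their own, so the grid is square with
#' `floor(N / step)` pixels per side.
#'
#' @param x,y [ranked_profile()]s over the same gene universe.
#' @param step Bin step size in genes, `1 <= step <= N`; defaults to
#'   [default_step_size()] of the universe size.
#' @return An object of class `rrho_grid` with fields `values` (signed
#'   log10 p matrix, rows = cutoffs in `x`), `overlaps` (integer overlap
#'   counts), `thresholds_x`, `thresholds_y`, `step`, `n` (universe size),
#'   `corrected` flag and the two profile names.
#' @export
rrho_map <- function(x, y, step = default_step_size(x$n)) {
  stopifnot(inherits(x, "ranked_profile"), inherits(y, "ranked_profile"))
  if (!identical(names(x$ranks), names(y$ranks)))
    stop("profiles do not share the same gene universe", call. = FALSE)
  N <- x$n
  step <- as.integer(step)
  if (length(step) != 1L || is.na(step) || step < 1L || step > N)
    stop("'step' must be an integer in 1..N", call. = FALSE)
  nb <- N %/% step
  thr <- seq_len(nb) * step
  bx <- ceiling(x$ranks / step)
  by <- ceiling(y$ranks / step)
  keep <- bx <= nb & by <= nb
  counts <- matrix(0L, nb, nb)
  if (any(keep)) {
    tab <- table(factor(bx[keep], levels = seq_len(nb)),
                 factor(by[keep], levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nb, nb)
  }
  # cumulative in both directions: u(i, j) = #{rank_x <= i*step & rank_y <= j*step}
  u <- if (nb == 1L) counts
       else t(apply(apply(counts, 2L, cumsum), 1L, cumsum))
  nn <- matrix(thr, nb, nb, byrow = FALSE)  # row i: cutoff in x
  kk <- matrix(thr, nb, nb, byrow = TRUE)   # col j: cutoff in y
  vals <- matrix(signed_log_p(N, as.vector(nn), as.vector(kk), as.vector(u)),
                 nb, nb)
  dn <- list(paste0("n", thr), paste0("k", thr))
  dimnames(vals) <- dn
  dimnames(u) <- dn
  structure(list(values = vals, overlaps = u,
                 thresholds_x = thr, thresholds_y = thr,
                 step = step, n = N, corrected = FALSE,
                 x_name = x$name, y_name = y$name),
            class = "rrho_grid")
}

#' @export
print.rrho_grid <- function(x, ...) {
  cat("rrho_grid: ", nrow(x$values), "x", ncol(x$values),
      " pixels, step ", x$step, ", N = ", x$n,
      if (x$corrected) ", BY-corrected" else "",
      " ('", x$x_name, "' vs '", x$y_name, "')\n", sep = "")
  cat("  signed log10 p range: [",
      sprintf("%.3g", min(x$values)), ", ",
      sprintf("%.3g", max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Genes overlapping in one RRHO pixel
#'
#' Returns the genes in the top `n_i` of `x` that are also in the top `k_j`
#' of `y`, ordered by their rank in `x`. The length equals the stored
#' overlap count for that pixel.
#'
#' @param grid An `rrho_grid` computed from `x` and `y`.
#' @param x,y The two [ranked_profile()]s the grid was computed from.
#' @param i,j Pixel indices (row = cutoff in `x`, column = cutoff in `y`).
#' @return Character vector of gene ids.
#' @export
pixel_genes <- function(grid, x, y, i, j) {
  stopifnot(inherits(grid, "rrho_grid"))
  nb <- nrow(grid$values)
  if (length(i) != 1L || length(j) != 1L ||
      is.na(i) || is.na(j) || i < 1L || i > nb || j < 1L || j > nb)
    stop("pixel index out of range (grid is ", nb, "x", nb, ")",
         call. = FALSE)
  if (!identical(names(x$ranks), names(y$ranks)))
    stop("profiles do not share the same gene universe", call. = FALSE)
  sel <- x$ranks <= grid$thresholds_x[i] & y$ranks <= grid$thresholds_y[j]
  genes <- names(x$ranks)[sel]
  genes[order(x$ranks[sel])]
}

#' Benjamini-Yekutieli correction of an RRHO grid
#'
#' Converts each pixel's signed value back to a one-sided tail probability,
#' forms the two-tailed p-value `min(1, 2p)`, applies the
#' Benjamini-Yekutieli step-up adjustment across all pixels (valid under
#' the strong dependence between neighbouring pixels), and re-encodes the
#' adjusted values with the original signs.
#'
#' @param grid An uncorrected `rrho_grid`.
#' @return A new `rrho_grid` with `corrected = TRUE`.
#' @export
correct_grid <- function(grid) {
  stopifnot(inherits(grid, "rrho_grid"))
  if (isTRUE(grid$corrected))
    stop("grid is already corrected", call. = FALSE)
  v <- grid$values
  p_one <- 10^(-abs(v))
  p_two <- pmin(1, 2 * p_one)
  p_adj <- matrix(stats::p.adjust(as.vector(p_two), method = "BY"),
                  nrow(v), ncol(v), dimnames = dimnames(v))
  grid$values <- sign(v) * -log10(p_adj)
  grid$corrected <- TRUE
  grid
}

#' Render an RRHO grid as a heat map
#'
#' Writes a PNG with a diverging colour scale centred at 0 (blue =
#' depletion, red = enrichment). The cutoff in profile 1 runs along the
#' horizontal axis and profile 2 along the vertical axis, both increasing
#' away from the origin, so the bottom-left corner compares the top
#' (upregulated) ends of the two lists and the top-right corner the bottom
#' (downregulated) ends. The signed log10 value matrix is also written as
#' TSV next to the image for programmatic use.
#'
#' @param grid An `rrho_grid`.
#' @param path Output PNG path; the TSV is written to
#'   `<path without extension>.values.tsv`.
#' @return Invisibly, a list with the `png` and `tsv` paths.
#' @export
render_heatmap <- function(grid, path) {
  stopifnot(inherits(grid, "rrho_grid"))
  tsv <- paste0(tools::file_path_sans_ext(path), ".values.tsv")
  out <- data.frame(cutoff_x = grid$thresholds_x, grid$values,
                    check.names = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  lim <- max(abs(grid$values), 1e-12)
  pal <- grDevices::colorRampPalette(
    c("#2166AC", "#F7F7F7", "#B2182B"))(255L)
  ok <- tryCatch({
    grDevices::png(path, width = 800L, height = 800L)
    TRUE
  }, error = function(e) {
    stop("cannot write image to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(if (ok) grDevices::dev.off(), add = TRUE)
  graphics::image(x = grid$thresholds_x, y = grid$thresholds_y,
                  z = grid$values,
                  zlim = c(-lim, lim), col = pal,
                  xlab = paste0("rank cutoff in ", grid$x_name),
                  ylab = paste0("rank cutoff in ", grid$y_name),
                  main = sprintf("RRHO: %s vs %s (step %d%s)",
                                 grid$x_name, grid$y_name, grid$step,
                                 if (grid$corrected) ", BY" else ""),
                  useRaster = TRUE)
  invisible(list(png = path, tsv = tsv))
}
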