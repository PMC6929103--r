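# Synthetic ranked-profile fixtures with controlled concordance.
#
# Each group has its own random base ordering; replicates perturb the
# latent score -r (r = base rank) with Gaussian noise of sd sigma * N and
# re-rank. sigma = 0 reproduces the base ordering exactly; as sigma grows
# the replicates decorrelate towards independent permutations, whose
# expected pairwise footrule is (N^2 - 1) / 3.

#' Specify a synthetic fixture of ranked-profile groups
#'
#' @param n_genes Universe size N, >= 2.
#' @param groups Data frame with columns `label` (unique group labels),
#'   `replicates` (counts >= 1) and `noise` (sigma >= 0, the sd of the
#'   latent-score jitter as a fraction of N).
#' @param seed Integer seed; all randomness in [simulate_profiles()] and
#'   the group base orderings flows from it.
#' @return An object of class `fixture_spec`.
#' @examples
#' fixture_spec(200, data.frame(label = c("A", "B"), replicates = 5,
#'                              noise = 0.05), seed = 1)
#' @export
fixture_spec <- function(n_genes, groups, seed) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 2L)
    stop("'n_genes' must be an integer >= 2", call. = FALSE)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  need <- c("label", "replicates", "noise")
  if (!all(need %in% names(groups)) || nrow(groups) < 1L)
    stop("'groups' needs columns label, replicates, noise and >= 1 row",
         call. = FALSE)
  if (anyDuplicated(groups$label))
    stop("group labels must be unique", call. = FALSE)
  if (any(groups$replicates < 1L) || any(groups$replicates != round(groups$replicates)))
    stop("replicate counts must be integers >= 1", call. = FALSE)
  if (any(!is.finite(groups$noise)) || any(groups$noise < 0))
    stop("noise levels must be finite and >= 0", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(list(n_genes = n_genes, groups = groups, seed = seed),
            class = "fixture_spec")
}

# run expr with a private RNG stream seeded from `seed`, restoring any
# pre-existing global .Random.seed afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate groups of concordant ranked profiles
#'
#' For each group an independent uniform random base ordering is drawn.
#' Each replicate assigns gene `g` (at base rank `r_g`) the latent score
#' `-r_g + e_g`, `e_g ~ N(0, (sigma * N)^2)`, and ranks the latent scores
#' in descending order (ties, which occur only at sigma = 0, resolve to
#' the base ordering). The same seed always yields the same output.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `matrix` (a [ranked_matrix()] of all replicates,
#'   named `<label>_r<i>`), `labels` (named character vector: profile ->
#'   group label) and `bases` (list of the ground-truth base
#'   [ranked_profile()]s, one per group).
#' @export
simulate_profiles <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  N <- spec$n_genes
  genes <- sprintf("g%0*d", nchar(N), seq_len(N))
  .with_seed(spec$seed, {
    profs <- list()
    labels <- character(0)
    bases <- list()
    for (gi in seq_len(nrow(spec$groups))) {
      lab <- as.character(spec$groups$label[gi])
      reps <- as.integer(spec$groups$replicates[gi])
      sigma <- spec$groups$noise[gi]
      base_rank <- sample.int(N)
      names(base_rank) <- genes
      bases[[lab]] <- ranked_profile(base_rank, name = paste0(lab, "_base"))
      for (ri in seq_len(reps)) {
        latent <- -as.numeric(base_rank)
        if (sigma > 0) latent <- latent + stats::rnorm(N, sd = sigma * N)
        r <- as.integer(rank(-latent, ties.method = "first"))
        nm <- paste0(lab, "_r", ri)
        profs[[nm]] <- ranked_profile(stats::setNames(r, genes), name = nm)
        labels[nm] <- lab
      }
    }
    list(matrix = ranked_matrix(profs), labels = labels, bases = bases)
  })
}

#' Synthesize a differential-expression table from a ranked profile
#'
#' Generates strictly decreasing log2 fold-change values along the rank
#' order (cumulative exponential gaps, centred), so that
#' `to_ranked_profile(make_de_table(x))` recovers `x` exactly. Different
#' seeds give different fold-change values but the same ordering.
#'
#' @param x A [ranked_profile()].
#' @param seed Integer seed for the fold-change values.
#' @return A [de_profile()].
#' @export
make_de_table <- function(x, seed = 1L) {
  stopifnot(inherits(x, "ranked_profile"))
  N <- x$n
  .with_seed(as.integer(seed), {
    gaps <- stats::rexp(N, rate = 2)
    fc_sorted <- rev(cumsum(gaps))   # strictly decreasing, positive
    fc_sorted <- fc_sorted - mean(fc_sorted)
    fc <- fc_sorted[x$ranks]         # gene with rank r gets the r-th value
    de_profile(stats::setNames(fc, names(x$ranks)), name = x$name)
  })
}
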