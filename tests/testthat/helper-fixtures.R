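# Shared fixtures and independent oracles used across the suite.

# a uniformly random ranked profile over n synthetic gene ids
rand_profile <- function(n, name = "p") {
  genes <- sprintf("g%04d", seq_len(n))
  ranked_profile(stats::setNames(sample.int(n), genes), name = name)
}

# the full reversal: rank r -> n + 1 - r
rev_profile <- function(x, name = paste0(x$name, "_rev")) {
  ranked_profile(stats::setNames(x$n + 1L - x$ranks, names(x$ranks)),
                 name = name)
}

# all permutations of 1..n as rows (n! x n integer matrix)
all_perms <- function(n) {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], perms(v[-i]))))
  }
  unname(perms(seq_len(n)))
}

# brute-force hypergeometric pmf over u = 0..N from binomial coefficients
# (independent of stats::phyper / dhyper)
hyper_pmf_oracle <- function(N, n, k) {
  u <- 0:N
  p <- choose(k, u) * choose(N - k, n - u) / choose(N, n)
  p[!is.finite(p)] <- 0
  p
}

# signed log10 tail from the brute-force pmf
signed_log_p_oracle <- function(N, n, k, u) {
  pmf <- hyper_pmf_oracle(N, n, k)
  p_ge <- sum(pmf[seq.int(u + 1L, N + 1L)])
  p_le <- sum(pmf[seq_len(u + 1L)])
  if (u * N >= n * k) -log10(p_ge) else log10(p_le)
}

# run the installed command-line interface in a subprocess, propagating the
# current library paths
run_cli <- function(...) {
  cli <- system.file("cli", "rankcmp.R", package = "rankcmp")
  stopifnot(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(shQuote(cli), vapply(c(...), shQuote, character(1L))),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(),
                                  collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
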