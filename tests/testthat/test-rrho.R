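test_that("default step size is the ceiling square root", {
  expect_identical(default_step_size(100), 10L)
  expect_identical(default_step_size(1), 1L)
  expect_identical(default_step_size(101), 11L)
})

test_that("signed log10 tails match exact combinatorics on toy cases", {
  # two halves of a 10-gene universe overlapping perfectly: P(U>=5) = 1/252
  expect_equal(signed_log_p(10, 5, 5, 5), log10(252), tolerance = 1e-12)
  # perfect avoidance: P(U<=0) = 1/252, negative sign
  expect_equal(signed_log_p(10, 5, 5, 0), -log10(252), tolerance = 1e-12)
  # whole-list cutoff: overlap is certain, P = 1
  expect_equal(signed_log_p(10, 10, 4, 4), 0)

  expect_error(signed_log_p(10, 5, 5, 6), "outside")
  expect_error(signed_log_p(10, 3, 9, 1), "outside")  # u below max(0, n+k-N)
  expect_error(signed_log_p(10, 11, 5, 5), "cutoffs")
})

test_that("signed log10 tails agree with the brute-force pmf oracle", {
  set.seed(41)
  for (rep in 1:200) {
    N <- sample(2:25, 1)
    n <- sample(0:N, 1); k <- sample(0:N, 1)
    rng <- max(0, n + k - N):min(n, k)
    u <- rng[sample.int(length(rng), 1)]
    expect_equal(signed_log_p(N, n, k, u), signed_log_p_oracle(N, n, k, u),
                 tolerance = 1e-9)
  }
})

test_that("over- and under-tails of the oracle pmf are complementary", {
  for (N in c(6, 13, 20)) {
    for (n in 0:N) for (k in 0:N) {
      pmf <- hyper_pmf_oracle(N, n, k)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      for (u in max(1, n + k - N):min(n, k)) {
        p_ge <- sum(pmf[seq.int(u + 1L, N + 1L)])
        p_le_prev <- sum(pmf[seq_len(u)])
        expect_equal(p_ge + p_le_prev, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("the RRHO self-map peaks on the diagonal with full overlaps", {
  set.seed(43)
  x <- rand_profile(100, "x")
  g <- rrho_map(x, x, step = 10)
  expect_equal(dim(g$values), c(10L, 10L))
  expect_equal(diag(g$overlaps), g$thresholds_x, ignore_attr = TRUE)
  expect_true(all(diag(g$values) >= 0))
  expect_equal(max(g$values), max(diag(g$values)))
})

test_that("RRHO maps transpose under argument exchange", {
  set.seed(47)
  x <- rand_profile(90, "x"); y <- rand_profile(90, "y")
  gxy <- rrho_map(x, y, step = 9)
  gyx <- rrho_map(y, x, step = 9)
  expect_equal(unname(gxy$values), unname(t(gyx$values)))
  expect_equal(unname(gxy$overlaps), unname(t(gyx$overlaps)))
})

test_that("reversed profiles deplete the co-regulation corner", {
  set.seed(53)
  x <- rand_profile(100, "x")
  g <- rrho_map(x, rev_profile(x), step = 10)
  expect_identical(g$overlaps[1L, 1L], 0L)
  expect_lte(g$values[1L, 1L], 0)
})

test_that("degenerate and invalid step sizes are handled", {
  set.seed(59)
  x <- rand_profile(30, "x"); y <- rand_profile(30, "y")
  g <- rrho_map(x, y, step = 30)
  expect_equal(dim(g$values), c(1L, 1L))
  expect_identical(g$overlaps[1L, 1L], 30L)
  expect_equal(g$values[1L, 1L], 0, ignore_attr = TRUE)

  expect_error(rrho_map(x, y, step = 0), "step")
  expect_error(rrho_map(x, y, step = 31), "step")
  z <- rand_profile(10, "z")
  expect_error(rrho_map(x, z), "universe")
})

test_that("independent profiles rarely reach nominal significance", {
  set.seed(61)
  x <- rand_profile(400, "x"); y <- rand_profile(400, "y")
  g <- rrho_map(x, y, step = 20)
  frac <- mean(abs(g$values) > -log10(0.05))
  expect_lt(frac, 0.15)
})

test_that("pixel gene lists match brute-force set intersection", {
  set.seed(67)
  x <- rand_profile(40, "x")
  g_self <- rrho_map(x, x, step = 5)
  expect_equal(pixel_genes(g_self, x, x, 1, 1),
               names(sort(x$ranks))[1:5])

  # 6-gene toy, step 2, hand-constructed profiles
  a <- ranked_profile(c(A = 1L, B = 2L, C = 3L, D = 4L, E = 5L, F = 6L), "a")
  b <- ranked_profile(c(A = 5L, B = 1L, C = 6L, D = 2L, E = 3L, F = 4L), "b")
  g <- rrho_map(a, b, step = 2)
  for (i in 1:3) for (j in 1:3) {
    expected <- intersect(names(sort(a$ranks))[seq_len(2 * i)],
                          names(sort(b$ranks))[seq_len(2 * j)])
    got <- pixel_genes(g, a, b, i, j)
    expect_setequal(got, expected)
    expect_equal(length(got), g$overlaps[i, j], ignore_attr = TRUE)
    expect_false(is.unsorted(a$ranks[got]))  # ordered by rank in a
  }

  # disjoint top bins give an empty list
  g_rev <- rrho_map(a, rev_profile(a, "ar"), step = 2)
  expect_length(pixel_genes(g_rev, a, rev_profile(a, "ar"), 1, 1), 0)

  expect_error(pixel_genes(g, a, b, 4, 1), "out of range")
  expect_error(pixel_genes(g, a, b, 1, 0), "out of range")
})

test_that("Benjamini-Yekutieli correction matches the step-up formula", {
  set.seed(71)
  x <- rand_profile(20, "x"); y <- rand_profile(20, "y")
  g <- rrho_map(x, y, step = 10)  # 2x2 grid
  corrected <- correct_grid(g)
  expect_true(corrected$corrected)
  expect_error(correct_grid(corrected), "already corrected")

  # independent step-up BY oracle on the two-tailed p-values
  p_two <- pmin(1, 2 * 10^(-abs(g$values)))
  m <- length(p_two)
  cm <- sum(1 / seq_len(m))
  ord <- order(p_two)
  adj <- pmin(1, rev(cummin(rev(m * cm * p_two[ord] / seq_len(m)))))
  expected <- numeric(m); expected[ord] <- adj
  expect_equal(as.vector(abs(corrected$values)),
               -log10(expected), tolerance = 1e-12)
  expect_equal(sign(as.vector(corrected$values)[expected < 1]),
               sign(as.vector(g$values)[expected < 1]))

  # single-pixel grid: adjustment with m = 1 changes nothing
  g1 <- rrho_map(x, y, step = 20)
  expect_equal(correct_grid(g1)$values, g1$values)
})

test_that("heat maps export a PNG plus the value matrix as TSV", {
  set.seed(73)
  x <- rand_profile(60, "x")
  g <- rrho_map(x, x, step = 10)
  png_path <- withr::local_tempfile(fileext = ".png")
  out <- render_heatmap(g, png_path)
  expect_true(file.exists(out$png))
  expect_gt(file.size(out$png), 0)
  tsv <- utils::read.delim(out$tsv, check.names = FALSE)
  expect_equal(tsv$cutoff_x, g$thresholds_x)
  vals <- as.matrix(tsv[, -1L])
  expect_equal(unname(vals), unname(g$values), tolerance = 1e-6)
  expect_true(all(diag(vals) >= 0))  # identical profiles: positive diagonal

  # reversal: co-regulation corner depleted, anti-diagonal corners maximal
  gr <- rrho_map(x, rev_profile(x), step = 10)
  out2 <- render_heatmap(gr, withr::local_tempfile(fileext = ".png"))
  v <- as.matrix(utils::read.delim(out2$tsv, check.names = FALSE)[, -1L])
  nb <- nrow(v)
  expect_lt(v[1, 1], 0)
  expect_equal(unname(v[1, nb]), max(v), tolerance = 1e-9)
  expect_equal(unname(v[nb, 1]), max(v), tolerance = 1e-9)

  # 1x1 grid still writes a single-cell matrix
  g1 <- rrho_map(x, x, step = 60)
  out3 <- render_heatmap(g1, withr::local_tempfile(fileext = ".png"))
  v1 <- utils::read.delim(out3$tsv, check.names = FALSE)
  expect_equal(dim(v1), c(1L, 2L))
})
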