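test_that("residue_inputs keeps only scored missense guides in range", {
  scored <- tibble::tibble(
    guide_id = paste0("g", 1:6),
    outcome_class = c("missense", "nonsense", "silent", "non_editing",
                      "missense", "missense"),
    representative_residue = c(10L, 11L, NA, NA, 311L, 311L),
    score = c(1, 2, NA, NA, 0.5, -0.5)
  )
  inp <- residue_inputs(scored, L = 400)
  expect_equal(inp$position, c(10L, 311L, 311L))  # duplicates retained
  expect_equal(inp$score, c(1, 0.5, -0.5))
  expect_error(residue_inputs(scored[3:4, ], L = 400), "no missense")
})

test_that("constant scores give a constant track and p = 1 everywhere", {
  set.seed(1)
  pos <- sort(sample(1:50, 30, replace = TRUE))
  cfg <- clustering_config(n_perm = 50, seed = 4)
  tr <- loess_interpolate(pos, rep(2.5, 30), L = 50, config = cfg)
  expect_equal(tr$loess_score, rep(2.5, 50), tolerance = 1e-12)
  expect_equal(tr$interpolated, tabulate(pos, 50) == 0)
  pt <- permutation_pvalues(pos, rep(2.5, 30), L = 50, config = cfg)
  expect_equal(pt$p_emp, rep(1, 50))
})

test_that("collinear scores are reproduced exactly across 1..L", {
  pos <- 1:60
  sc <- 0.3 * pos - 2
  tr <- loess_interpolate(pos, sc, L = 60)
  expect_lt(max(abs(tr$loess_score - sc)), 1e-9)
})

test_that("the smoother agrees with an independent tricube local-linear
           oracle at observed positions", {
  set.seed(17)
  n <- 80; L <- 200
  pos <- sort(sample(1:L, n, replace = FALSE))
  sc <- rnorm(n) + sin(pos / 15)
  cfg <- clustering_config(window_aa = 20)
  tr <- loess_interpolate(pos, sc, L = L, config = cfg)
  want <- oracle_lowess(as.numeric(pos), sc, f = 20 / L)
  expect_lt(max(abs(tr$loess_score[pos] - want)), 1e-8)
})

test_that("quadratic spline interpolation reproduces the reference
           values on a fixed instance", {
  # frozen from an independent quadratic-B-spline interpolation of the
  # same knot convention (boundary knots tripled, interior knots at
  # midpoints of consecutive sites without the outermost two)
  x <- c(1, 2.5, 4, 7, 9, 12)
  y <- c(0.3, -1.2, 2.0, 0.5, 1.1, -0.4)
  expected <- c(0.300000000, -1.370332712, -0.359334576, 2.000000000,
                2.449240242, 1.209930520, 0.500000000, 0.689103542,
                1.100000000, 1.055448229, 0.555448229, -0.400000000)
  machine <- bescan:::qspline_machine(x, seq(1, 12, length.out = 12))
  expect_equal(machine(y), expected, tolerance = 1e-9)
})

test_that("residues outside the observed span are clamped to the
           nearest fitted value and flagged interpolated", {
  pos <- 11:40
  set.seed(23)
  sc <- rnorm(30)
  tr <- loess_interpolate(pos, sc, L = 60)
  expect_equal(tr$loess_score[1:10], rep(tr$loess_score[11], 10))
  expect_equal(tr$loess_score[41:60], rep(tr$loess_score[40], 20))
  expect_true(all(tr$interpolated[c(1:10, 41:60)]))
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(31)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("cluster calling returns maximal contiguous runs", {
  cl <- call_clusters(c(0.2, 0.01, 0.02, 0.3), alpha = 0.05)
  expect_equal(cl$start_res, 2L)
  expect_equal(cl$end_res, 3L)
  expect_equal(cl$min_p_adj, 0.01)
  expect_equal(nrow(call_clusters(rep(0.5, 10), 0.05)), 0L)
  all_in <- call_clusters(rep(0.01, 7), 0.05)
  expect_equal(c(all_in$start_res, all_in$end_res, all_in$width),
               c(1L, 7L, 7L))
})

test_that("the plotting transform applies the documented pseudocount", {
  expect_equal(neglog_transform(1), -log10(1.0001))
  expect_equal(neglog_transform(1e-4), -log10(2e-4))
  expect_equal(neglog_transform(0.05), -log10(0.0501))
})

test_that("permutation p-values are seed-deterministic", {
  set.seed(5)
  pos <- sort(sample(1:80, 60, replace = TRUE))
  sc <- rnorm(60)
  cfg <- clustering_config(n_perm = 100, seed = 11)
  p1 <- permutation_pvalues(pos, sc, L = 80, config = cfg)
  p2 <- permutation_pvalues(pos, sc, L = 80, config = cfg)
  expect_identical(p1, p2)
  p3 <- permutation_pvalues(pos, sc, L = 80,
                            config = clustering_config(n_perm = 100,
                                                       seed = 12))
  expect_false(identical(p1$p_emp, p3$p_emp))
})

test_that("a single strong outlier yields its smallest p-values near
           the outlier position", {
  set.seed(6)
  pos <- sort(sample(1:100, 70, replace = TRUE))
  sc <- rnorm(70, 0, 0.05)
  target <- which.min(abs(pos - 50))[1]
  sc[pos == pos[target]] <- 8  # all guides at that residue spike
  cfg <- clustering_config(n_perm = 200, seed = 2)
  pt <- permutation_pvalues(pos, sc, L = 100, config = cfg)
  best <- which(pt$p_emp == min(pt$p_emp))
  expect_true(any(abs(best - pos[target]) <= 10))
})

test_that("cluster calls are invariant to a score translation", {
  set.seed(7)
  pos <- sort(sample(1:60, 50, replace = TRUE))
  sc <- rnorm(50)
  sc[pos >= 25 & pos <= 35] <- sc[pos >= 25 & pos <= 35] + 3
  cfg <- clustering_config(n_perm = 300, seed = 9)
  t1 <- residue_clustering(tibble::tibble(position = pos, score = sc),
                           L = 60, config = cfg)
  t2 <- residue_clustering(tibble::tibble(position = pos,
                                          score = sc + 100),
                           L = 60, config = cfg)
  expect_equal(clusters(t1), clusters(t2))
  expect_equal(t1$p_emp, t2$p_emp, tolerance = 1e-12)
})

test_that("residue_clustering assembles track, transform and clusters
           coherently", {
  set.seed(8)
  pos <- sort(sample(1:50, 45, replace = TRUE))
  sc <- rnorm(45)
  cfg <- clustering_config(n_perm = 100, seed = 3)
  tr <- residue_clustering(tibble::tibble(position = pos, score = sc),
                           L = 50, config = cfg)
  expect_equal(nrow(tr), 50L)
  expect_true(all(tr$p_emp > 0 & tr$p_emp <= 1))
  expect_equal(tr$p_adj, bh_adjust(tr$p_emp))
  expect_equal(tr$neglog10_padj, -log10(tr$p_adj + 1e-4))
  expect_equal(tr$in_cluster, tr$p_adj <= cfg$alpha)
  cl <- clusters(tr)
  in_cl <- rep(FALSE, 50)
  if (nrow(cl) > 0) {
    for (i in seq_len(nrow(cl))) in_cl[cl$start_res[i]:cl$end_res[i]] <- TRUE
  }
  expect_equal(tr$in_cluster, in_cl)
})
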