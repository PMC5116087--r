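test_that("group t-test matches stats::t.test and handles edge cases", {
  # hand-specified example against the textbook Welch computation
  ca <- matrix(c(5.1, 4.9, 5.0), 1, 3,
               dimnames = list("g1", paste0("c", 1:3)))
  no <- matrix(c(3.1, 2.9, 3.0), 1, 3,
               dimnames = list("g1", paste0("n", 1:3)))
  res <- groupTTest(ca, no)
  ref <- stats::t.test(ca[1, ], no[1, ])
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)

  # vectorized path against per-gene t.test on a random matrix
  set.seed(21)
  X <- matrix(rnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("c", 1:6)))
  Y <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("n", 1:4)))
  res <- groupTTest(X, Y)
  for (i in c(1, 17, 50)) {
    ref <- stats::t.test(X[i, ], Y[i, ])
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
  }

  # identical groups: zero t, p = 1
  Z <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  same <- groupTTest(Z, `colnames<-`(Z, c("x", "y")))
  expect_equal(same$p_value, c(1, 1))

  # zero variance in both groups, different means: weight-1 signal
  ca0 <- matrix(10, 1, 4, dimnames = list("g1", paste0("c", 1:4)))
  no0 <- matrix(8, 1, 4, dimnames = list("g1", paste0("n", 1:4)))
  r0 <- groupTTest(ca0, no0)
  expect_equal(r0$p_value, 1e-7)
  expect_equal(statisticalWeight(r0$p_value), 1)

  expect_error(groupTTest(ca[, 1, drop = FALSE], no), "2 samples")
})

test_that("log fold changes use the mean-log2 (geometric) normal reference", {
  pair <- exact_expr_pair(c(g1 = 3), c(g1 = 3))
  expect_true(all(logFoldChanges(pair$cases, pair$normals) == 0))

  # linear scale: case 8 vs normals {2, 2} -> log2(8) - log2(2) = 2
  ca <- ExpressionData(matrix(8, 1, 1, dimnames = list("g1", "c1")),
                       scale = "linear")
  no <- ExpressionData(matrix(c(2, 2), 1, 2,
                              dimnames = list("g1", c("n1", "n2"))),
                       scale = "linear")
  expect_equal(logFoldChanges(ca, no)["g1", "c1"], 2)

  # normals {1, 4} linear: reference is mean(0, 2) = 1 on log2 scale
  no2 <- ExpressionData(matrix(c(1, 4), 1, 2,
                               dimnames = list("g1", c("n1", "n2"))),
                        scale = "linear")
  ca2 <- ExpressionData(matrix(4, 1, 1, dimnames = list("g1", "c1")),
                        scale = "linear")
  expect_equal(logFoldChanges(ca2, no2)["g1", "c1"], 1)
})

test_that("swapping group labels negates fold changes, p-values unchanged", {
  set.seed(33)
  X <- matrix(rnorm(30 * 5, 7), 30, 5,
              dimnames = list(sprintf("g%02d", 1:30), paste0("c", 1:5)))
  Y <- matrix(rnorm(30 * 5, 7), 30, 5,
              dimnames = list(sprintf("g%02d", 1:30), paste0("n", 1:5)))
  fwd <- groupTTest(X, Y)
  rev <- groupTTest(Y, X)
  expect_equal(fwd$p_value, rev$p_value)
  lf <- rowMeans(logFoldChanges(X, Y))
  lr <- rowMeans(logFoldChanges(Y, X))
  # per-sample references differ, but the group-mean contrast negates
  expect_equal(unname(lf), -unname(lr), tolerance = 1e-12)
})

test_that("statistical weights trace the smooth cosine threshold", {
  expect_equal(statisticalWeight(1e-8), 1)
  expect_equal(statisticalWeight(1e-7), 1)
  expect_equal(statisticalWeight(1e-4), 0.5)
  expect_equal(statisticalWeight(1e-1), 0)
  expect_equal(statisticalWeight(0.5), 0)
  expect_equal(statisticalWeight(1e-2), 0.5 * (1 + cos(5 * pi / 6)),
               tolerance = 1e-12)
  # continuous and monotone non-increasing over the whole domain
  grid <- 10^seq(-9, 0, length.out = 1000)
  w <- statisticalWeight(grid)
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0 & w <= 1))
  expect_error(statisticalWeight(0), "\\(0, 1\\]")
  expect_error(statisticalWeight(-0.1), "\\(0, 1\\]")
  expect_error(statisticalWeight(0.5, pMin = 0.2, pMax = 0.1), "pMin")
})

test_that("weight tables are per-dataset and blind to other datasets", {
  set.seed(44)
  mk <- function(seed) {
    set.seed(seed)
    list(
      ca = matrix(rnorm(20 * 4, 7), 20, 4,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  paste0("c", 1:4))),
      no = matrix(rnorm(20 * 4, 7), 20, 4,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  paste0("n", 1:4))))
  }
  d1 <- mk(1)
  w_before <- statWeightTable(d1$ca, d1$no)
  d2 <- mk(2)                      # a second, unrelated dataset
  invisible(statWeightTable(d2$ca, d2$no))
  w_after <- statWeightTable(d1$ca, d1$no)
  expect_identical(w_before, w_after)
})
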