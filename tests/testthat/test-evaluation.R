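test_that("quadrant labels follow the cutoff with ties going high", {
  expect_equal(quadrant_label(7, 8, 5), 0L)     # HVHA
  expect_equal(quadrant_label(7, 2, 5), 1L)     # HVLA
  expect_equal(quadrant_label(2, 8, 5), 2L)     # LVHA
  expect_equal(quadrant_label(3, 2, 5), 3L)     # LVLA
  expect_equal(quadrant_label(5, 5, 5), 0L)     # ties assigned to high
  expect_equal(quadrant_label(c(7, 3), c(8, 2), 5), c(0L, 3L))
  expect_equal(quadrant_label(2.4, 2.5, 2.5, scale_max = 5), 2L)
  expect_error(quadrant_label(10, 5, 5), "ratings")
})

test_that("the 8:2 split is exact, disjoint, exhaustive and seeded", {
  sp <- split_train_test(100, 0.8, 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:100)
  expect_identical(split_train_test(100, 0.8, 1), sp)
  expect_false(identical(split_train_test(100, 0.8, 2), sp))
  sp3 <- split_train_test(10, 0.25, 1)
  expect_length(sp3$train, 2)                   # floor(0.25 * 10)
  expect_error(split_train_test(1, 0.8, 1), "at least 2")
  expect_error(split_train_test(10, 1.2, 1), "ratio")
})

test_that("metrics reproduce the hand-computed confusion example", {
  r <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(r$accuracy, 75)
  pc <- r$per_class
  expect_equal(pc$precision[1], 100)
  expect_equal(pc$recall[1], 50)
  expect_equal(pc$f1[1], 200 / 3, tolerance = 1e-10)
  expect_equal(pc$precision[2], 200 / 3, tolerance = 1e-10)
  expect_equal(pc$recall[2], 100)
  expect_equal(pc$f1[2], 80)
  perfect <- compute_metrics(0:3, 0:3)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall, perfect$f1),
               rep(100, 4))
  expect_equal(compute_metrics(c(0, 1), c(1, 0))$accuracy, 0)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
  expect_error(compute_metrics(0:2, 0:1), "length")
})

test_that("accuracy equals trace(confusion)/n and macro metrics are label-permutation invariant", {
  set.seed(3)
  for (i in 1:10) {
    y <- sample(0:3, 60, replace = TRUE)
    p <- ifelse(runif(60) < 0.6, y, sample(0:3, 60, replace = TRUE))
    r <- compute_metrics(y, p)
    expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) / 60)
    expect_equal(sum(r$confusion), 60)
    expect_equal(as.vector(rowSums(r$confusion)), tabulate(y + 1, 4))
    perm <- sample(0:3)
    r2 <- compute_metrics(perm[y + 1], perm[p + 1])
    expect_equal(r2$precision, r$precision, tolerance = 1e-10)
    expect_equal(r2$recall, r$recall, tolerance = 1e-10)
    expect_equal(r2$f1, r$f1, tolerance = 1e-10)
  }
})

test_that("Cronbach's alpha matches its closed forms and the covariance-based oracle", {
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(2, 3, 4))), 1)
  m_same <- cbind(c(1, 5, 2, 4), c(1, 5, 2, 4), c(1, 5, 2, 4))
  expect_equal(cronbach_alpha(m_same), 1)
  # anti-correlated items can give negative alpha
  expect_lt(cronbach_alpha(cbind(c(1, 2, 3), c(3, 2, 1) * 2)), 0)
  expect_error(cronbach_alpha(matrix(1, 3, 2)), "zero total variance")
  expect_error(cronbach_alpha(matrix(1:3, 3, 1)), ">= 2")
  # covariance-form oracle: alpha = k*cbar / (vbar + (k-1)*cbar)
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    m <- matrix(rnorm(8 * k), 8) + rnorm(8) * runif(1, 0, 2)
    V <- cov(m)
    cbar <- mean(V[upper.tri(V)])
    vbar <- mean(diag(V))
    expect_equal(cronbach_alpha(m), k * cbar / (vbar + (k - 1) * cbar),
                 tolerance = 1e-10)
  }
})
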