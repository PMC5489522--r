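# Sobol' machinery: sample-size rule, Saltelli design, Jansen estimators,
# ideotype extraction.

test_that("sample-size rule returns the smallest admissible design", {
  # brute-force oracle over q
  oracle <- function(n, gamma) {
    m <- 2^((1:30) + 3) * (2 * n + 2)
    m[m > gamma * n][1]
  }
  cases <- expand.grid(n = c(1, 3, 10, 17), gamma = c(1, 50, 500, 2000))
  for (i in seq_len(nrow(cases))) {
    expect_equal(sobol_sample_size(cases$n[i], cases$gamma[i]),
                 oracle(cases$n[i], cases$gamma[i]))
  }
  expect_equal(sobol_sample_size(10, 500), 5632)
  expect_equal(sobol_sample_size(1, 1), 64)
  expect_error(sobol_sample_size(0, 10), ">= 1")
})

test_that("trait distributions implement the 5%-of-mean rule", {
  d <- trait_distributions()
  expect_equal(nrow(d), 10)
  expect_equal(d$sd, 0.05 * d$mean)
  expect_true(all(d$lower > 0))
  expect_true(all(d$upper[d$name %in%
                            c("sub_dep_eff", "na_to_pan", "part_cap")] <= 1))
  expect_equal(sort(unique(d$trait)), c("T1", "T2", "T3", "T4", "T5"))
})

test_that("Saltelli design has the block structure and row count", {
  d <- trait_distributions()
  des <- saltelli_sample(d, 256, seed = 1)
  expect_equal(nrow(des$matrix), 256 * (2 * 10 + 2))
  expect_equal(nrow(des$matrix), sobol_sample_size(10, 500))
  expect_identical(des$matrix, saltelli_sample(d, 256, seed = 1)$matrix)
  # AB_i blocks differ from A in exactly column i
  a <- des$matrix[1:256, ]
  b <- des$matrix[256 + 1:256, ]
  for (i in c(1, 5, 10)) {
    abi <- des$matrix[(1 + i) * 256 + 1:256, ]
    expect_equal(abi[, i], b[, i])
    expect_equal(abi[, -i], a[, -i])
  }
  # degenerate marginals collapse every row onto the means
  d0 <- d; d0$sd <- 0; d0$lower <- d0$mean; d0$upper <- d0$mean
  des0 <- saltelli_sample(d0, 8, seed = 2)
  expect_equal(unname(des0$matrix),
               matrix(d$mean, 8 * 22, 10, byrow = TRUE))
  # marginals respect their truncation bounds
  expect_true(all(sweep(des$matrix, 2, d$lower, ">=")))
  expect_true(all(sweep(des$matrix, 2, d$upper, "<=")))
})

test_that("indices recover an additive linear benchmark", {
  # closed form: for y = sum a_i x_i with independent x_i,
  # S_i = ST_i = a_i^2 Var(x_i) / sum(a_j^2 Var(x_j))
  a <- c(4, 2, 1, 0)
  dists <- uniform_distributions(paste0("x", 1:4), 0, 1)
  des <- saltelli_sample(dists, 1024, seed = 3)
  y <- as.numeric(des$matrix %*% a)
  res <- sobol_indices(y, des, n_boot = 50)
  truth <- a^2 * (1 / 12) / sum(a^2 / 12)
  expect_false(res$degenerate)
  # ~3 sigma of the Jansen estimators at this base size: the first-order
  # form has sampling error proportional to (1 - S_i), the total-order
  # form is much tighter
  expect_lt(max(abs(res$indices$first - truth)), 0.12)
  expect_lt(max(abs(res$indices$total - truth)), 0.07)
  # inactive parameter: total order is exact by construction (the A and
  # AB_4 blocks give identical outputs), first order within MC noise
  expect_lt(abs(res$indices$first[4]), 0.12)
  expect_lt(abs(res$indices$total[4]), 1e-9)
  # first <= total within Monte-Carlo slack, everything in [0,1] band
  expect_true(all(res$indices$first <= res$indices$total + 0.12))
  expect_true(all(res$indices$total >= -0.05 &
                    res$indices$total <= 1.05))
  # bootstrap intervals bracket the point estimates
  expect_true(all(res$indices$first_lo <= res$indices$first + 1e-9))
  expect_true(all(res$indices$first_hi >= res$indices$first - 1e-9))
})

test_that("indices recover the Ishigami benchmark", {
  # analytic values for a = 7, b = 0.1 over [-pi, pi]^3
  a <- 7; b <- 0.1
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * 8 / 225
  v <- v1 + v2 + v13
  truth_first <- c(v1, v2, 0) / v
  truth_total <- c(v1 + v13, v2, v13) / v
  dists <- uniform_distributions(c("x1", "x2", "x3"), -pi, pi)
  des <- saltelli_sample(dists, 1024, seed = 4)
  x <- des$matrix
  y <- sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1])
  res <- sobol_indices(y, des, n_boot = 0)
  expect_lt(max(abs(res$indices$first - truth_first)), 0.12)
  expect_lt(max(abs(res$indices$total - truth_total)), 0.07)
})

test_that("estimator error shrinks as the base sample doubles", {
  a <- c(4, 2, 1, 0.5)
  dists <- uniform_distributions(paste0("x", 1:4), 0, 1)
  truth <- a^2 / sum(a^2)
  rms <- vapply(c(128, 1024), function(n) {
    errs <- vapply(1:4, function(s) {
      des <- saltelli_sample(dists, n, seed = s)
      y <- as.numeric(des$matrix %*% a)
      res <- sobol_indices(y, des, n_boot = 0)
      sqrt(mean((res$indices$first - truth)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(rms[2], rms[1])
})

test_that("zero output variance is flagged as degenerate", {
  dists <- uniform_distributions(c("x1", "x2"), 0, 1)
  des <- saltelli_sample(dists, 16, seed = 5)
  res <- sobol_indices(rep(3.3, nrow(des$matrix)), des, n_boot = 0)
  expect_true(res$degenerate)
  expect_true(all(is.na(res$indices$first)))
})

test_that("ideotype selection returns the best-yield row", {
  m <- matrix(seq_len(12), nrow = 4)
  expect_equal(as.numeric(select_ideotype(m, c(1, 9, 4, 2))), m[2, ])
  expect_equal(attr(select_ideotype(m, c(1, 9, 4, 2)), "row"), 2)
  # ties break to the lowest row index
  expect_equal(attr(select_ideotype(m, c(5, 5, 5, 5)), "row"), 1)
  expect_equal(as.numeric(select_ideotype(m[1, , drop = FALSE], 7)),
               m[1, ])
  # strictly increasing outputs pick the last row
  expect_equal(attr(select_ideotype(m, 1:4), "row"), 4)
  # known-optimum quadratic response: picked row is the argmax by
  # brute-force enumeration
  dists <- uniform_distributions(c("x1", "x2"), 0, 1)
  des <- saltelli_sample(dists, 64, seed = 6)
  y <- -(des$matrix[, 1] - 0.4)^2 - (des$matrix[, 2] - 0.7)^2
  pick <- select_ideotype(des, y)
  expect_equal(attr(pick, "row"), which.max(y))
  expect_error(select_ideotype(m, 1:3), "align")
})
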