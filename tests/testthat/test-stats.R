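# independent enumeration oracle for the two-sided Fisher p-value: explicit
# binomial-coefficient arithmetic, no distribution functions
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  probs <- exp(lp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# independent U oracle: count discordant (x > y) pairs, ties as 1/2
u_oracle <- function(x, y)
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

test_that("fisher_exact matches hand-enumerable tables", {
  expect_equal(fisher_exact(two_by_two(2, 0, 0, 2))$p_two_sided, 1 / 3)
  expect_equal(fisher_exact(two_by_two(5, 5, 5, 5))$p_two_sided, 1)
  # the lateral-notching comparison: 59/59 vs 100/118
  res <- fisher_exact(two_by_two(59, 0, 100, 18))
  expect_lt(res$p_two_sided, 0.01)
  expect_equal(res$p_two_sided, fisher_oracle(59, 0, 100, 18))
  expect_equal(res$odds_ratio, Inf)
  expect_error(fisher_exact(two_by_two(0, 0, 3, 2)), "degenerate")
})

test_that("fisher_exact agrees with stats::fisher.test on random tables", {
  withr::with_seed(19, {
    for (i in 1:200) {
      cells <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
      if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
      t <- two_by_two(cells[1], cells[3], cells[2], cells[4])
      expect_equal(fisher_exact(t)$p_two_sided,
                   stats::fisher.test(unclass(t))$p.value,
                   tolerance = 1e-10,
                   info = paste(cells, collapse = ","))
    }
  })
})

test_that("chi_square reproduces the closed 2x2 form", {
  expect_equal(chi_square(two_by_two(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi_square(two_by_two(10, 10, 10, 10))$p, 1)
  expect_equal(chi_square(two_by_two(20, 10, 10, 20))$statistic, 20 / 3)
  expect_equal(chi_square(two_by_two(1, 0, 0, 1))$statistic, 2)
  expect_error(chi_square(two_by_two(1, 1, 0, 0)), "degenerate")
})

test_that("chi_square agrees with stats::chisq.test, with and without Yates", {
  withr::with_seed(23, {
    for (i in 1:100) {
      cells <- as.integer(rmultinom(1, sample(20:200, 1), runif(4, 0.1, 1)))
      t <- two_by_two(cells[1], cells[3], cells[2], cells[4])
      if (any(c(rowSums(unclass(t)), colSums(unclass(t))) == 0)) next
      plain <- suppressWarnings(stats::chisq.test(unclass(t), correct = FALSE))
      yates <- suppressWarnings(stats::chisq.test(unclass(t), correct = TRUE))
      expect_equal(chi_square(t)$statistic, unname(plain$statistic),
                   tolerance = 1e-12)
      expect_equal(chi_square(t)$p, plain$p.value, tolerance = 1e-12)
      expect_equal(chi_square(t, continuity_correction = TRUE)$statistic,
                   unname(yates$statistic), tolerance = 1e-12)
    }
  })
})

test_that("chi_square statistic is zero exactly when ad = bc", {
  withr::with_seed(29, {
    for (i in 1:50) {
      cells <- sample(1:30, 4, replace = TRUE)
      t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
      s <- chi_square(t)$statistic
      if (cells[1] * cells[4] == cells[2] * cells[3]) expect_equal(s, 0)
      else expect_gt(s, 0)
    }
  })
})

test_that("fisher_exact is invariant under simultaneous row and column swaps", {
  withr::with_seed(31, {
    for (i in 1:50) {
      cells <- sample(0:15, 4, replace = TRUE)
      if (cells[1] + cells[2] == 0 || cells[3] + cells[4] == 0) next
      p1 <- fisher_exact(two_by_two(cells[1], cells[2], cells[3],
                                    cells[4]))$p_two_sided
      p2 <- fisher_exact(two_by_two(cells[4], cells[3], cells[2],
                                    cells[1]))$p_two_sided
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  })
})

test_that("mann_whitney matches hand-enumerable cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 1 / 3)
  expect_equal(mann_whitney(1, 2)$p_two_sided, 1)
  same <- mann_whitney(1:8, 1:8)
  expect_equal(same$U, 32)   # n^2 / 2
  expect_equal(same$p_two_sided, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact mann_whitney p equals permutation enumeration up to n = 12", {
  withr::with_seed(37, {
    for (i in 1:60) {
      nx <- sample(1:6, 1); ny <- sample(1:6, 1)
      x <- sample(1:5, nx, replace = TRUE)   # ties likely
      y <- sample(1:5, ny, replace = TRUE)
      got <- mann_whitney(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$U, u_oracle(x, y))
      pooled <- c(x, y)
      mu <- nx * ny / 2
      us <- apply(utils::combn(nx + ny, nx), 2, function(idx)
        u_oracle(pooled[idx], pooled[-idx]))
      expect_equal(got$p_two_sided,
                   mean(abs(us - mu) >= abs(got$U - mu) - 1e-9),
                   info = paste(c(x, "|", y), collapse = " "))
    }
  })
})

test_that("large-sample mann_whitney matches the tie-corrected normal form", {
  withr::with_seed(41, {
    x <- round(rnorm(30, 0, 2), 1)
    y <- round(rnorm(25, 0.5, 2), 1)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
  })
})
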