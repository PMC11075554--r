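events_tbl <- function(time, event, group = "A") {
  tibble::tibble(
    subject_id = sprintf("%s_%02d", group, seq_along(time)),
    group = group, time = time, event = as.integer(event)
  )
}

test_that("KM without censoring equals the empirical survival function", {
  ev <- events_tbl(c(2, 5, 7, 9), c(1, 1, 1, 1))
  km <- km_estimate(ev, "A")
  expect_equal(km$survival, c(3, 2, 1, 0) / 4)
  expect_equal(km$at_risk, c(4L, 3L, 2L, 1L))
})

test_that("all-censored subjects give a flat curve at 1", {
  ev <- events_tbl(c(3, 6, 8), c(0, 0, 0))
  km <- km_estimate(ev, "A")
  expect_true(all(km$survival == 1))
  expect_error(km_estimate(ev, "missing"), "no subjects")
})

test_that("KM with mixed censoring matches the brute-force product limit", {
  withr::with_seed(303, {
    for (rep in 1:30) {
      n <- sample(10:25, 1)
      time <- round(rexp(n, 0.1), 1)
      event <- rbinom(n, 1, 0.7)
      if (sum(event) == 0) event[1] <- 1L
      ev <- events_tbl(time, event)
      km <- km_estimate(ev, "A")
      want <- oracle_km(time, event)
      expect_equal(km$time, want$time)
      expect_equal(km$survival, want$survival, tolerance = 1e-12)
      expect_equal(km$at_risk, want$at_risk)
      expect_true(all(diff(km$survival) <= 1e-12)) # non-increasing
    }
  })
})

test_that("log-rank is null on identical groups and detects separation", {
  a <- events_tbl(c(2, 4, 6, 8), c(1, 1, 1, 0), "A")
  b <- events_tbl(c(2, 4, 6, 8), c(1, 1, 1, 0), "B")
  same <- logrank_test(rbind(a, b), "A", "B")
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  withr::with_seed(71, {
    early <- events_tbl(round(rexp(30, 1), 2), rep(1, 30), "early")
    late <- events_tbl(round(rexp(30, 0.2), 2) + 5, rep(1, 30), "late")
  })
  sep <- logrank_test(rbind(early, late), "early", "late")
  expect_lt(sep$p_value, 0.05)
})

test_that("log-rank matches the expected/observed hand computation", {
  small_a <- events_tbl(c(1, 3, 5, 7), c(1, 1, 0, 1), "A")
  small_b <- events_tbl(c(2, 4, 6, 8), c(1, 0, 1, 1), "B")
  got <- logrank_test(rbind(small_a, small_b), "A", "B")
  want <- oracle_logrank(small_a$time, small_a$event,
                         small_b$time, small_b$event)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-9)

  flipped <- logrank_test(rbind(small_a, small_b), "B", "A")
  expect_equal(flipped$statistic, got$statistic)
})

test_that("fold change rounds half-up and respects orientation", {
  expect_equal(fold_change(1165, 384.9), 3.03)
  expect_equal(fold_change(384.9, 1165), 3.03) # magnitude: order-free
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(2, 1, orientation = "directed"), 2)
  expect_equal(fold_change(1, 2, orientation = "directed"), 0.5)
  expect_error(fold_change(-1, 2), "value_a > 0")
})

test_that("Mann-Whitney exact branch enumerates the null distribution", {
  single <- mann_whitney_u(5, 5)
  expect_equal(single$p_value, 1)
  expect_equal(single$method, "exact")

  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1) # 2 of choose(6,3)=20 assignments as extreme
  # frozen hand enumeration with a tie across groups: pooled {1,2,2,3},
  # n1 = n2 = 2, U = 0.5; the 6 assignments give U in {0.5, 0.5, 2, 2,
  # 3.5, 3.5}, so |U - 2| >= 1.5 in 4 of 6
  tied <- mann_whitney_u(c(1, 2), c(2, 3))
  expect_equal(tied$U, 0.5)
  expect_equal(tied$p_value, 4 / 6)
})

test_that("Mann-Whitney exact branch matches an independent exact test", {
  withr::with_seed(88, {
    for (rep in 1:40) {
      n1 <- sample(2:6, 1)
      n2 <- sample(2:6, 1)
      x <- round(rnorm(n1), 3) # continuous: tie-free
      y <- round(rnorm(n2), 3)
      got <- mann_whitney_u(x, y)
      want <- wilcox.test(x, y, exact = TRUE)
      expect_equal(got$U, unname(want$statistic))
      expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney normal approximation is close to exact at n = 12", {
  # the implementation switches to the normal branch above n = 12; at the
  # crossover the same formula (wilcox.test's corrected approximation) must
  # track the exact enumeration closely
  withr::with_seed(101, {
    for (rep in 1:20) {
      x <- rnorm(6)
      y <- rnorm(6)
      exact_p <- mann_whitney_u(x, y)$p_value
      approx_p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
      expect_lt(abs(exact_p - approx_p), 0.02)
    }
  })
})

test_that("Mann-Whitney normal branch equals the tie-corrected z formula", {
  withr::with_seed(13, {
    x <- sample(1:8, 10, replace = TRUE) # heavy ties
    y <- sample(2:9, 12, replace = TRUE)
  })
  got <- mann_whitney_u(x, y)
  expect_equal(got$method, "normal")
  want <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$U, unname(want$statistic))
  expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the rank formula with ties", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  withr::with_seed(202, {
    for (rep in 1:30) {
      k <- sample(3:5, 1)
      samples <- lapply(seq_len(k), function(i) {
        round(rnorm(sample(4:10, 1), mean = i / 2), 1) # some ties
      })
      got <- kruskal_wallis(samples)
      want <- oracle_kw(samples)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
      expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    }
  })
})

test_that("rank tests are invariant under group relabeling", {
  ev <- rbind(events_tbl(c(1, 2, 5, 9), c(1, 1, 1, 1), "zzz"),
              events_tbl(c(3, 4, 7, 8), c(1, 0, 1, 1), "aaa"))
  p1 <- logrank_test(ev, "zzz", "aaa")$p_value
  ev2 <- ev
  ev2$group <- ifelse(ev$group == "zzz", "g1", "g2")
  p2 <- logrank_test(ev2, "g1", "g2")$p_value
  expect_equal(p1, p2)
})
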