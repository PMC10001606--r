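test_that("grey relational coefficients match hand-computed values", {
  # mean images (0.5,1,1.5) vs (1.5,1,0.5): |delta| = (1,0,1)
  gam <- grey_coefficients(c(1, 2, 3), c(3, 2, 1), epsilon = 0.5)
  expect_equal(unname(gam[, 1]), c(1 / 3, 1, 1 / 3))
  # coefficient is exactly 1 where |delta| attains the global minimum
  expect_equal(which(gam[, 1] == 1), 2L, ignore_attr = TRUE)
  # proportional comparison: identical mean images, all coefficients 1
  expect_equal(unname(grey_coefficients(c(1, 2, 3), c(2, 4, 6))[, 1]),
               c(1, 1, 1))
  # reference vs itself with a single comparison: 0/0 guard yields 1
  expect_equal(unname(grey_coefficients(c(2, 5, 9), c(2, 5, 9))[, 1]),
               c(1, 1, 1))
  expect_error(grey_coefficients(c(1, 2, 3), c(1, 2, 3, 4)), "length")
  expect_error(grey_coefficients(c(1, 2, 3), c(3, 2, 1), epsilon = 0),
               "epsilon")
})

test_that("Deng's degree averages the coefficients and detects proportionality", {
  expect_equal(unname(deng_degree(c(1, 2, 3), c(3, 2, 1))), 5 / 9)
  expect_equal(unname(deng_degree(c(1, 2, 3), c(2, 4, 6))), 1)
  s <- c(4, 7, 2, 9)
  expect_equal(unname(deng_degree(s, s)), 1)
})

test_that("absolute degree follows the zero-start area construction", {
  # shifted copy: identical zero-start images
  expect_equal(unname(absolute_degree(c(1, 2, 3), c(2, 3, 4))), 1)
  # flat comparison: s0 = 2, si = 0 -> 3/5
  expect_equal(unname(absolute_degree(c(1, 2, 3), c(7, 7, 7))), 0.6)
  s <- c(3, 1, 4, 1, 5)
  expect_equal(unname(absolute_degree(s, s)), 1)
})

test_that("relative degree is the absolute construction on initial images", {
  expect_equal(unname(relative_degree(c(2, 4, 6), c(1, 2, 3))), 1)
  s <- c(2, 7, 1, 8)
  expect_equal(unname(relative_degree(s, s)), 1)
  # initial images (1,2,3) vs (1,1,1): zero-start areas 2 and 0 -> 0.6
  expect_equal(unname(relative_degree(c(1, 2, 3), c(1, 1, 1))), 0.6)
  expect_error(relative_degree(c(0, 1, 2), c(1, 2, 3)), "zero first value")
})

test_that("composite degrees enforce their domains and identities", {
  expect_equal(sdgra(0.4, 0.8, theta = 0.25), 0.7)
  expect_equal(sdgra(0.37, 0.37, theta = runif(1)), 0.37)
  expect_equal(ssgra(1, 1), 1)
  expect_error(sdgra(1.2, 0.5), "out of range")
  expect_error(sdgra(0.5, 0), "out of range")
  expect_error(ssgra(-0.1, 0.5), "out of range")
  expect_error(sdgra(0.5, 0.5, theta = 1.5), "theta")
})

test_that("scale invariance holds for Deng's and relative but not absolute", {
  set.seed(23)
  for (i in 1:40) {
    m <- sample(3:8, 1)
    x0 <- rand_small_seq(m)
    xi <- rand_small_seq(m)
    a <- runif(1, 0.2, 20)
    expect_equal(deng_degree(a * x0, xi), deng_degree(x0, xi),
                 tolerance = 1e-12)
    expect_equal(deng_degree(x0, a * xi), deng_degree(x0, xi),
                 tolerance = 1e-12)
    expect_equal(relative_degree(x0, a * xi), relative_degree(x0, xi),
                 tolerance = 1e-12)
  }
  # magnitude sensitivity of the absolute degree
  expect_false(isTRUE(all.equal(
    absolute_degree(c(1, 2, 3), 10 * c(1, 3, 2)),
    absolute_degree(c(1, 2, 3), c(1, 3, 2)))))
})

test_that("Deng's degree is non-decreasing in the resolution coefficient", {
  set.seed(31)
  eps_grid <- c(0.05, 0.2, 0.5, 0.8, 1)
  for (i in 1:25) {
    m <- sample(4:9, 1)
    x0 <- rand_small_seq(m)
    xi <- rand_small_seq(m)
    degs <- vapply(eps_grid, function(e)
      unname(deng_degree(x0, xi, grey_config(epsilon = e))), numeric(1))
    expect_true(all(diff(degs) >= -1e-12))
  }
})

test_that("all degrees agree with the brute-force oracle to 1e-12", {
  set.seed(47)
  for (i in 1:250) {
    m <- sample(3:6, 1)
    x0 <- rand_small_seq(m)
    xs <- lapply(seq_len(sample(1:3, 1)), function(j) rand_small_seq(m))
    names(xs) <- paste0("f", seq_along(xs))
    eps <- runif(1, 0.05, 1)

    expect_equal(unname(deng_degree(x0, xs, grey_config(epsilon = eps))),
                 brute_deng(x0, xs, eps), tolerance = 1e-12)
    for (j in seq_along(xs)) {
      expect_equal(unname(absolute_degree(x0, xs[[j]])),
                   brute_absolute(x0, xs[[j]]), tolerance = 1e-12)
      expect_equal(unname(relative_degree(x0, xs[[j]])),
                   brute_relative(x0, xs[[j]]), tolerance = 1e-12)
    }
  }
})

test_that("ranking sorts descending and shares ranks on rounded ties", {
  rk <- rank_factors(c(income = 0.566, physician = 0.859, smoking = 0.941))
  expect_equal(rk$rank[match(c("income", "physician", "smoking"),
                             rk$factor)], c(3L, 2L, 1L))
  expect_equal(rk$rank_label[rk$factor == "smoking"], "1")

  # two of five coincide at 3 decimals in sorted positions 3 and 4
  d5 <- c(a = 0.9, b = 0.8, c = 0.64312, d = 0.64296, e = 0.5)
  rk5 <- rank_factors(d5)
  expect_equal(rk5$rank_label[rk5$factor %in% c("c", "d")],
               c("3(4)", "3(4)"))
  expect_equal(rk5$rank[rk5$factor %in% c("c", "d")], c(3L, 3L))

  expect_equal(rank_factors(c(only = 0.7))$rank_label, "1")
})

test_that("gra_table produces all five degrees, exact composite identities, and ranks", {
  set.seed(59)
  years <- 2001:2015
  ref <- grey_seq(80 - seq_along(years) + rnorm(15, 0, 0.5), years,
                  name = "mortality")
  cmp <- list(
    rescaled = grey_seq(2.5 * ref$values, years),
    trend = grey_seq(seq(10, 40, length.out = 15), years),
    noise = grey_seq(rnorm(15, 20, 4), years))
  tab <- gra_table(ref, cmp)

  for (model in c("deng", "sdgra", "ssgra", "absolute", "relative")) {
    expect_true(all(tab[[model]] > 0 & tab[[model]] <= 1))
    expect_setequal(unique(tab[[paste0(model, "_rank")]]),
                    sort(unique(tab[[paste0(model, "_rank")]])))
  }
  expect_equal(tab$sdgra, 0.5 * tab$absolute + 0.5 * tab$relative,
               tolerance = 1e-15)
  expect_equal(tab$ssgra, (tab$deng + tab$absolute) / 2, tolerance = 1e-15)
  # a positive rescaling of the reference wins under the scale-free models
  expect_equal(tab$deng_rank[tab$factor == "rescaled"], 1L)
  expect_equal(tab$relative_rank[tab$factor == "rescaled"], 1L)
  expect_equal(tab$deng[tab$factor == "rescaled"], 1)

  single <- gra_table(ref, list(self = ref))
  expect_equal(unlist(single[, c("deng", "sdgra", "ssgra", "absolute",
                                 "relative")]),
               rep(1, 5), ignore_attr = TRUE)
  expect_true(all(single$deng_rank == 1L))
})

test_that("gra_table honours the lag by aligning factors to t - lag", {
  set.seed(71)
  years <- 2001:2020
  x_vals <- 10 + cumsum(runif(20, 0.5, 2))
  # outcome at t is exactly proportional to the factor at t - 1
  ref <- grey_seq(c(50, 3 * x_vals[1:19]), years, name = "y")
  cmp <- list(x = grey_seq(x_vals, years))
  lag0 <- gra_table(ref, cmp, lag = 0)
  lag1 <- gra_table(ref, cmp, lag = 1)
  expect_equal(attr(lag1, "years"), 2002:2020)
  expect_equal(lag1$deng, 1)
  expect_lt(lag0$deng, 1)
})
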