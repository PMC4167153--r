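test_that("lambda solves the measure polynomial in closed form for n = 2", {
  expect_identical(solve_lambda(c(0.5, 0.5)), 0)         # additive measure
  expect_equal(solve_lambda(c(0.3, 0.3)), (1 - 0.6) / 0.09, tolerance = 1e-10)
  expect_equal(solve_lambda(c(0.6, 0.6)), (1 - 1.2) / 0.36, tolerance = 1e-10)
  lam <- solve_lambda(c(0.6, 0.6))
  expect_gt(lam, -1); expect_lt(lam, 0)
  # g(Y) = 1 under the closed form for both signs
  for (g in list(c(0.3, 0.3), c(0.6, 0.6))) {
    l <- solve_lambda(g)
    expect_equal((prod(1 + l * g) - 1) / l, 1, tolerance = 1e-9)
  }
})

test_that("lambda root sign tracks the density sum and residuals vanish", {
  set.seed(51)
  for (i in 1:50) {
    g <- random_densities(sample(2:27, 1))
    lam <- solve_lambda(g)
    expect_gt(lam, -1)
    if (abs(sum(g) - 1) >= 1e-9) {
      if (sum(g) < 1) expect_gt(lam, 0) else expect_lt(lam, 0)
    }
    expect_lt(abs(prod(1 + lam * g) - (1 + lam)), 1e-12)
  }
})

test_that("invalid densities are rejected", {
  expect_error(solve_lambda(c(0.5, 0)), "strictly in")
  expect_error(solve_lambda(c(0.5, 1)), "strictly in")
  expect_error(fuzzy_densities(c(0.2, -0.1)), "strictly in")
})

test_that("the measure chain follows the recursion and ends at one", {
  expect_equal(measure_chain(1.0, 0), 1.0)   # single-expert base case
  set.seed(52)
  for (i in 1:40) {
    g <- random_densities(sample(2:8, 1))
    lam <- solve_lambda(g)
    ord <- sample(seq_along(g))      # any fusion order
    chain <- measure_chain(g[ord], lam)
    expect_equal(chain[length(chain)], 1, tolerance = 1e-9)
    expect_true(all(diff(chain) >= -1e-12))  # monotone coalition measure
    # closed-form product oracle
    closed <- vapply(seq_along(g), function(i) {
      if (lam == 0) sum(g[ord][1:i]) else (prod(1 + lam * g[ord][1:i]) - 1) / lam
    }, numeric(1))
    expect_lt(max(abs(chain - closed)), 1e-10)
  }
})

test_that("an inconsistent lambda triggers the internal consistency error", {
  expect_error(measure_chain(c(0.2, 0.2), 0), "inconsistent")
})

test_that("the fuzzy integral reduces to the certainty level when all agree", {
  g <- c(0.5, 0.3, 0.2)   # sums to one: additive
  for (c_ in c(0, 0.25, 0.8, 1)) {
    expect_equal(sugeno_integral(rep(c_, 3), g), c_)
  }
})

test_that("the worked three-expert example evaluates to 0.6", {
  g <- c(0.5, 0.3, 0.2)
  h <- c(0.9, 0.6, 0.2)
  # terms: min(.9,.5), min(.6,.8), min(.2,1) -> max = .6
  expect_equal(sugeno_integral(h, g), 0.6)
  expect_equal(brute_force_integral(h, g), 0.6)
})

test_that("sorted evaluation equals subset enumeration and the t-level form", {
  set.seed(53)
  for (i in 1:300) {
    n <- sample(2:8, 1)
    g <- random_densities(n)
    h <- runif(n)
    lam <- solve_lambda(g)
    e_sort <- sugeno_integral(h, g, lam)
    e_brute <- brute_force_integral(h, g, lam)
    expect_lt(abs(e_sort - e_brute), 1e-12)
    # second printed form: max over t of min(t, g({h >= t}))
    e_tlevel <- max(vapply(h, function(t) {
      min(t, leukofuse:::measure_subset(g, lam, which(h >= t)))
    }, numeric(1)))
    expect_lt(abs(e_sort - e_tlevel), 1e-12)
    expect_gte(e_sort, min(h) - 1e-12)
    expect_lte(e_sort, max(h) + 1e-12)
  }
})

test_that("raising any single certainty never lowers the integral", {
  set.seed(54)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    g <- random_densities(n)
    h <- runif(n)
    e0 <- sugeno_integral(h, g)
    j <- sample(n, 1)
    h2 <- h; h2[j] <- min(1, h[j] + runif(1, 0, 1 - h[j]))
    expect_gte(sugeno_integral(h2, g), e0 - 1e-12)
  }
})

test_that("fusion decides by per-class integrals with ties to leukocoric", {
  g <- rep(1 / 27, 27)
  unanimous <- fuse_predict(rep(1, 27), g)
  expect_equal(unanimous$class, 1L)
  expect_equal(unanimous$e_pos, 1)
  expect_equal(unanimous$e_neg, 0)
  split <- fuse_predict(rep(0.5, 27), g)
  expect_equal(split$e_pos, split$e_neg)
  expect_equal(split$class, 1L)   # documented tie rule
})

test_that("fusion matches brute-force per-class integrals on random cases", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(2:7, 1)
    g <- random_densities(n)
    h <- runif(n)
    lam <- solve_lambda(g)
    fp <- fuse_predict(h, g, lam)
    ep <- brute_force_integral(h, g, lam)
    en <- brute_force_integral(1 - h, g, lam)
    expect_equal(fp$e_pos, ep, tolerance = 1e-12)
    expect_equal(fp$e_neg, en, tolerance = 1e-12)
    expect_equal(fp$class, if (ep >= en) 1L else -1L)
  }
})

test_that("baseline combiners follow their documented arithmetic", {
  expect_equal(combine_majority(c(1, 1, -1)), 1L)
  expect_equal(combine_majority(c(1, -1)), 1L)          # tie to +1
  expect_equal(combine_weighted(c(1, -1), c(0.9, 0.1)), 1L)
  expect_equal(combine_weighted(c(1, -1), c(0.1, 0.9)), -1L)
  expect_equal(combine_average(c(1, -1)), 1L)           # zero mean to +1
  expect_equal(combine_average(c(-1, -1, 1)), -1L)
  # unanimity: all three agree with the unanimous class
  y <- rep(-1, 5)
  expect_equal(combine_average(y), -1L)
  expect_equal(combine_weighted(y, rep(0.2, 5)), -1L)
  expect_equal(combine_majority(y), -1L)
  expect_error(combine_average(numeric(0)), "empty")
  expect_error(combine_majority(c(1, 0)), "-1/\\+1")
})
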