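test_that("Boltzmann weighting reproduces the four-channel split", {
  pops <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
  expect_equal(round(pops$fractions, 2), c(0.46, 0.23, 0.15, 0.15))
  expect_equal(sum(pops$fractions), 1, tolerance = 1e-12)
  # integer-percent presentation
  expect_identical(as.integer(round(100 * pops$fractions)), c(46L, 23L, 15L, 15L))
})

test_that("degenerate population inputs behave as normalization demands", {
  expect_equal(boltzmann_populations(3.7)$fractions, 1)
  expect_equal(boltzmann_populations(c(5, 5))$fractions, c(0.5, 0.5))
  expect_error(boltzmann_populations(numeric(0)), "at least one")
  expect_error(boltzmann_populations(c(1, Inf)), "finite")
  expect_error(boltzmann_populations(c(1, 2), labels = "a"), "length")
})

test_that("fractions are invariant under a uniform stability shift", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- stats::runif(6, 2, 12)
    p0 <- boltzmann_populations(s)$fractions
    p1 <- boltzmann_populations(s + 500)$fractions
    expect_equal(p0, p1, tolerance = 1e-12)
    expect_equal(sum(p0), 1, tolerance = 1e-9)
    # larger stability always carries larger population
    expect_identical(order(p0), order(s))
  }
})

test_that("one-at-a-time perturbation reproduces the printed intervals", {
  s <- c(8.9, 8.2, 7.8, 7.8)
  u <- c(0.3, 0.4, 0.4, 0.4)
  iv <- perturbation_intervals(s, u)
  expect_true(all(iv$shift_up_pp >= 0))
  expect_true(all(iv$shift_down_pp <= 0))
  # second channel: [-6, +8] percentage points after integer rounding
  expect_identical(as.integer(round(iv$shift_up_pp[2])), 8L)
  expect_identical(as.integer(round(iv$shift_down_pp[2])), -6L)
  # equal-stability channels: +6 on the upward perturbation
  expect_identical(as.integer(round(iv$shift_up_pp[3])), 6L)
  # zero uncertainty moves nothing
  iv0 <- perturbation_intervals(s, rep(0, 4))
  expect_equal(iv0$shift_up_pp, rep(0, 4))
  expect_equal(iv0$shift_down_pp, rep(0, 4))
  expect_error(perturbation_intervals(s, u[1:2]), "equal length")
})

test_that("perturbation of a two-state system matches the closed form", {
  # p(s) = 1 / (1 + exp(d - s)): exact logistic recomputation
  s <- c(5, 5)
  u <- 0.4
  iv <- perturbation_intervals(s, c(u, u))
  closed <- 100 * (1 / (1 + exp(-u)) - 0.5)
  expect_equal(iv$shift_up_pp[1], closed, tolerance = 1e-12)
  expect_equal(iv$shift_up_pp[2], closed, tolerance = 1e-12)
  # linear regime: shift/u -> 100 * p(1-p) per kT as u -> 0
  s4 <- c(8.9, 8.2, 7.8, 7.8)
  p <- boltzmann_populations(s4)$fractions
  u_small <- 1e-6
  iv_small <- perturbation_intervals(s4, rep(u_small, 4))
  expect_equal(iv_small$shift_up_pp / (100 * u_small), p * (1 - p),
               tolerance = 1e-4)
})

test_that("equal-stability channels merge into one apparent channel", {
  pops <- boltzmann_populations(c(8.9, 8.2, 7.8, 7.8))
  ch <- merge_channels(pops, tolerance_kT = 0)
  expect_length(ch, 3L)
  merged <- ch[[3]]
  expect_identical(merged$member_labels, c("C3", "C4"))
  expect_identical(as.integer(round(100 * merged$combined_fraction)), 31L)
  # large tolerance collapses everything into a single channel
  all_in <- merge_channels(pops, tolerance_kT = 10)
  expect_length(all_in, 1L)
  expect_equal(all_in[[1]]$combined_fraction, 1, tolerance = 1e-12)
  # distinct stabilities at zero tolerance stay separate
  ch0 <- merge_channels(boltzmann_populations(c(9, 8, 7)), 0)
  expect_length(ch0, 3L)
  expect_error(merge_channels(pops, -1), ">= 0")
})
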