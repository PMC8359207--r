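# Core qSIP mathematics against hand-computed closed forms.

test_that("weighted average density matches hand-computed means and bounds", {
  expect_equal(weighted_average_density(100, 1.700), 1.700)
  # (1.70*10 + 1.74*30) / 40 = 1.73
  expect_equal(weighted_average_density(c(10, 30), c(1.70, 1.74)), 1.73)
  # scale invariance and range boundedness over random cases
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:13, 1)
    copies <- stats::rgamma(n, 2)
    dens <- sort(stats::runif(n, 1.66, 1.78))
    w <- weighted_average_density(copies, dens)
    expect_gte(w, min(dens))
    expect_lte(w, max(dens))
    expect_equal(weighted_average_density(copies * 7, dens), w)
  }
  expect_error(weighted_average_density(c(0, 0), c(1.7, 1.71)),
               "all copy numbers are zero")
  expect_error(weighted_average_density(c(-1, 2), c(1.7, 1.71)),
               "non-negative")
})

test_that("density-GC relation inverts at hand-computed anchor points", {
  # G = (W - 1.646057) / 0.083506 at W = intercept, intercept + slope,
  # intercept + slope/2
  expect_equal(gc_from_light_density(1.646057), 0)
  expect_equal(gc_from_light_density(1.729563), 1)
  expect_equal(gc_from_light_density(1.687810), 0.5)
  expect_warning(g <- gc_from_light_density(1.60), "clamped")
  expect_identical(g, 0)
})

test_that("density_from_gc and gc_from_light_density are mutual inverses", {
  g <- seq(0, 1, by = 0.01)
  expect_equal(suppressWarnings(gc_from_light_density(density_from_gc(g))),
               g, tolerance = 1e-12)
  expect_equal(density_from_gc(0), 1.646057)
  expect_equal(density_from_gc(0.5), 1.687810)
  expect_error(density_from_gc(1.2), "proportion")
})

test_that("light molecular weight is 0.496 G + 307.691", {
  expect_equal(light_molecular_weight(0), 307.691)
  expect_equal(light_molecular_weight(1), 308.187)
  expect_equal(light_molecular_weight(0.5), 307.939)
  expect_error(light_molecular_weight(-0.1), "proportion")
})

test_that("labelled molecular weight scales with the relative density shift", {
  # no shift: M_lab = M_light
  expect_equal(labelled_molecular_weight(1.70, 1.70, 307.939), 307.939)
  # dW/W = 0.017/1.700 = 0.01 exactly: M_lab = 1.01 * 307.939
  expect_equal(labelled_molecular_weight(1.700, 1.717, 307.939),
               1.01 * 307.939)
  # linearity: doubling dW doubles the gain
  gain1 <- labelled_molecular_weight(1.70, 1.71, 300) - 300
  gain2 <- labelled_molecular_weight(1.70, 1.72, 300) - 300
  expect_equal(gain2, 2 * gain1)
  expect_error(labelled_molecular_weight(0, 1.7, 300), "positive")
})

test_that("dual maximum heavy MW follows the printed combined equation", {
  expect_equal(max_heavy_mw_dual(0, 307.691), 321.107)
  # increment at G = 0.5 is 0.0025 * 0.5 + 13.416
  expect_equal(max_heavy_mw_dual(0.5, 307.939) - 307.939, 13.41725)
  # increment is independent of m_light
  for (m in c(100, 307.7, 500))
    expect_equal(max_heavy_mw_dual(0.3, m) - m, 0.0025 * 0.3 + 13.416)
  expect_error(max_heavy_mw_dual(2, 307), "proportion")
})

test_that("per-element maximum sums carbon and per-base nitrogen terms", {
  # carbon: full 13C substitution
  expect_equal(carbon_max_increment(0), 9.974564)
  expect_equal(carbon_max_increment(1), 9.4758358)
  # linear in G
  g <- seq(0, 1, by = 0.25)
  expect_equal(diff(carbon_max_increment(g)), rep(-0.4987282 / 4, 4))
  # nitrogen: means of complementary-pair per-base maxima
  expect_equal(nitrogen_max_increment(0), (4.985 + 1.994) / 2)   # A+T
  expect_equal(nitrogen_max_increment(1), (4.985 + 2.991) / 2)   # G+C
  # per-element dual mode = carbon + nitrogen, differing from the printed
  # combined coefficients (13.464 - 0.0002 G vs 13.416 + 0.0025 G)
  inc_pe <- max_heavy_mw_dual(0.5, 307.939, mode = "per_element") - 307.939
  expect_equal(inc_pe,
               carbon_max_increment(0.5) + nitrogen_max_increment(0.5))
  expect_false(isTRUE(all.equal(inc_pe,
                                max_heavy_mw_dual(0.5, 307.939) - 307.939)))
})

test_that("MWE interpolates linearly between light and heavy-max weights", {
  expect_equal(molecular_weight_excess(307.939, 307.939, 321.356), 0)
  expect_equal(molecular_weight_excess(321.356, 307.939, 321.356), 1)
  mid <- (307.939 + 321.356) / 2
  expect_equal(molecular_weight_excess(mid, 307.939, 321.356), 0.5)
  # negative shifts are reported, not clamped
  expect_lt(molecular_weight_excess(307.0, 307.939, 321.356), 0)
  expect_error(molecular_weight_excess(310, 308, 308), "invalid state")
})

test_that("MWE is strictly increasing in w_lab for fixed w_light", {
  w_light <- 1.687810
  g <- gc_from_light_density(w_light)
  ml <- light_molecular_weight(g)
  mh <- max_heavy_mw_dual(g, ml)
  w_lab <- seq(w_light - 0.005, w_light + 0.06, length.out = 40)
  mwe <- molecular_weight_excess(
    labelled_molecular_weight(w_light, w_lab, ml), ml, mh)
  expect_true(all(diff(mwe) > 0))
})

test_that("activity calls use an inclusive cutoff", {
  expect_identical(call_active(c(0.15, 0.139, 0.14, -0.2, NA)),
                   c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_true(call_active(0.05, threshold = 0.05))
  expect_error(call_active(0.2, threshold = "x"), "single number")
})
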