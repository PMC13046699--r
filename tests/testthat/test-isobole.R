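test_that("parallel additive arithmetic matches hand computation", {
  # published A375 values: cisplatin 1.29 +/- 0.34 uM,
  # mitoxantrone 0.04 +/- 0.02 uM, 1:1 ratio
  cis <- ic50_estimate(1.29, 0.34, "uM", n_effective = 9, agent = "cisplatin")
  mtx <- ic50_estimate(0.04, 0.02, "uM", n_effective = 9,
                       agent = "mitoxantrone")
  pred <- additive_parallel(cis, mtx, f = 0.5)
  expect_equal(pred$points$A$total, 0.665, tolerance = 1e-12)
  expect_equal(pred$points$A$sem, 0.17029, tolerance = 1e-4)
  expect_equal(pred$points$A$a + pred$points$A$b, pred$points$A$total)

  # nM -> uM conversion: FM55M2 vemurafenib 0.62 uM + docetaxel 2.06 nM
  vem <- ic50_estimate(0.62, 0.27, "uM", agent = "vemurafenib")
  doc <- ic50_estimate(2.06, 0.66, "nM", agent = "docetaxel")
  pred2 <- additive_parallel(vem, doc, f = 0.5, unit = "uM")
  expect_equal(pred2$points$A$total, 0.31103, tolerance = 1e-9)

  # identical components: total = IC50, SEM = SEM / sqrt(2)
  same <- ic50_estimate(1.2, 0.3, "uM")
  pred3 <- additive_parallel(same, same)
  expect_equal(pred3$points$A$total, 1.2)
  expect_equal(pred3$points$A$sem, sqrt(0.5^2 + 0.5^2) * 0.3,
               tolerance = 1e-12)
})

test_that("parallel additive total is monotone in each component", {
  base_a <- ic50_estimate(1, 0.1, "uM")
  base_b <- ic50_estimate(2, 0.1, "uM")
  t0 <- additive_parallel(base_a, base_b)$points$A$total
  for (bump in c(1.1, 1.5, 3)) {
    expect_gt(additive_parallel(ic50_estimate(bump, 0.1, "uM"),
                                base_b)$points$A$total, t0)
    expect_gt(additive_parallel(base_a,
                                ic50_estimate(2 * bump, 0.1, "uM")
                                )$points$A$total, t0)
  }
})

test_that("ray solver solves s + s^r = 1 with closed-form checks", {
  expect_equal(solve_ray_fraction(1), 0.5, tolerance = 1e-10)
  expect_equal(solve_ray_fraction(2), (sqrt(5) - 1) / 2, tolerance = 1e-9)
  expect_equal(solve_ray_fraction(0.5), 1 - (sqrt(5) - 1) / 2,
               tolerance = 1e-9)
  expect_error(solve_ray_fraction(0), "> 0")
  expect_error(solve_ray_fraction(-2), "> 0")
  expect_error(solve_ray_fraction(Inf), "> 0")
  # residual of the defining equation is at tolerance
  for (r in c(0.2, 1.7, 6)) {
    s <- solve_ray_fraction(r)
    expect_lt(abs(s + s^r - 1), 1e-10)
  }
})

test_that("lower and upper ray fractions are complementary", {
  for (r in seq(0.1, 10, by = 0.3)) {
    expect_equal(solve_ray_fraction(r) + solve_ray_fraction(1 / r), 1,
                 tolerance = 1e-9)
  }
})

mk_fit <- function(b, mu = 0, se_b = 0.1, se_mu = 0.05, agent = "x",
                   unit = "uM") {
  structure(list(agent = agent, cell_line = NA_character_, unit = unit,
                 b = b, se_b = se_b, mu = mu, se_mu = se_mu,
                 n_points = 7, n_window = 3, n_window_wells = 9,
                 flags = character(0)),
            class = "probit_fit")
}

test_that("nonparallel bounds bracket the parallel point and collapse at r = 1", {
  fa <- mk_fit(2, agent = "A")
  fb <- mk_fit(1, agent = "B")
  # equal unit IC50s, slope ratio 2: totals from the golden-ratio s
  pred <- additive_nonparallel(fa, fb, f = 0.5,
                               est_a = ic50_estimate(1, 0.1, "uM"),
                               est_b = ic50_estimate(1, 0.1, "uM"))
  expect_equal(pred$points$A_prime$total, 0.763932, tolerance = 1e-6)
  expect_equal(pred$points$A_dprime$total, 1.236068, tolerance = 1e-6)
  expect_lt(pred$points$A_prime$total, pred$points$A_dprime$total)
  # with equal component IC50s the bounds average to the parallel value
  expect_equal(pred$points$A_prime$total + pred$points$A_dprime$total,
               2 * 1, tolerance = 1e-9)

  # r = 1 collapses to the parallel prediction
  pred_eq <- additive_nonparallel(mk_fit(1.5), mk_fit(1.5), f = 0.5,
                                  est_a = ic50_estimate(1, 0.1, "uM"),
                                  est_b = ic50_estimate(3, 0.2, "uM"))
  par <- additive_parallel(ic50_estimate(1, 0.1, "uM"),
                           ic50_estimate(3, 0.2, "uM"))
  expect_equal(pred_eq$points$A_prime$total, par$points$A$total,
               tolerance = 1e-9)
  expect_equal(pred_eq$points$A_dprime$total, par$points$A$total,
               tolerance = 1e-9)

  # bounds bracket the parallel formula across slope ratios
  for (r in c(0.2, 0.5, 2, 5, 9)) {
    p <- additive_nonparallel(mk_fit(r), mk_fit(1), f = 0.5,
                              est_a = ic50_estimate(1, 0, "uM"),
                              est_b = ic50_estimate(2, 0, "uM"))
    expect_lte(p$points$A_prime$total, 1.5 + 1e-12)
    expect_gte(p$points$A_dprime$total, 1.5 - 1e-12)
  }
  expect_warning(
    additive_nonparallel(mk_fit(100), mk_fit(1), f = 0.5,
                         est_a = ic50_estimate(1, 0, "uM"),
                         est_b = ic50_estimate(1, 0, "uM")),
    "extreme slope ratio")
})

test_that("unit conversion leaves the additive prediction invariant", {
  a_um <- ic50_estimate(0.8, 0.1, "uM")
  b_um <- ic50_estimate(0.002, 0.0005, "uM")
  b_nm <- ic50_estimate(2, 0.5, "nM")
  p1 <- additive_parallel(a_um, b_um, unit = "uM")
  p2 <- additive_parallel(a_um, b_nm, unit = "uM")
  expect_equal(p1$points$A$total, p2$points$A$total, tolerance = 1e-12)
  expect_equal(p1$points$A$sem, p2$points$A$sem, tolerance = 1e-12)
  # whole analysis in nM scales by 1000
  p3 <- additive_parallel(convert_estimate(a_um, "nM"), b_nm, unit = "nM")
  expect_equal(p3$points$A$total, 1000 * p1$points$A$total, tolerance = 1e-9)
})

test_that("SEM propagation: analytic, degenerate and Monte-Carlo paths", {
  ea <- ic50_estimate(1.29, 0.34, "uM")
  eb <- ic50_estimate(0.04, 0.02, "uM")
  pred <- additive_parallel(ea, eb)
  pred <- propagate_sem(pred, ea, eb)
  expect_equal(pred$points$A$sem, 0.17029, tolerance = 1e-4)

  expect_error(propagate_sem(pred, ea, eb, n_mc = 50), ">= 100")

  # zero SEMs give zero MC SEM for any seed
  fa <- mk_fit(2, se_b = 0)
  fb <- mk_fit(1, se_b = 0)
  e0a <- ic50_estimate(1, 0, "uM")
  e0b <- ic50_estimate(1, 0, "uM")
  pred0 <- additive_nonparallel(fa, fb, est_a = e0a, est_b = e0b)
  for (seed in c(1, 99)) {
    p <- propagate_sem(pred0, e0a, e0b, n_mc = 500, seed = seed)
    expect_equal(p$points$A_prime$sem, 0)
    expect_equal(p$points$A_dprime$sem, 0)
  }

  # nonparallel toy vs finite-difference delta oracle (slopes exact)
  e1 <- ic50_estimate(1, 0.1, "uM")
  pred1 <- additive_nonparallel(fa, fb, est_a = e1, est_b = e1)
  mc <- propagate_sem(pred1, e1, e1, n_mc = 1e5, seed = 42)
  # A' total = s_low * (ic_a + ic_b): gradient components are s_low each
  s_low <- solve_ray_fraction(2)
  h <- 1e-6
  tot <- function(ia, ib) {
    min(s_low, 1 - s_low) * (ia + ib)
  }
  g_a <- (tot(1 + h, 1) - tot(1 - h, 1)) / (2 * h)
  g_b <- (tot(1, 1 + h) - tot(1, 1 - h)) / (2 * h)
  delta_sem <- sqrt(g_a^2 * 0.1^2 + g_b^2 * 0.1^2)
  expect_lt(abs(mc$points$A_prime$sem - delta_sem) / delta_sem, 0.05)

  # MC is reproducible under seed
  mc2 <- propagate_sem(pred1, e1, e1, n_mc = 1e4, seed = 7)
  mc3 <- propagate_sem(pred1, e1, e1, n_mc = 1e4, seed = 7)
  expect_identical(mc2$points$A_prime$sem, mc3$points$A_prime$sem)
})
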