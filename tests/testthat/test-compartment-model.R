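test_that("eigenrates match closed-form special cases and a quadratic-solver oracle", {
  a <- computeAlphas(kineticParams(1, 0.1, 0.05, 0))
  expect_equal(a@alpha1, 0)                 # k4 = 0 forces alpha1 = 0
  expect_equal(a@alpha2, 0.15)

  a0 <- computeAlphas(kineticParams(1, 0, 0, 0))
  expect_equal(c(a0@alpha1, a0@alpha2), c(0, 0))

  # subcutaneous-tumor group means: check the sum/product identities and the
  # individual roots against base R's polynomial solver
  a <- computeAlphas(kineticParams(0.00229, 0.042, 0.0104, 0.00177))
  expect_equal(a@alpha1 + a@alpha2, 0.05417, tolerance = 1e-12)
  expect_equal(a@alpha1 * a@alpha2, 7.434e-5, tolerance = 1e-12)
  roots <- sort(Re(polyroot(c(0.042 * 0.00177, -0.05417, 1))))
  expect_equal(c(a@alpha1, a@alpha2), roots, tolerance = 1e-10)
})

test_that("eigenrate identities hold to machine tolerance over random draws", {
  set.seed(11)
  for (i in 1:10000) {
    k <- runif(3, 0, 2)
    a <- dynFDG:::.alphas(k[1], k[2], k[3])
    s <- sum(k)
    expect_true(abs(a[1] + a[2] - s) < 1e-12 * max(1, s))
    expect_true(abs(a[1] * a[2] - k[1] * k[3]) < 1e-12 * max(1, s))
    expect_true(a[1] >= 0 && a[2] >= a[1])
  }
})

test_that("influx constant follows K1*k3/(k2+k3) with the zero-exchange convention", {
  expect_equal(influxConstant(kineticParams(0.5, 0.1, 0, 0)), 0)
  expect_equal(influxConstant(kineticParams(0.5, 0, 0.1, 0)), 0.5)
  expect_equal(influxConstant(kineticParams(0.00229, 0.042, 0.0104, 0.00177)),
               0.00229 * 0.0104 / 0.0524, tolerance = 1e-12)
  expect_equal(influxConstant(kineticParams(0.5, 0, 0, 0)), 0)
})

test_that("influx constant is non-decreasing in k3 and K1", {
  base <- c(K1 = 0.01, k2 = 0.1, k3 = 0.02, k4 = 0.001)
  k3s <- seq(0, 1, length.out = 25)
  ki3 <- vapply(k3s, function(k3)
    influxConstant(kineticParams(base[1], base[2], k3, base[4])), 0)
  expect_true(all(diff(ki3) >= 0))
  k1s <- seq(0, 1, length.out = 25)
  ki1 <- vapply(k1s, function(k1)
    influxConstant(kineticParams(k1, base[2], base[3], base[4])), 0)
  expect_true(all(diff(ki1) >= 0))
})

test_that("tissue ODE reproduces degenerate closed forms", {
  cp1 <- function(t) rep(1, length(t))
  # pure accumulation: k2 = k3 = k4 = 0 gives CT = K1*t + VB
  s <- solveTissueODE(kineticParams(0.01, 0, 0, 0, VB = 0.2), cp1,
                      tGrid = c(0, 10, 20, 50))
  expect_equal(s$CT, 0.01 * c(0, 10, 20, 50) + 0.2, tolerance = 1e-10)
  # zero input
  s0 <- solveTissueODE(kineticParams(0.01, 0.1, 0.05, 0.01, 0.3),
                       function(t) rep(0, length(t)), c(0, 10, 100))
  expect_equal(unlist(s0[, c("Ce", "Cm", "CT")]), rep(0, 9),
               ignore_attr = TRUE)
  # single-compartment: k3 = k4 = 0, VB = 0
  tg <- c(0, 50, 200, 600)
  s1 <- solveTissueODE(kineticParams(0.005, 0.05, 0, 0, 0), cp1, tg)
  expect_equal(s1$CT, 0.005 / 0.05 * (1 - exp(-0.05 * tg)), tolerance = 1e-8)
  expect_error(solveTissueODE(kineticParams(0.01, 0, 0, 0), cp1, c(0, 5, 5)),
               "increasing")
})

test_that("analytic solution agrees with the RK4 oracle on bolus inputs", {
  bol <- defaultBolus()
  tg <- seq(0, 3600, by = 10)
  set.seed(21)
  for (i in 1:10) {
    p <- randomParams()
    ode <- solveTissueODE(p, bol, tg)$CT
    an <- analyticTissueCurve(p, bol, tg)
    expect_lt(max(abs(an - ode)) / max(abs(ode)), 1e-4)
  }
})

test_that("analytic solution handles zero input and the accumulation limit", {
  p <- kineticParams(0.02, 0.3, 0.1, 0.05, 0.1)
  expect_equal(analyticTissueCurve(p, function(t) rep(0, length(t)),
                                   c(0, 10, 100)), rep(0, 3))
  # kernel degenerates to the constant K1 (all-zero rates, confluent at 0)
  ct <- analyticTissueCurve(kineticParams(0.01, 0, 0, 0, 0),
                            function(t) rep(1, length(t)), c(0, 10, 20))
  expect_equal(ct, c(0, 0.1, 0.2), tolerance = 1e-10)
})

test_that("confluent eigenrate case matches the ODE oracle", {
  # k3 = 0 with k2 = k4 makes the discriminant vanish exactly
  p <- kineticParams(0.01, 0.2, 0, 0.2, 0.05)
  a <- computeAlphas(p)
  expect_equal(a@alpha1, a@alpha2)
  bol <- defaultBolus()
  tg <- seq(0, 1800, by = 10)
  ode <- solveTissueODE(p, bol, tg)$CT
  an <- analyticTissueCurve(p, bol, tg)
  expect_lt(max(abs(an - ode)) / max(abs(ode)), 1e-4)
})

test_that("tissue response is linear in the input", {
  bol <- defaultBolus()
  p <- kineticParams(0.01, 0.1, 0.03, 0.002, 0.08)
  tg <- seq(0, 1200, by = 20)
  expect_equal(analyticTissueCurve(p, function(t) 2 * bol(t), tg),
               2 * analyticTissueCurve(p, bol, tg), tolerance = 1e-12)
})

test_that("with k4 = 0 the metabolized pool never decreases", {
  # finite-support input: bolus that is zero after 60 s
  cpf <- function(t) ifelse(t > 5 & t < 60, 1, 0)
  s <- solveTissueODE(kineticParams(0.01, 0.1, 0.05, 0, 0), cpf,
                      tGrid = seq(0, 600, by = 10))
  expect_true(all(diff(s$Cm) > -1e-12))
})

test_that("frame averaging integrates curves exactly", {
  sched <- frameSchedule(durations = c(10, 10))
  expect_equal(activity(frameAverage(function(t) rep(7, length(t)), sched)),
               c(7, 7))
  expect_equal(activity(frameAverage(function(t) t, sched)), c(5, 15))
  e <- frameAverage(function(t) exp(-t), frameSchedule(durations = c(1)))
  expect_equal(activity(e), 1 - exp(-1), tolerance = 1e-7)
})

test_that("frame schedules validate contiguity and the full protocol length", {
  expect_error(frameSchedule(starts = c(0, 5), durations = c(2, 2)),
               "contiguous")
  expect_error(frameSchedule(durations = c(1, -1)), "positive")
  sched <- mouseDynamicSchedule()
  expect_equal(nFrames(sched), 29L)
  expect_equal(totalDuration(sched), 3093)
  expect_equal(frameMids(sched)[1], 0.75)
})
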