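test_that("Lee-Radok prefactor is 8 sqrt(R) / (3 (1 - nu))", {
  expect_equal(lr_prefactor(GEOM), 8 * sqrt(12.5e-6) / 1.5)  # 1.88562e-2
  expect_equal(lr_prefactor(contact_geometry(9 / 64, 0)), 1)
  # halving (1 - nu) doubles the prefactor
  expect_equal(lr_prefactor(contact_geometry(1e-6, 0.5)),
               2 * lr_prefactor(contact_geometry(1e-6, 0)))
  expect_error(contact_geometry(-1), "positive")
  expect_error(contact_geometry(1e-6, 0.6), "Poisson")
})

test_that("zero-arm hereditary force reduces to the Hertz closed form", {
  t <- seq(0, 0.05, by = 1e-4)
  h <- 2e-6 * t
  F <- predict_force(gm_model(1000), t, h, GEOM)
  expect_lt(max(abs(F - lr_prefactor(GEOM) * 1000 * h^1.5)) / max(F), 1e-14)
  # spot value: 100 nm indentation at Ge = 1000 Pa
  i <- which.min(abs(h - 1e-7))
  expect_equal(F[i], lr_prefactor(GEOM) * 1000 * (1e-7)^1.5,
               tolerance = 1e-10)  # ~5.963e-10 N
})

test_that("step indentation yields the relaxation curve", {
  m <- sls_100_300()
  t <- seq(0, 0.01, by = 2e-6)
  h <- c(0, rep(1e-7, length(t) - 1))  # step to 100 nm at the first sample
  F <- predict_force(m, t, h, GEOM)
  expected <- lr_prefactor(GEOM) * relaxation_modulus(m, t) * (1e-7)^1.5
  expect_lt(max(abs(F[-1] - expected[-1]) / expected[-1]), 1e-3)
})

test_that("ramp force matches an adaptive-quadrature oracle", {
  m <- gm_model(200, G = 800, tau = 5e-3)
  v <- 2e-6
  t <- seq(0, 0.05, by = 1e-5)
  F <- predict_force(m, t, v * t, GEOM)
  Gt <- function(s) 200 + 800 * exp(-s / 5e-3)
  for (i in c(501, 2501, 5001)) {
    oracle <- integrate(function(z) Gt(t[i] - z) * 1.5 * v * sqrt(v * z),
                        0, t[i], rel.tol = 1e-12)$value
    expect_equal(F[i] / lr_prefactor(GEOM), oracle, tolerance = 1e-6)
  }
})

test_that("production recursion matches the O(n^2) double-loop oracle", {
  m <- gm_model(300, G = c(2000, 900), tau = c(2e-4, 4e-3))
  t <- seq(0, 0.02, by = 2e-5)
  h <- 2e-6 * t
  a <- predict_force(m, t, h, GEOM, method = "recursive")
  b <- predict_force(m, t, h, GEOM, method = "direct")
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-12)
  # and both agree with a pure-R trapezoid double loop on a small grid
  tt <- t[1:200]; g <- (2e-6 * tt)^1.5; dt <- 2e-5
  I <- numeric(200)
  for (i in 2:200) {
    w <- exp(-(tt[i] - tt[1:i]) / 2e-4) * g[1:i]
    I[i] <- dt * (sum(w) - 0.5 * w[1] - 0.5 * w[i])
  }
  expect_equal(as.numeric(exp_trapz_rec(g, dt, 2e-4)), I, tolerance = 1e-12)
})

test_that("grid refinement converges at trapezoid order O(dt^2)", {
  m <- sls_100_300()
  v <- 2e-6
  err_at <- function(dt) {
    t <- seq(0, 0.02, by = dt)
    F <- predict_force(m, t, v * t, GEOM)
    Gt <- function(s) 100 + 300 * exp(-s / 1e-3)
    n <- length(t)
    oracle <- integrate(function(z) Gt(t[n] - z) * 1.5 * v * sqrt(v * z),
                        0, t[n], rel.tol = 1e-13)$value
    abs(F[n] / lr_prefactor(GEOM) - oracle)
  }
  e1 <- err_at(4e-5); e2 <- err_at(2e-5)
  expect_gt(e1 / e2, 3)  # halving dt cuts the error ~4x
  expect_lt(e1 / e2, 5)
})

test_that("predict_indentation handles elastic, creep and SLS round trips", {
  t <- seq(0, 0.02, by = 2e-5)
  # elastic limit: h^{3/2} = Jg F / k0
  Fel <- seq(0, 5e-9, length.out = length(t))
  g <- predict_indentation(gkv_model(1e-3), t, Fel, GEOM)
  expect_equal(g, 1e-3 * Fel / lr_prefactor(GEOM), tolerance = 1e-12)
  # step force -> creep curve J(t) F0 / k0
  kv <- gkv_model(2.5e-3, J = 7.5e-3, tau = 4e-3)
  Fstep <- c(0, rep(2e-9, length(t) - 1))
  g <- predict_indentation(kv, t, Fstep, GEOM)
  expected <- creep_compliance(kv, t) * 2e-9 / lr_prefactor(GEOM)
  # the discrete "step" is smeared over one sample, so the trapezoid sees a
  # ramp delayed by dt/2: error ~ (dt/2) J'(0) F0
  expect_lt(max(abs(g[-1] - expected[-1])) / max(expected), 5e-3)
  # composition: predict_indentation(predict_force(h)) recovers h^{3/2}
  m <- sls_100_300()
  h <- 2e-6 * t
  F <- predict_force(m, t, h, GEOM)
  g2 <- predict_indentation(sls_interconvert(m), t, F, GEOM)
  expect_lt(max(abs(g2[-1] - h[-1]^1.5) / max(h^1.5)), 1e-4)
})

test_that("grid and sign preconditions give descriptive errors", {
  m <- gm_model(100)
  expect_error(predict_force(m, c(0, 1e-3, 3e-3), c(0, 1e-9, 2e-9), GEOM),
               "resample")
  expect_error(predict_force(m, c(1e-3, 2e-3), c(0, 1e-9), GEOM), "start at 0")
  expect_error(predict_force(m, c(0, 1e-3), c(0, -1e-9), GEOM), "non-negative")
  expect_error(predict_indentation(gkv_model(1e-3), c(0, 1e-3), c(0, -1), GEOM),
               "non-negative")
})

test_that("action integral is self-consistent and detects misfit", {
  m <- gm_model(500, G = c(1500, 700), tau = c(2e-4, 2e-3))
  cv <- simulate_curve(m, prot_tiny(), GEOM, seed = 1)
  ai <- action_integral(m, cv)
  expect_lt(max(abs(ai$observable - ai$convolution)) /
              max(abs(ai$observable)), 1e-12)
  # zero-force/zero-indentation curve -> both series identically zero
  t <- seq(0, 0.003, by = 2e-4)
  cv0 <- force_curve(t, rep(0, 16), rep(0, 16), GEOM)
  ai0 <- action_integral(m, cv0)
  expect_equal(ai0$observable, rep(0, 16))
  expect_equal(ai0$convolution, rep(0, 16))
  # a 1-arm misfit model on 2-arm data leaves strictly positive SSE
  expect_gt(sse_cost(gm_model(500, G = 1500, tau = 2e-4), cv), 0)
  # Kelvin-Voigt side: SLS twin of the generator reproduces the curve
  # (50 kHz here: the two independent trapezoid routes only agree to the
  # quadrature error, which scales as (dt/tau)^2)
  m1 <- sls_100_300()
  cv1 <- simulate_curve(m1, ramp_protocol(speed = 5e-6, trigger_force = 5e-9),
                        GEOM, seed = 2)
  ai1 <- action_integral(sls_interconvert(m1), cv1)
  expect_lt(max(abs(ai1$observable - ai1$convolution)) /
              max(abs(ai1$observable)), 1e-3)
})
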