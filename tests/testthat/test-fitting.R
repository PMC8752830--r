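test_that("SSE cost is zero for the generator and positive for misfits", {
  m <- gm_model(800, G = 1600, tau = 2e-4)
  cv <- simulate_curve(m, prot_tiny(), GEOM, seed = 1)
  expect_lt(sse_cost(m, cv), 1e-12)
  # doubling the modulus of a correct elastic model gives the closed-form SSE
  el <- gm_model(1000)
  cve <- simulate_curve(el, prot_tiny(), GEOM, seed = 1)
  g <- cve$h^1.5
  expect_equal(sse_cost(gm_model(2000), cve), sum((1000 * g)^2),
               tolerance = 1e-9)
})

test_that("closed-form elastic fit is exact and linear", {
  cve <- simulate_curve(gm_model(1000), prot_tiny(), GEOM, seed = 1)
  expect_equal(fit_elastic(cve), 1000, tolerance = 1e-12)
  cv2 <- cve
  cv2$F <- 2 * cv2$F
  expect_equal(fit_elastic(cv2), 2000, tolerance = 1e-12)
  # relaxing data: effective modulus between equilibrium and glassy
  m <- sls_100_300()
  cvs <- simulate_curve(m, prot_tiny(), GEOM, seed = 2)
  Ge_hat <- fit_elastic(cvs)
  expect_gt(Ge_hat, 100)
  expect_lt(Ge_hat, 400)
  t <- seq(0, 0.003, by = 2e-4)
  expect_error(fit_elastic(force_curve(t, rep(0, 16), rep(0, 16), GEOM)),
               "degenerate")
})

test_that("open search recovers a 1-arm model and is deterministic", {
  m <- gm_model(500, G = 1500, tau = 1e-4)
  cv <- simulate_curve(m, prot_tiny(), GEOM, seed = 3)
  cfg <- cfg_tiny(max_terms = 1)
  fit <- fit_open_search(cv, GEOM, 1, cfg)
  expect_lt(max_param_err(fit$model, m), 0.01)
  expect_true(fit$converged)
  expect_equal(nrow(fit$attempt_log), cfg$n_attempts)
  # determinism: identical call -> identical result (sans wall time)
  fit2 <- fit_open_search(cv, GEOM, 1, cfg)
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$attempt_log, fit2$attempt_log)
  expect_identical(fit$sse, fit2$sse)
})

test_that("open search on elastic data parks the arm at negligible weight", {
  cve <- simulate_curve(gm_model(1200), prot_tiny(), GEOM, seed = 5)
  fit <- fit_open_search(cve, GEOM, 1, cfg_tiny(max_terms = 1))
  expect_equal(fit$model$Ge, 1200, tolerance = 0.01)
  expect_lt(fit$model$G[1] / (fit$model$Ge + fit$model$G[1]), 0.01)
})

test_that("iterative ladder warm-starts, nests, and recovers 2 arms", {
  m <- gm_model(400, G = c(2000, 900), tau = c(1e-4, 1e-3))
  cv <- simulate_curve(m, prot_tiny(), GEOM, seed = 6)
  cfg <- cfg_tiny(max_terms = 3)
  fits <- fit_iterative(cv, GEOM, cfg)
  expect_length(fits, 3)
  expect_lt(max_param_err(fits[[2]]$model, m), 0.05)
  # nesting: each stage at least as good as the previous (fallback attempt),
  # up to a floor of 1e-10 of the signal energy: arm magnitudes are bounded
  # below by 1 Pa, so a redundant arm perturbs the convolution by ~G_lo/G0
  # relatively and the re-tuned fit leaves a tiny but nonzero residual
  sses <- vapply(fits, `[[`, 0, "sse")
  floor_sse <- 1e-10 * sum((cv$F / lr_prefactor(GEOM))^2)
  expect_true(all(diff(sses) <= 1e-6 * sses[-length(sses)] + floor_sse))
  # elastic data: stage-1 cost no worse than the elastic-only cost
  cve <- simulate_curve(gm_model(1000), prot_tiny(), GEOM, seed = 7)
  f1 <- fit_iterative(cve, GEOM, cfg_tiny(max_terms = 1))[[1]]
  floor_e <- 1e-10 * sum((cve$F / lr_prefactor(GEOM))^2)
  expect_lte(f1$sse, sse_cost(gm_model(fit_elastic(cve)), cve) + floor_e)
  # iterative attempt log has the fallback attempt 0 plus n_attempts restarts
  expect_equal(nrow(f1$attempt_log), cfg_tiny()$n_attempts + 1L)
})

test_that("every reported parameter sits strictly inside its bounds", {
  cfg <- cfg_tiny(max_terms = 2)
  cv <- simulate_curve(gm_model(700, G = 1400, tau = 1e-4), prot_tiny(),
                       GEOM, seed = 8)
  fits <- fit_iterative(cv, GEOM, cfg)
  for (f in fits) {
    th <- viscofit:::model_to_theta(f$model)
    b <- viscofit:::theta_bounds(cfg, f$n_terms)
    expect_true(all(th > b$lower & th < b$upper))
  }
})

test_that("timescale windows are increasing, disjoint decades", {
  cfg <- fit_config()
  w1 <- tau_window(cfg, 1)
  w2 <- tau_window(cfg, 2)
  expect_equal(w1[1], 1e-4 / sqrt(10), tolerance = 0.01)
  expect_equal(w1[2], 1e-4 * sqrt(10), tolerance = 0.01)
  expect_lt(w1[2], w2[1])
  expect_equal(w2[1] / w1[1], 10, tolerance = 1e-6)
})

test_that("select_terms applies the parsimony rule", {
  m2 <- gm_model(400, G = c(2000, 900), tau = c(1e-4, 1e-3))
  cv <- simulate_curve(m2, prot_tiny(), GEOM, seed = 9)
  cfg <- cfg_tiny(max_terms = 3)
  fits <- fit_iterative(cv, GEOM, cfg)
  expect_equal(select_terms(fits, cv, GEOM, cfg), 2L)
  # elastic data -> minimal configuration
  cve <- simulate_curve(gm_model(900), prot_tiny(), GEOM, seed = 10)
  fe <- fit_iterative(cve, GEOM, cfg_tiny(max_terms = 2))
  expect_equal(select_terms(fe, cve, GEOM, cfg_tiny(max_terms = 2)), 1L)
  # eps -> Inf always selects 1
  cfg_inf <- cfg_tiny(max_terms = 3, select_eps = Inf)
  expect_equal(select_terms(fits, cv, GEOM, cfg_inf), 1L)
  expect_error(select_terms(list(), cv, GEOM, cfg), "empty")
})

test_that("Kelvin-Voigt family fits its own synthetic data", {
  m <- sls_100_300()
  cv <- simulate_curve(m, prot_tiny(), GEOM, seed = 11)
  kv_true <- sls_interconvert(m)   # tau_ret = 4e-3: third window
  cfg <- cfg_tiny(family = "kelvinvoigt", max_terms = 2, tau_seed = 4e-4)
  fits <- fit_iterative(cv, GEOM, cfg)
  best <- fits[[select_terms(fits, cv, GEOM, cfg)]]$model
  expect_s3_class(best, "generalized_kelvin_voigt")
  expect_equal(best$Jg, kv_true$Jg, tolerance = 0.05)
  expect_equal(sum(best$J), kv_true$J, tolerance = 0.1)
})

test_that("compare_methods produces a reproducible populated report", {
  cfg <- cfg_tiny(max_terms = 1, n_attempts = 5)
  cmp <- compare_methods(gm_model(500, G = 1500, tau = 1e-4), prot_tiny(),
                         GEOM, cfg, n_replicates = 2, seed = 13)
  expect_s3_class(cmp, "method_comparison")
  expect_equal(nrow(cmp$table), 2 * 2)  # 2 methods x 1 term x 2 replicates
  expect_setequal(unique(cmp$table$method), c("iterative", "open"))
  cmp2 <- compare_methods(gm_model(500, G = 1500, tau = 1e-4), prot_tiny(),
                          GEOM, cfg, n_replicates = 2, seed = 13)
  expect_identical(cmp$table$sse, cmp2$table$sse)
  expect_identical(cmp$summary[c("median_sse", "sd_sse")],
                   cmp2$summary[c("median_sse", "sd_sse")])
})

test_that("fit results serialize to JSON without wall-clock fields", {
  cv <- simulate_curve(gm_model(500, G = 1500, tau = 1e-4), prot_tiny(),
                       GEOM, seed = 3)
  fit <- fit_open_search(cv, GEOM, 1, cfg_tiny(max_terms = 1))
  txt <- fit_to_json(fit)
  doc <- jsonlite::fromJSON(txt)
  expect_equal(doc$n_terms, 1)
  expect_equal(doc$model$family, "maxwell")
  expect_false(grepl("elapsed", txt))
  expect_identical(fit_to_json(fit), txt)
})
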