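# Closed-form coverage densities, areas and per-read likelihoods.

test_that("synthesis end-point densities carry the correct boundary mass", {
  l <- 6000

  # zero stop rate forces full-length synthesis
  pd0 <- synthesis_end_density(l, 0, "toward_5prime", l)
  expect_equal(pd0$point_masses$position, 0)
  expect_equal(pd0$point_masses$mass, 1)
  expect_equal(pd0$continuous(l / 2), 0)

  # theta * l = log(2) leaves half the mass at the 5' end
  pd <- synthesis_end_density(l, log(2) / l, "toward_5prime", l)
  expect_equal(pd$point_masses$mass, 0.5)

  # continuous part integrates to 1 - exp(-theta*l); total mass is 1
  pd2 <- synthesis_end_density(l, 2e-4, "toward_5prime", l)
  cont <- integrate(pd2$continuous, 0, l, rel.tol = 1e-10)$value
  expect_equal(cont, 1 - exp(-1.2), tolerance = 1e-9)
  expect_equal(pd2$total_mass(), 1, tolerance = 1e-9)

  # second strand: mass sits at the 3' terminus
  pd3 <- synthesis_end_density(1000, 5e-4, "toward_3prime", l)
  expect_equal(pd3$point_masses$position, l)
  expect_equal(pd3$point_masses$mass, exp(-5e-4 * 5000))
  expect_equal(pd3$total_mass(), 1, tolerance = 1e-9)

  expect_error(synthesis_end_density(-1, 1e-4, "toward_5prime", l), "start")
  expect_error(synthesis_end_density(l + 1, 1e-4, "toward_5prime", l), "start")
  expect_error(synthesis_end_density(10, -1e-4, "toward_5prime", l), "theta")
})

test_that("coverage density matches hand-computable limits", {
  l <- 1000
  # zero-rate identity: interior weight (1/d + 1) * exp(0)
  p0 <- model_params(theta1 = 0, theta2 = 0, d = 1, h = 0)
  expect_equal(coverage_density("A", p0, c(1, 250, 999), l), rep(2, 3))

  # theta1 + theta2 = log(2)/l halves it
  ph <- model_params(theta1 = log(2) / (2 * l), theta2 = log(2) / (2 * l),
                     d = 1, h = 0)
  expect_equal(coverage_density("A", ph, 500, l), 1)

  # model D is 3'-biased even at equal rates: the second strand has to
  # re-cover the first strand's span, so f(x) ~ e^{-th(l-x)} + e^{-th(l+x)}
  # (for h = 0) rises monotonically toward the 3' end
  ps <- model_params(theta1 = 3e-4, theta2 = 3e-4, d = 4, h = 0)
  x <- seq(10, 990, by = 49)
  fx <- coverage_density("D", ps, x, l)
  expect_true(all(diff(fx) > 0))
  th <- 3e-4
  expect_equal(fx, (1 / ps$d + 1) *
                 (exp(-th * (l - x)) + exp(-th * (l + x))) / 2,
               tolerance = 1e-12)
  # and exactly at the 5' boundary only the edge branch applies
  expect_equal(coverage_density("D", ps, 0, l), exp(-th * l) / ps$d,
               tolerance = 1e-12)

  # interior/edge density ratio is exactly d + 1 where both g-parts
  # coincide (model A)
  pa <- model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150)
  expect_equal(coverage_density("A", pa, 500, 6000) /
                 coverage_density("A", pa, 50, 6000), pa$d + 1)

  # domain errors
  expect_error(coverage_density("D", pa, -1, l), "\\[0, l\\]")
  expect_error(coverage_density("D", pa, l + 1, l), "\\[0, l\\]")
  expect_error(model_params(d = 0), "d must be")
  expect_error(coverage_density("Z", pa, 1, l), "unknown model")
  expect_error(coverage_area("Z", pa, l), "unknown model")
  expect_error(sample_read("Z", pa, l), "unknown model")
})

test_that("the BD mixture is exactly linear in its components", {
  l <- 6000
  x <- seq(0, l, length.out = 101)
  for (a in c(0, 0.25, 0.5, 0.9, 1)) {
    p <- model_params(theta1 = 2e-4, theta2 = 5e-4, d = 4, h = 150,
                      alpha = a)
    expect_equal(coverage_density("BD", p, x, l),
                 a * coverage_density("B", p, x, l) +
                   (1 - a) * coverage_density("D", p, x, l),
                 tolerance = 1e-13)
    expect_equal(coverage_area("BD", p, l),
                 a * coverage_area("B", p, l) +
                   (1 - a) * coverage_area("D", p, l),
                 tolerance = 1e-13)
  }
})

test_that("exponentiated per-read likelihood integrates to one", {
  set.seed(41)
  for (m in MODEL_IDS) {
    for (p in param_grid()) {
      l <- sample(c(800, 4000, 12000), 1)
      v <- integrate(function(x) exp(read_log_likelihood(m, p, x, l)),
                     0, l, rel.tol = 1e-10, subdivisions = 400L)$value
      expect_equal(v, 1, tolerance = 1e-8,
                   label = paste("normalization", m, "l =", l))
    }
  }
})

test_that("closed-form areas equal adaptive quadrature on the full grid", {
  for (m in MODEL_IDS) {
    for (p in param_grid()) {
      for (l in c(300, 2000, 6000, 20000)) {
        a <- coverage_area(m, p, l)
        q <- quad_area(m, p, l)
        expect_lt(abs(a - q) / q, 1e-6,
                  label = paste("area", m, "l =", l, "h =", p$h))
      }
    }
  }
})

test_that("model C area decreases with length for theta1 > 0", {
  p <- model_params(theta1 = 5e-4, theta2 = 3e-4, d = 4, h = 100)
  areas <- coverage_area("C", p, c(2000, 4000, 8000, 16000))
  expect_true(all(diff(areas) < 0))
})

test_that("per-read log-likelihood has the closed-form single-read value", {
  p <- default_params()
  l <- 6000
  # model A interior: log((1/d+1) e^{-l(th1+th2)}) - log(area)
  ll <- read_log_likelihood("A", p, 3000, l)
  expect_equal(ll, log((1 / p$d + 1) * exp(-l * (p$theta1 + p$theta2))) -
                 log(coverage_area("A", p, l)), tolerance = 1e-12)
  # model D, h = 0, equal rates: independent re-derivation of the
  # normalized log-density
  ps <- model_params(theta1 = 3e-4, theta2 = 3e-4, d = 4, h = 0)
  th <- 3e-4
  f1200 <- (1 / ps$d + 1) * (exp(-th * (l - 1200)) + exp(-th * (l + 1200))) / 2
  areaD <- (1 / ps$d + 1) * (1 - exp(-2 * th * l)) / (2 * th)
  expect_equal(read_log_likelihood("D", ps, 1200, l),
               log(f1200) - log(areaD), tolerance = 1e-12)
  # degenerate parameters signal -Inf, not an error
  expect_identical(read_log_likelihood("A", model_params(theta1 = 1, d = 1),
                                       10, 6000), -Inf)
})

test_that("mean log-likelihood peaks near the generating rate (grid oracle)", {
  p <- default_params()
  set.seed(21)
  x <- sample_read("D", p, 6000, 4000)
  grid <- c(1e-4, 2.5e-4, 5e-4, 1e-3, 2e-3)
  mll <- vapply(grid, function(t2) {
    mean(read_log_likelihood("D", model_params(p$theta1, t2, p$d, p$h),
                             x, 6000))
  }, numeric(1))
  expect_equal(grid[which.max(mll)], 5e-4)
})

test_that("model D shows the documented shape transitions with length", {
  p <- default_params()
  # short transcripts: maximum nearer the 5' end
  x1 <- seq(1, 999, length.out = 1001)
  d1 <- coverage_density("D", p, x1, 1000)
  expect_lt(x1[which.max(d1)], 500)
  # intermediate: two boundary-adjacent maxima, interior minimum
  x4 <- seq(p$h + 1e-6, 4000 - p$h - 1e-6, length.out = 2001)
  d4 <- coverage_density("D", p, x4, 4000)
  imin <- which.min(d4)
  expect_gt(imin, 1)
  expect_lt(imin, length(x4))
  expect_gt(d4[1], d4[imin])
  expect_gt(d4[length(d4)], d4[imin])
  # long: 3' side dominates, and the 5' interior edge sits below the 3'
  # interior edge (edge asymmetry)
  l <- 12000
  dd <- coverage_density("D", p, c(p$h + 1e-4, l - p$h - 1e-4), l)
  expect_gt(dd[2], dd[1])
})

test_that("parameter configs round-trip through YAML and JSON", {
  p <- model_params(theta1 = 1.5e-4, theta2 = 7e-4, d = 2.5, h = 80,
                    alpha = 0.3, alpha1 = 1e-5, alpha2 = 2e-5)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_params_config("BD", p, f)
    back <- read_params_config(f)
    expect_identical(back$model, "BD")
    expect_equal(unclass(back$params), unclass(p), tolerance = 1e-12)
  }
})
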