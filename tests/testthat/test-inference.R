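# Read subsampling, dataset likelihood, MCMC fitting and model ranking.

test_that("subsampling caps reads per transcript and balances strata", {
  set.seed(2)
  ids <- sprintf("T%03d", 1:40)
  lens <- seq(500, 20000, length.out = 40)
  reads <- lapply(seq_along(ids), function(i) {
    runif(if (i <= 20) 500 else 40, 0, lens[i])
  })
  rs <- read_set(ids, lens, reads)

  sub <- subsample_reads(rs, max_reads_per_transcript = 100,
                         length_bins = 2)
  n <- n_reads(sub, total = FALSE)
  expect_true(all(n <= 100))
  # under-cap transcripts keep everything unless balancing removes reads:
  # the short stratum holds 20 x min(500,100)=2000, the long one 20 x 40=800;
  # both must end at 800
  short <- sum(n[1:20])
  long <- sum(n[21:40])
  expect_equal(long, 800)
  expect_equal(short, 800)
  # retained reads are a subset of the originals
  expect_true(all(sub$reads[[1]] %in% rs$reads[[1]]))

  # a transcript with 50 reads and cap 100 keeps all 50 (single stratum)
  rs1 <- read_set("t", 1000, list(runif(50, 0, 1000)))
  expect_equal(n_reads(subsample_reads(rs1, 100, 1)), 50)

  # stratum without reads triggers a warning and is dropped
  rs2 <- read_set(c("a", "b"), c(1000, 9000),
                  list(runif(30, 0, 1000), numeric(0)))
  expect_warning(subsample_reads(rs2, 100, 2), "no reads")
})

test_that("dataset log-likelihood obeys its contracts", {
  p <- default_params()
  empty <- read_set("t", 1000)
  expect_identical(dataset_log_likelihood(empty, "D", p), 0)

  # single-read closed form, model A interior position
  one <- read_set("t", 6000, list(2500))
  expect_equal(dataset_log_likelihood(one, "A", p),
               log((1 / p$d + 1) * exp(-6000 * (p$theta1 + p$theta2))) -
                 log(coverage_area("A", p, 6000)), tolerance = 1e-10)

  # invariance under transcript and read reordering
  rs <- small_sim("D", p, 15, 30, seed = 5)
  perm <- sample(15)
  rs_perm <- read_set(rs$transcripts$id[perm], rs$transcripts$length[perm],
                      lapply(rs$reads[perm], rev))
  for (m in MODEL_IDS) {
    expect_equal(dataset_log_likelihood(rs, m, p),
                 dataset_log_likelihood(rs_perm, m, p), tolerance = 1e-9)
  }

  # compiled and reference engines agree for every model
  for (m in MODEL_IDS) {
    expect_equal(dataset_log_likelihood(rs, m, p, engine = "cpp"),
                 dataset_log_likelihood(rs, m, p, engine = "r"),
                 tolerance = 1e-10, label = m)
  }
  # ... including models that drop parameters and the E rate convention
  pe <- model_params(theta1 = 1e-4, theta2 = 3e-4, d = 2, h = 50,
                     alpha1 = 2e-4, alpha2 = 1e-4)
  expect_equal(dataset_log_likelihood(rs, "E", pe, engine = "cpp"),
               dataset_log_likelihood(rs, "E", pe, engine = "r"),
               tolerance = 1e-10)
})

test_that("likelihood prefers generating over perturbed parameters", {
  p <- default_params()
  wrong <- model_params(theta1 = 4e-4, theta2 = 1e-3, d = 8, h = 300)
  wins <- 0
  for (r in 1:40) {
    rs <- small_sim("D", p, 15, 25, seed = 400 + r)
    if (dataset_log_likelihood(rs, "D", p) >
          dataset_log_likelihood(rs, "D", wrong)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 38)
})

test_that("mcmc_fit is deterministic given the seed", {
  rs <- small_sim("D", default_params(), 50, 25, seed = 8)
  fc <- fit_config("D", n_iterations = 400, burn_in = 150, seed = 3)
  f1 <- suppressWarnings(mcmc_fit(rs, fc))
  f2 <- suppressWarnings(mcmc_fit(rs, fc))
  expect_identical(f1$median, f2$median)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$max_log_likelihood, f2$max_log_likelihood)
  # medians/MADs come from post-burn-in samples only
  post <- f1$chains[151:400, "d"]
  expect_equal(unname(f1$median["d"]), median(post))
  expect_true(all(f1$mad >= 0))
})

test_that("degenerate inputs are handled with diagnostics", {
  expect_error(subsample_reads(read_set("t", 100), 10, 1), "empty")
  # extreme priors (h far above any transcript length, so only the edge
  # branch ever applies) still give a well-defined, finite fit
  rs <- small_sim("D", default_params(), 5, 10, seed = 1)
  fc <- fit_config("D", n_iterations = 200, burn_in = 50, seed = 1,
                   priors = list(theta = c(1e-6, 1e-2), d = c(1e-4, 100),
                                 h = c(2e4, 3e4), alpha = c(0, 1)))
  fit <- suppressWarnings(mcmc_fit(rs, fc))
  expect_s3_class(fit, "posterior_summary")
  expect_true(is.finite(fit$max_log_likelihood))
  expect_error(fit_config("D", n_iterations = 100, burn_in = 100),
               "burn_in")
})

test_that("SMART-like processivities are recovered inside their brackets", {
  # 1/theta1 in [5,10] kb and 1/theta2 in [1,3] kb, B&D mixture library
  p <- model_params(theta1 = 1 / 7000, theta2 = 1 / 2000, d = 4, h = 150,
                    alpha = 0.4)
  rs <- small_sim("BD", p, 500, 40, seed = 13)
  fit <- suppressWarnings(
    mcmc_fit(rs, fit_config("BD", n_iterations = 4000, burn_in = 1500,
                            seed = 29)))
  expect_gt(1 / fit$median["theta1"], 5000)
  expect_lt(1 / fit$median["theta1"], 10000)
  expect_gt(1 / fit$median["theta2"], 1000)
  expect_lt(1 / fit$median["theta2"], 3000)
})

test_that("model ranking reports ratios and rejects mismatched fits", {
  rs <- small_sim("D", default_params(), 60, 25, seed = 44)
  rs_sub <- subsample_reads(rs)
  fits <- lapply(c("A", "D"), function(m) {
    suppressWarnings(mcmc_fit(rs_sub, fit_config(
      m, n_iterations = 600, burn_in = 200, seed = 5, subsample = FALSE)))
  })
  rk <- compare_models(rs_sub, fits)
  expect_equal(rk$model[1], "D")
  expect_equal(rk$log_ratio_vs_best[1], 0)
  expect_lt(rk$log_ratio_vs_best[2], 0)
  pw <- attr(rk, "pairwise")
  expect_equal(dim(pw), c(2, 2))
  expect_equal(pw[1, 2], -pw[2, 1])

  # single fit: ranking of length one, zero ratio
  rk1 <- compare_models(rs_sub, fits[[2]])
  expect_equal(nrow(rk1), 1)
  expect_equal(rk1$log_ratio_vs_best, 0)

  # fits on different data are refused
  other <- subsample_reads(small_sim("D", default_params(), 60, 25,
                                     seed = 45))
  fit_other <- suppressWarnings(mcmc_fit(other, fit_config(
    "D", n_iterations = 600, burn_in = 200, seed = 5, subsample = FALSE)))
  expect_error(compare_models(rs_sub, list(fits[[1]], fit_other)),
               "different")
  expect_error(compare_models(other, fits), "does not match")
})

test_that("fit summaries round-trip through JSON", {
  rs <- small_sim("D", default_params(), 30, 20, seed = 21)
  fit <- suppressWarnings(mcmc_fit(rs, fit_config(
    "D", n_iterations = 300, burn_in = 100, seed = 9)))
  f <- tempfile(fileext = ".json")
  ch <- tempfile(fileext = ".tsv")
  write_fit_summary(fit, f, chains_path = ch)
  back <- read_fit_summary(f)
  expect_equal(back$model, "D")
  expect_equal(back$median, fit$median, tolerance = 1e-12)
  expect_equal(back$max_log_likelihood, fit$max_log_likelihood,
               tolerance = 1e-12)
  expect_equal(nrow(data.table::fread(ch)), fit$n_iterations)
})
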