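# Sampler contracts, convergence diagnostics, summaries, draw I/O.

test_that("run_mcmc is deterministic given seed and respects support", {
  b <- make_study_like_bundle(seed = 51)
  cfg <- tiny_sampler(seed = 99)
  f1 <- run_mcmc(b$data, sources = "parasites", config = cfg)
  f2 <- run_mcmc(b$data, sources = "parasites", config = cfg)
  expect_identical(f1$chains, f2$chains)
  f3 <- run_mcmc(b$data, sources = "parasites",
                 config = tiny_sampler(seed = 100))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
  # retained dimensions follow (n_iter - burn_in) / thin
  expect_equal(nrow(f1$chains[[1]]), (cfg$n_iter - cfg$burn_in) / cfg$thin)
  # every retained draw satisfies the support constraints
  X <- as.matrix(f1)
  f_cols <- grep("^f_nb", colnames(X))
  expect_true(all(X[, f_cols] > 0 & X[, f_cols] < 1))
  expect_true(all(X[, "a"] > 0))
  expect_true(all(X[, "theta"] <= 0))
  m_cols <- grep("^m\\[", colnames(X))
  expect_true(all(X[, m_cols] >= 0 & X[, m_cols] <= 1))
  row_sums <- sapply(seq_len(8), function(i) {
    rowSums(X[, m_cols[((i - 1) * 4 + 1):(i * 4)], drop = FALSE])
  })
  expect_equal(range(row_sums), c(1, 1), tolerance = 1e-12)
  # implied breeding prevalences stay in (0,1) on the Table 3 fixture
  fb_draws <- X[, "a"] * (X[, "m[Central_breeding,Western]"] *
                            X[, "f_nb[Western,GRW09]"] +
                            X[, "m[Central_breeding,Central]"] *
                            X[, "f_nb[Central,GRW09]"] +
                            X[, "m[Central_breeding,Eastern]"] *
                            X[, "f_nb[Eastern,GRW09]"] +
                            X[, "m[Central_breeding,Southern]"] *
                            X[, "f_nb[Southern,GRW09]"])
  expect_true(all(fb_draws > 0 & fb_draws < 1))
})

test_that("run_mcmc validates inputs", {
  b <- make_study_like_bundle(seed = 52)
  expect_error(run_mcmc(mc_bundle(isotopes = b$data$isotopes), sources = "rings"),
               "no reencounter data")
  expect_error(sampler_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("gelman_rubin reproduces closed-form and limiting behavior", {
  x <- rnorm(400)
  # identical chains: B = 0, R-hat = sqrt((n-1)/n) exactly
  expect_equal(gelman_rubin(list(x, x, x)), sqrt(399 / 400), tolerance = 1e-12)
  # same-distribution chains approach 1
  set.seed(1)
  chains <- replicate(4, rnorm(5000), simplify = FALSE)
  expect_lt(gelman_rubin(chains), 1.01)
  # well-separated chains are flagged
  expect_gt(gelman_rubin(list(rnorm(500, 0), rnorm(500, 10))), 1.1)
  expect_error(gelman_rubin(list(rnorm(10))), "at least 2 chains")
  # named-parameter interface on a posterior_draws object
  b <- make_study_like_bundle(seed = 53)
  fit <- run_mcmc(b$data, sources = "parasites", config = tiny_sampler(seed = 3))
  rh <- gelman_rubin(fit, c("a", "f_nb[Central,GRW09]"))
  expect_named(rh, c("a", "f_nb[Central,GRW09]"))
  expect_error(gelman_rubin(fit, "nonexistent"), "unknown parameter")
})

test_that("summaries report means, sds and central credible intervals", {
  const <- structure(list(chains = list(
    matrix(5, 50, 2, dimnames = list(NULL, c("p1", "p2"))),
    matrix(5, 50, 2, dimnames = list(NULL, c("p1", "p2")))),
    param_names = c("p1", "p2")), class = "posterior_draws")
  s <- summarize_draws(const)
  expect_equal(s$mean, c(5, 5))
  expect_equal(s$sd, c(0, 0))
  expect_equal(s$q2.5, c(5, 5))
  expect_equal(s$q97.5, c(5, 5))
  # simplex conservation under averaging on a real fit
  b <- make_study_like_bundle(seed = 54)
  fit <- run_mcmc(b$data, config = tiny_sampler(seed = 4))
  s <- summarize_draws(fit)
  for (g in group_labels()) {
    rows <- grepl(paste0("^m\\[", g, ","), s$parameter)
    expect_equal(sum(s$mean[rows]), 1, tolerance = 1e-3)
  }
})

test_that("a conjugate corner matches the closed-form beta posterior", {
  # with no breeding samples, each wintering prevalence is conjugate:
  # f ~ Beta(1 + G, 1 + H - G), independent of everything else
  z45 <- matrix(0L, 4, 5)
  z35 <- matrix(0L, 3, 5)
  G <- z45; G[2, 3] <- 12L
  H <- z45; H[2, 3] <- 60L
  pd <- parasite_data(G, H, z35, z35)
  fit <- run_mcmc(mc_bundle(parasites = pd), sources = "parasites",
                  config = sampler_config(3, 12000, 4000, 4, seed = 7))
  draws <- as.matrix(fit)[, "f_nb[Central,GRW09]"]
  expect_equal(mean(draws), 13 / 62, tolerance = 0.01)
  qs <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  expect_equal(qs, qbeta(c(0.025, 0.5, 0.975), 13, 49), tolerance = 0.012)
})

test_that("draw CSV round trip preserves chain structure", {
  b <- make_study_like_bundle(seed = 55)
  fit <- run_mcmc(b$data, sources = "parasites", config = tiny_sampler(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- read_draws(path)
  expect_equal(length(back$chains), length(fit$chains))
  expect_equal(back$chains[[2]], fit$chains[[2]], ignore_attr = TRUE)
  expect_equal(back$param_names, fit$param_names)
})
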