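# Likelihoods, priors, transforms, and the R-vs-compiled dual route.

test_that("cell probabilities behave as products and conserve mass", {
  expect_equal(cell_probs_known(c(1, 0, 0, 0), rep(1, 4)), c(1, 0, 0, 0, 0))
  expect_equal(cell_probs_known(c(0.5, 0.5, 0, 0), rep(2e-4, 4)),
               c(1e-4, 1e-4, 0, 0, 1 - 2e-4))
  # r cancels in the conditional probabilities under equal reporting
  expect_equal(cond_cell_probs_unknown(c(0.1, 0.2, 0.3, 0.4), rep(0.37, 4)),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(cond_cell_probs_unknown(c(0.5, 0.5, 0, 0), c(0.1, 0.3, 0.2, 0.2)),
               c(0.25, 0.75, 0, 0))
  set.seed(42)
  for (i in 1:50) {
    m <- random_simplex()
    r <- runif(4)
    expect_equal(sum(cell_probs_known(m, r)), 1, tolerance = 1e-12)
    expect_equal(sum(cond_cell_probs_unknown(m, r)), 1, tolerance = 1e-12)
  }
  expect_error(cond_cell_probs_unknown(c(1, 0, 0, 0), c(0, 1, 1, 1)), "undefined")
})

test_that("ring log likelihoods match the multinomial pmf oracle", {
  # frozen examples
  expect_equal(loglik_known(c(4, 0, 0, 0, 0), c(1, 0, 0, 0), c(1, 0.5, 0.5, 0.5)), 0)
  expect_equal(loglik_known(c(1, 1, 1, 1, 0), rep(0.25, 4), rep(0.5, 4)),
               log(24 * 0.125^4), tolerance = 1e-12)
  expect_identical(loglik_known(c(0, 1, 0, 0, 0), c(1, 0, 0, 0), rep(0.5, 4)), -Inf)
  expect_equal(loglik_unknown(c(0, 0, 0, 0), random_simplex(), runif(4)), 0)
  expect_equal(loglik_unknown(c(1, 1, 0, 0), c(0.5, 0.5, 0, 0), c(0.1, 0.3, 1, 1)),
               log(2 * 0.25 * 0.75), tolerance = 1e-12)
  expect_error(loglik_known(c(1, 0, 0, 0, 0), rep(0.25, 4), rep(0.5, 4), N = 7),
               "must equal N")
  # randomized oracle equivalence against stats::dmultinom
  set.seed(7)
  for (i in 1:300) {
    m <- random_simplex()
    r <- runif(4)
    p5 <- cell_probs_known(m, r)
    x5 <- as.numeric(rmultinom(1, sample(0:6, 1), p5))
    expect_equal(loglik_known(x5, m, r),
                 dmultinom(x5, prob = p5, log = TRUE), tolerance = 1e-10)
    q <- cond_cell_probs_unknown(m, r)
    x4 <- as.numeric(rmultinom(1, sample(1:6, 1), q))
    expect_equal(loglik_unknown(x4, m, r),
                 dmultinom(x4, prob = q, log = TRUE), tolerance = 1e-10)
  }
  # multiplying all r by a common factor leaves the unknown-totals
  # likelihood unchanged: the non-identifiability motivating integration
  set.seed(8)
  for (i in 1:25) {
    m <- random_simplex()
    r <- runif(4, 0, 0.5)
    x <- as.numeric(rmultinom(1, 20, cond_cell_probs_unknown(m, r)))
    expect_equal(loglik_unknown(x, m, r), loglik_unknown(x, m, r * 1.9),
                 tolerance = 1e-10)
  }
})

# independent bivariate-normal density via the conditional decomposition
# f(x, y) = N(x; mu_x, s_x) * N(y; mu_y + rho s_y / s_x (x - mu_x),
#                               s_y sqrt(1 - rho^2))
oracle_bvn <- function(x, y, mu_x, mu_y, s_x, s_y, rho) {
  dnorm(x, mu_x, s_x, log = TRUE) +
    dnorm(y, mu_y + rho * s_y / s_x * (x - mu_x), s_y * sqrt(1 - rho^2),
          log = TRUE)
}

test_that("isotope mixture likelihood: closed forms, limits, marginalization", {
  st <- small_state()
  m <- st$m
  # single bird at the origin, equal weights, two standard components
  iso0 <- list(mu_S_d13C = 0, theta = 0, mu_WCE_d15N = 0, mu_S_d15N = 0,
               sigma_C = c(1, 1), sigma_N = c(1, 1), rho0 = c(0.5, 0.5))
  m50 <- m
  m50[population_rows(), ] <- rep(c(1 / 6, 1 / 6, 1 / 6, 1 / 2), each = 3)
  one <- isotope_data(matrix(0, 1, 2), 1,
                      constants = list(mean = c(0, 0), sd = c(1, 1)))
  expect_equal(isotope_loglik(one, iso0, m50), log(1 / (2 * pi)),
               tolerance = 1e-12)
  # single-component limit: all weight on the Southern component
  set.seed(11)
  y <- matrix(rnorm(40), 20, 2)
  dat <- isotope_data(y, rep(1:3, length.out = 20),
                      constants = list(mean = c(0, 0), sd = c(1, 1)))
  mS <- m
  mS[population_rows(), ] <- rep(c(0, 0, 0, 1), each = 3)
  iso <- st$iso
  rho <- rho_from_rho0(iso$rho0)
  expect_equal(isotope_loglik(dat, iso, mS),
               sum(oracle_bvn(y[, 1], y[, 2], iso$mu_S_d13C, iso$mu_S_d15N,
                              iso$sigma_C[2], iso$sigma_N[2], rho[2])),
               tolerance = 1e-10)
  # identifiability null case: identical components make m irrelevant
  iso_eq <- list(mu_S_d13C = 0.3, theta = 0, mu_WCE_d15N = -0.1,
                 mu_S_d15N = -0.1, sigma_C = c(0.8, 0.8),
                 sigma_N = c(1.2, 1.2), rho0 = c(0.6, 0.6))
  st2 <- small_state(2)
  expect_equal(isotope_loglik(dat, iso_eq, st$m), isotope_loglik(dat, iso_eq, st2$m),
               tolerance = 1e-10)
  # randomized two-component oracle via the conditional decomposition
  set.seed(12)
  for (i in 1:100) {
    stv <- sample_prior_state()
    isov <- stv$iso
    rhov <- rho_from_rho0(isov$rho0)
    mp <- stv$m[population_rows(), ]
    v1 <- rowSums(mp[, 1:3])[dat$pop]
    d1 <- oracle_bvn(y[, 1], y[, 2], isov$mu_S_d13C + isov$theta,
                     isov$mu_WCE_d15N, isov$sigma_C[1], isov$sigma_N[1], rhov[1])
    d2 <- oracle_bvn(y[, 1], y[, 2], isov$mu_S_d13C, isov$mu_S_d15N,
                     isov$sigma_C[2], isov$sigma_N[2], rhov[2])
    a1 <- d1 + log(v1)
    a2 <- d2 + log(1 - v1)
    top <- pmax(a1, a2)
    expect_equal(isotope_loglik(dat, isov, stv$m),
                 sum(top + log(exp(a1 - top) + exp(a2 - top))), tolerance = 1e-10)
  }
  # sampled-indicator route vs analytic marginalization: with W drawn from
  # its prior, E_W[ exp(conditional loglik) ] equals the marginal
  # likelihood, so the mean importance ratio is 1 (small n, 3 SE band)
  n_small <- 6L
  dat6 <- isotope_data(y[1:n_small, ], dat$pop[1:n_small],
                       constants = list(mean = c(0, 0), sd = c(1, 1)))
  iso_mod <- list(mu_S_d13C = 0.5, theta = -1, mu_WCE_d15N = -0.3,
                  mu_S_d15N = 0.3, sigma_C = c(1, 1), sigma_N = c(1, 1),
                  rho0 = c(0.4, 0.7))
  st3 <- small_state(3)
  marg <- isotope_loglik(dat6, iso_mod, st3$m)
  mp3 <- st3$m[population_rows(), ]
  v2 <- mp3[, 4][dat6$pop]
  set.seed(13)
  B <- 4000
  ratio <- numeric(B)
  for (b in 1:B) {
    W <- 1L + (runif(n_small) < v2)
    cond <- isotope_loglik(dat6, iso_mod, st3$m, W = W) -
      sum(log(ifelse(W == 1L, 1 - v2, v2)))
    ratio[b] <- exp(cond - marg)
  }
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(B))
})

test_that("parasite likelihood follows the mixing equation and binomial pmf", {
  st <- small_state(4)
  # indicator mixing: a population entirely in one area inherits its rates
  m1 <- st$m
  m1[4, ] <- c(1, 0, 0, 0) # Central population all-Western
  fb <- breeding_prevalence(st$par$f_nb, 1, m1)
  expect_equal(unname(fb["Central", ]), unname(st$par$f_nb["Western", ]))
  # arithmetic example: a = 2, equal mixing over (0.1, 0.2, 0.3, 0.4)
  f <- matrix(c(0.1, 0.2, 0.3, 0.4), 4, 5)
  m2 <- st$m
  m2[population_rows(), ] <- 0.25
  expect_equal(unname(breeding_prevalence(f, 2, m2)[1, 1]), 0.5)
  # the study's largest cell in isolation: likelihood equals the direct
  # binomial pmf at the empirical rate (the mode)
  z45 <- matrix(0L, 4, 5)
  z35 <- matrix(0L, 3, 5)
  G1 <- z45; G1[2, 3] <- 74L
  H1 <- z45; H1[2, 3] <- 2767L
  one_cell <- parasite_data(G1, H1, z35, z35)
  st_cell <- small_state(9)
  st_cell$par$f_nb[2, 3] <- 74 / 2767
  expect_equal(parasite_loglik(one_cell, st_cell$par, st_cell$m),
               dbinom(74, 2767, 74 / 2767, log = TRUE), tolerance = 1e-10)
  pd <- table3_parasites()
  # randomized oracle equivalence
  set.seed(14)
  for (i in 1:100) {
    stv <- sample_prior_state()
    ll <- parasite_loglik(pd, stv$par, stv$m)
    f_b <- breeding_prevalence(stv$par$f_nb, stv$par$a, stv$m)
    if (any(f_b >= 1)) {
      expect_identical(ll, -Inf)
    } else {
      oracle <- sum(dbinom(pd$G_nb, pd$H_nb, stv$par$f_nb, log = TRUE)) +
        sum(dbinom(pd$G_b, pd$H_b, f_b, log = TRUE))
      expect_equal(ll, oracle, tolerance = 1e-10)
    }
  }
  # invalid-region handling: f_b >= 1 has zero posterior density
  stv <- small_state(5)
  stv$par$a <- 1e6
  expect_identical(parasite_loglik(pd, stv$par, stv$m), -Inf)
})

test_that("log prior encodes the stated densities and truncations", {
  st <- small_state(6)
  pr <- mc_priors()
  # independent recomputation of every non-flat term
  oracle <- dnorm(st$iso$mu_S_d13C, 0.97, 0.07, log = TRUE) +
    dnorm(st$iso$theta, 0, 1, log = TRUE) + log(2) +
    dnorm(st$iso$mu_WCE_d15N, 0, 1, log = TRUE) +
    dnorm(st$iso$mu_S_d15N, 0, 1, log = TRUE) +
    sum(dnorm(c(st$iso$sigma_C, st$iso$sigma_N), 0, 2, log = TRUE) + log(2)) +
    dbeta(st$iso$rho0[["WCE"]], 2, 4, log = TRUE) +
    dbeta(st$iso$rho0[["Southern"]], 10, 4, log = TRUE) +
    dnorm(st$par$a, 0, 5, log = TRUE) + log(2)
  expect_equal(log_prior(st, pr), oracle, tolerance = 1e-12)
  # theta is truncated to be nonpositive
  st_bad <- st
  st_bad$iso$theta <- 0.5
  expect_identical(log_prior(st_bad, pr), -Inf)
  # Beta(10,4) prior on rho0_Southern peaks at (10-1)/(10+4-2) = 0.75,
  # i.e. rho = 0.5
  at <- function(x) {
    s <- st
    s$iso$rho0["Southern"] <- x
    log_prior(s, pr)
  }
  expect_gt(at(0.75), at(0.6))
  expect_gt(at(0.75), at(0.9))
})

test_that("log posterior is additive over active sources", {
  b <- make_study_like_bundle(seed = 21)
  st <- small_state(7)
  lp_r <- log_posterior(st, b$data, "rings")
  lp_i <- log_posterior(st, b$data, "isotopes")
  lp_p <- log_posterior(st, b$data, "parasites")
  pr <- log_prior(st)
  lp_all <- log_posterior(st, b$data)
  expect_equal(lp_all, lp_r + lp_i + lp_p - 2 * pr, tolerance = 1e-10)
  expect_equal(log_posterior(st, b$data, "parasites"),
               pr + parasite_loglik(b$data$parasites, st$par, st$m),
               tolerance = 1e-12)
  expect_error(log_posterior(st, b$data, character(0)), "at least one")
  expect_error(log_posterior(st, mc_bundle(parasites = b$data$parasites), "rings"),
               "no reencounter data")
})

test_that("transforms round-trip and the compiled posterior matches R exactly", {
  set.seed(31)
  b <- make_study_like_bundle(seed = 22)
  for (i in 1:25) {
    st <- sample_prior_state()
    u <- state_to_unconstrained(st)
    back <- unconstrained_to_state(u)
    expect_equal(back$m, st$m, tolerance = 1e-12)
    expect_equal(back$par$a, st$par$a, tolerance = 1e-12)
    # every evaluated state keeps simplex rows normalized
    expect_equal(unname(rowSums(back$m)), rep(1, 8), tolerance = 1e-12)
    lp_r <- log_posterior(st, b$data) + log_jacobian(u)
    lp_c <- log_posterior_unconstrained(u, b$data)
    if (is.finite(lp_r) || is.finite(lp_c)) {
      expect_equal(lp_c, lp_r, tolerance = 1e-10)
    } else {
      expect_identical(lp_c, lp_r)
    }
    # deactivating a source removes exactly its term, compiled route too
    lp_c2 <- log_posterior_unconstrained(u, b$data, c("rings", "parasites"))
    lp_r2 <- log_posterior(st, b$data, c("rings", "parasites")) + log_jacobian(u)
    if (is.finite(lp_r2)) expect_equal(lp_c2, lp_r2, tolerance = 1e-10)
  }
})

test_that("log_jacobian matches finite-difference transform derivatives", {
  set.seed(32)
  u <- state_to_unconstrained(sample_prior_state())
  h <- 1e-6
  fd <- function(fwd, x) abs(fwd(x + h) - fwd(x - h)) / (2 * h)
  logit_idx <- c(1:38, 47:48, 49:68)   # sigmoid-transformed coordinates
  scale_idx <- c(40, 43:46, 69)        # theta (-exp) and the positive scales
  oracle <- sum(log(fd(plogis, u[logit_idx]))) +
    sum(log(fd(exp, u[scale_idx])))
  expect_equal(log_jacobian(u), oracle, tolerance = 1e-6)
})
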