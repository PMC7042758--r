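# Parameter container, the unconstrained reparameterization used by the
# sampler, and the joint prior.
#
# Unconstrained layout (length 69):
#   1..32   logit m*_{i,k}, row-major (group i fast over k = 1..4)
#   33..35  logit r_ad free (Western, Central(=Eastern), Southern)
#   36..38  logit r_juv free
#   39      mu_S_d13C (identity)
#   40      u_theta, theta = -exp(u_theta)
#   41      mu_WCE_d15N; 42 mu_S_d15N
#   43..46  log sigma: C_WCE, N_WCE, C_S, N_S
#   47      logit rho0_WCE; 48 logit rho0_S
#   49..68  logit f_nb, column-per-lineage (area fast), 4x5
#   69      log a

N_UNC <- 69L

idx_m <- function() 1:32
idx_rad <- function() 33:35
idx_rjuv <- function() 36:38
idx_iso <- function() 39:48
idx_par <- function() 49:69

log_sigmoid <- function(z) ifelse(z < 0, z - log1p(exp(z)), -log1p(exp(-z)))
sigmoid <- function(z) plogis(z)

#' Construct a full model state on the natural scale
#'
#' A model state collects the shared connectivity simplex and the
#' parameters of the three data models: the auxiliary `m_star` values in
#' (0,1) whose row-normalization gives the 8x4 connectivity matrix `m`; the
#' reporting (reencounter) probabilities per age class with the
#' Eastern = Central equality constraint (three free values each, ordered
#' Western, Central, Southern); the isotope mixture parameters (means on the
#' standardized scale, the nonpositive d13C offset `theta` of the pooled
#' WCE region, standard deviations, and correlation auxiliaries `rho0` with
#' `rho = 2 (rho0 - 0.5)`); and the parasite parameters (wintering
#' prevalences `f_nb` and the prevalence ratio `a`).
#'
#' @param m_star 8x4 matrix with entries in (0,1).
#' @param r_ad,r_juv Length-3 free reporting probabilities in (0,1),
#'   ordered (Western, Central, Southern); Eastern is tied to Central.
#' @param iso List with `mu_S_d13C`, `theta` (<= 0), `mu_WCE_d15N`,
#'   `mu_S_d15N`, `sigma_C`, `sigma_N` (each length-2, ordered (WCE,
#'   Southern), positive), `rho0` (length-2 in (0,1), ordered (WCE,
#'   Southern)).
#' @param par List with `f_nb` (4x5 in (0,1)) and `a` (> 0).
#' @return An object of class `model_state`.
#' @export
model_state <- function(m_star, r_ad, r_juv, iso, par) {
  m_star <- as.matrix(m_star)
  if (!all(dim(m_star) == c(n_groups(), n_areas()))) stop("m_star must be 8x4")
  if (any(m_star <= 0 | m_star >= 1)) stop("m_star entries must lie in (0,1)")
  chk_p <- function(x, nm, len) {
    if (length(x) != len || any(x <= 0 | x >= 1)) {
      stop(nm, " must be length ", len, " with entries in (0,1)")
    }
  }
  chk_p(r_ad, "r_ad", 3L); chk_p(r_juv, "r_juv", 3L)
  if (iso$theta > 0) stop("theta must be <= 0")
  if (any(c(iso$sigma_C, iso$sigma_N) <= 0)) stop("sigmas must be positive")
  chk_p(iso$rho0, "rho0", 2L)
  f_nb <- as.matrix(par$f_nb)
  if (!all(dim(f_nb) == c(n_areas(), n_lineages()))) stop("f_nb must be 4x5")
  if (any(f_nb <= 0 | f_nb >= 1)) stop("f_nb entries must lie in (0,1)")
  if (par$a <= 0) stop("a must be positive")
  m <- m_star / rowSums(m_star)
  dimnames(m) <- dimnames(m_star) <- list(group_labels(), area_labels())
  dimnames(f_nb) <- list(area_labels(), lineage_labels())
  structure(list(
    m = m, m_star = m_star,
    r_ad = stats::setNames(as.numeric(r_ad), c("Western", "Central", "Southern")),
    r_juv = stats::setNames(as.numeric(r_juv), c("Western", "Central", "Southern")),
    iso = list(mu_S_d13C = iso$mu_S_d13C, theta = iso$theta,
               mu_WCE_d15N = iso$mu_WCE_d15N, mu_S_d15N = iso$mu_S_d15N,
               sigma_C = stats::setNames(as.numeric(iso$sigma_C), c("WCE", "Southern")),
               sigma_N = stats::setNames(as.numeric(iso$sigma_N), c("WCE", "Southern")),
               rho0 = stats::setNames(as.numeric(iso$rho0), c("WCE", "Southern"))),
    par = list(f_nb = f_nb, a = par$a)
  ), class = "model_state")
}

#' Expand the free reporting probabilities to all four areas
#'
#' Applies the Eastern = Central equality constraint.
#' @param r_free Length-3 (Western, Central, Southern).
#' @return Named length-4 vector in area order.
#' @export
expand_r <- function(r_free) {
  stats::setNames(c(r_free[1L], r_free[2L], r_free[2L], r_free[3L]), area_labels())
}

#' Correlation from its auxiliary beta variate
#' @param rho0 Value(s) in (0,1).
#' @return `2 * (rho0 - 0.5)` in (-1, 1).
#' @export
rho_from_rho0 <- function(rho0) 2 * (rho0 - 0.5)

# ---- unconstrained <-> natural ---------------------------------------------

#' Map a model state to/from the sampler's unconstrained vector
#'
#' Probabilities and `rho0` are logit-transformed, scale parameters (`sigma`,
#' `a`) log-transformed, `theta = -exp(u)`, and means are untouched.
#' `log_jacobian()` is the log absolute determinant of the natural-from-
#' unconstrained map; the sampler targets
#' `log_posterior(state(u)) + log_jacobian(u)`.
#'
#' @param state A [model_state()].
#' @param u Numeric vector of length 69.
#' @return `state_to_unconstrained()` a length-69 vector;
#'   `unconstrained_to_state()` a `model_state`; `log_jacobian()` a scalar.
#' @export
state_to_unconstrained <- function(state) {
  u <- numeric(N_UNC)
  u[idx_m()] <- qlogis(t(state$m_star))[TRUE] # row-major: transpose then flatten
  u[idx_rad()] <- qlogis(state$r_ad)
  u[idx_rjuv()] <- qlogis(state$r_juv)
  u[39L] <- state$iso$mu_S_d13C
  u[40L] <- log(-state$iso$theta)
  u[41L] <- state$iso$mu_WCE_d15N
  u[42L] <- state$iso$mu_S_d15N
  u[43:46] <- log(c(state$iso$sigma_C[1L], state$iso$sigma_N[1L],
                    state$iso$sigma_C[2L], state$iso$sigma_N[2L]))
  u[47:48] <- qlogis(state$iso$rho0)
  u[idx_par()[1:20]] <- qlogis(as.numeric(state$par$f_nb)) # column-major 4x5
  u[69L] <- log(state$par$a)
  u
}

#' @rdname state_to_unconstrained
#' @export
unconstrained_to_state <- function(u) {
  stopifnot(length(u) == N_UNC)
  m_star <- matrix(sigmoid(u[idx_m()]), n_groups(), n_areas(), byrow = TRUE)
  model_state(
    m_star = m_star,
    r_ad = sigmoid(u[idx_rad()]),
    r_juv = sigmoid(u[idx_rjuv()]),
    iso = list(mu_S_d13C = u[39L], theta = -exp(u[40L]),
               mu_WCE_d15N = u[41L], mu_S_d15N = u[42L],
               sigma_C = exp(u[c(43L, 45L)]), sigma_N = exp(u[c(44L, 46L)]),
               rho0 = sigmoid(u[47:48])),
    par = list(f_nb = matrix(sigmoid(u[49:68]), n_areas(), n_lineages()),
               a = exp(u[69L]))
  )
}

#' @rdname state_to_unconstrained
#' @export
log_jacobian <- function(u) {
  stopifnot(length(u) == N_UNC)
  logit_idx <- c(idx_m(), idx_rad(), idx_rjuv(), 47:48, 49:68)
  log_idx <- c(40L, 43:46, 69L) # theta (via -exp) and the positive scales
  sum(log_sigmoid(u[logit_idx]) + log_sigmoid(-u[logit_idx])) + sum(u[log_idx])
}

# ---- natural-scale parameter names and reporting ---------------------------

#' Names of the reported (natural-scale) parameters
#'
#' 72 quantities: the 32 connectivity proportions, the 8 reporting
#' probabilities (Eastern duplicated from Central), the isotope means,
#' offset, sds and correlations, the 20 wintering prevalences, and `a`.
#' @return Character vector of length 72.
#' @export
param_names <- function() {
  c(paste0("m[", rep(group_labels(), each = n_areas()), ",",
           rep(area_labels(), n_groups()), "]"),
    paste0("r_ad[", area_labels(), "]"),
    paste0("r_juv[", area_labels(), "]"),
    "mu_d13C[Southern]", "theta", "mu_d13C[WCE]",
    "mu_d15N[WCE]", "mu_d15N[Southern]",
    "sigma_d13C[WCE]", "sigma_d15N[WCE]",
    "sigma_d13C[Southern]", "sigma_d15N[Southern]",
    "rho[WCE]", "rho[Southern]",
    paste0("f_nb[", rep(area_labels(), n_lineages()), ",",
           rep(lineage_labels(), each = n_areas()), "]"),
    "a")
}

#' Natural-scale reported vector for a state
#' @param state A [model_state()].
#' @return Named numeric vector matching [param_names()].
#' @export
state_to_natural <- function(state) {
  v <- c(as.numeric(t(state$m)),
         expand_r(state$r_ad), expand_r(state$r_juv),
         state$iso$mu_S_d13C, state$iso$theta,
         state$iso$mu_S_d13C + state$iso$theta,
         state$iso$mu_WCE_d15N, state$iso$mu_S_d15N,
         state$iso$sigma_C[1L], state$iso$sigma_N[1L],
         state$iso$sigma_C[2L], state$iso$sigma_N[2L],
         rho_from_rho0(state$iso$rho0),
         as.numeric(state$par$f_nb), state$par$a)
  stats::setNames(v, param_names())
}

# Vectorized conversion of a matrix of unconstrained draws (rows = draws)
unconstrained_draws_to_natural <- function(U) {
  stopifnot(ncol(U) == N_UNC)
  P <- sigmoid(U[, idx_m(), drop = FALSE])
  M <- matrix(NA_real_, nrow(U), 32L)
  for (i in seq_len(n_groups())) {
    cols <- ((i - 1L) * 4L + 1L):(i * 4L)
    M[, cols] <- P[, cols, drop = FALSE] / rowSums(P[, cols, drop = FALSE])
  }
  rad <- sigmoid(U[, idx_rad(), drop = FALSE])
  rjuv <- sigmoid(U[, idx_rjuv(), drop = FALSE])
  out <- cbind(
    M,
    rad[, 1L], rad[, 2L], rad[, 2L], rad[, 3L],
    rjuv[, 1L], rjuv[, 2L], rjuv[, 2L], rjuv[, 3L],
    U[, 39L], -exp(U[, 40L]), U[, 39L] - exp(U[, 40L]),
    U[, 41L], U[, 42L],
    exp(U[, 43L]), exp(U[, 44L]), exp(U[, 45L]), exp(U[, 46L]),
    rho_from_rho0(sigmoid(U[, 47L])), rho_from_rho0(sigmoid(U[, 48L])),
    sigmoid(U[, 49:68, drop = FALSE]), exp(U[, 69L])
  )
  colnames(out) <- param_names()
  out
}

# ---- prior -----------------------------------------------------------------

#' Joint log prior density on the natural scale
#'
#' Flat Beta(1,1) on each `m_star` and Uniform(0,1) on each reporting
#' probability and wintering prevalence (contributing zero inside the
#' support); Normal(0.97, 0.07) on the Southern-Africa mean d13C; negative
#' half-standard-normal on `theta`; standard normals on the d15N means;
#' Beta(10,4) on `rho0[Southern]` and Beta(2,4) on `rho0[WCE]`; positive
#' half-normal sd 5 on `a`; half-normal (default sd 2) on the isotope
#' standard deviations.  Returns `-Inf` outside the support.
#'
#' @param state A [model_state()].
#' @param priors A [mc_priors()].
#' @return Scalar log density (up to the flat components' normalizing
#'   constant, which is zero).
#' @export
log_prior <- function(state, priors = mc_priors()) {
  if (any(state$m_star <= 0 | state$m_star >= 1)) return(-Inf)
  if (any(c(state$r_ad, state$r_juv) <= 0 | c(state$r_ad, state$r_juv) >= 1)) return(-Inf)
  if (state$iso$theta > 0) return(-Inf)
  if (any(c(state$iso$sigma_C, state$iso$sigma_N) <= 0)) return(-Inf)
  if (any(state$iso$rho0 <= 0 | state$iso$rho0 >= 1)) return(-Inf)
  if (any(state$par$f_nb <= 0 | state$par$f_nb >= 1)) return(-Inf)
  if (state$par$a <= 0) return(-Inf)
  lp <- stats::dnorm(state$iso$mu_S_d13C, priors$mu_SC_mean, priors$mu_SC_sd, log = TRUE)
  lp <- lp + stats::dnorm(state$iso$theta, 0, priors$theta_sd, log = TRUE) + log(2)
  lp <- lp + stats::dnorm(state$iso$mu_WCE_d15N, 0, priors$mu_N_sd, log = TRUE)
  lp <- lp + stats::dnorm(state$iso$mu_S_d15N, 0, priors$mu_N_sd, log = TRUE)
  lp <- lp + sum(stats::dnorm(c(state$iso$sigma_C, state$iso$sigma_N),
                              0, priors$sigma_sd, log = TRUE)) + 4 * log(2)
  lp <- lp + stats::dbeta(state$iso$rho0["WCE"], priors$rho0_WCE_shape1,
                          priors$rho0_WCE_shape2, log = TRUE)
  lp <- lp + stats::dbeta(state$iso$rho0["Southern"], priors$rho0_S_shape1,
                          priors$rho0_S_shape2, log = TRUE)
  lp <- lp + stats::dnorm(state$par$a, 0, priors$a_sd, log = TRUE) + log(2)
  as.numeric(lp)
}

#' Draw a model state from the prior
#'
#' @param priors A [mc_priors()].
#' @return A [model_state()].
#' @export
sample_prior_state <- function(priors = mc_priors()) {
  half_norm <- function(sd) abs(stats::rnorm(1, 0, sd))
  model_state(
    m_star = matrix(stats::runif(32), n_groups(), n_areas()),
    r_ad = stats::runif(3), r_juv = stats::runif(3),
    iso = list(
      mu_S_d13C = stats::rnorm(1, priors$mu_SC_mean, priors$mu_SC_sd),
      theta = -half_norm(priors$theta_sd),
      mu_WCE_d15N = stats::rnorm(1, 0, priors$mu_N_sd),
      mu_S_d15N = stats::rnorm(1, 0, priors$mu_N_sd),
      sigma_C = c(half_norm(priors$sigma_sd), half_norm(priors$sigma_sd)),
      sigma_N = c(half_norm(priors$sigma_sd), half_norm(priors$sigma_sd)),
      rho0 = c(stats::rbeta(1, priors$rho0_WCE_shape1, priors$rho0_WCE_shape2),
               stats::rbeta(1, priors$rho0_S_shape1, priors$rho0_S_shape2))
    ),
    par = list(f_nb = matrix(stats::runif(20), n_areas(), n_lineages()),
               a = half_norm(priors$a_sd))
  )
}

#' Draw natural-scale parameter vectors from the joint prior
#'
#' Used by the identifiability diagnostics: the prior on the connectivity
#' proportions is sampled through the `m_star` construction, not assumed
#' Dirichlet.
#'
#' @param n Number of draws.
#' @param priors A [mc_priors()].
#' @return `n` x 72 matrix with [param_names()] columns.
#' @export
sample_prior <- function(n, priors = mc_priors()) {
  out <- matrix(NA_real_, n, length(param_names()),
                dimnames = list(NULL, param_names()))
  for (i in seq_len(n)) {
    out[i, ] <- state_to_natural(sample_prior_state(priors))
  }
  out
}
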