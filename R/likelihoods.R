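# The three data-source likelihoods sharing the connectivity simplex, and
# the joint log posterior.  These R implementations are the package's
# reference; the sampler uses a compiled translation that is tested for
# exact agreement against them.

log_or_neg_inf <- function(p) ifelse(p > 0, log(p), -Inf)

# multinomial log pmf with exact -Inf handling for impossible cells
dmultinom_log <- function(x, prob) {
  n <- sum(x)
  if (any(x > 0 & prob <= 0)) return(-Inf)
  pos <- x > 0
  lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(prob[pos]))
}

#' Multinomial cell probabilities for groups with known ringed totals
#'
#' `P_k = m_k * r_k` for the four wintering areas and
#' `P_5 = 1 - sum_k P_k`, the probability of never being reencountered.
#'
#' @param m_row Length-4 simplex row of connectivity proportions.
#' @param r Length-4 reporting probabilities (use [expand_r()] to apply the
#'   Eastern = Central constraint).
#' @return Length-5 probability vector summing to 1.
#' @examples
#' cell_probs_known(c(0.5, 0.5, 0, 0), rep(2e-4, 4))
#' @export
cell_probs_known <- function(m_row, r) {
  stopifnot(length(m_row) == 4L, length(r) == 4L)
  p <- m_row * r
  c(p, 1 - sum(p))
}

#' Multinomial log likelihood of one known-totals reencounter row
#'
#' @param R_row Length-5 counts (four areas plus never reencountered).
#' @param m_row,r As in [cell_probs_known()].
#' @param N Total ringed; must equal `sum(R_row)` (the default).
#' @return Log pmf; `-Inf` when a zero-probability cell holds a positive
#'   count; exactly 0 when `N == 0`.
#' @export
loglik_known <- function(R_row, m_row, r, N = sum(R_row)) {
  stopifnot(length(R_row) == 5L)
  if (sum(R_row) != N) stop("sum(R_row) must equal N")
  if (N == 0) return(0)
  dmultinom_log(R_row, cell_probs_known(m_row, r))
}

#' Conditional cell probabilities for unknown ringed totals
#'
#' With the never-reencountered cell unobservable, the four area
#' probabilities are renormalized: `Q_k = m_k r_k / sum_v m_v r_v`.
#' Under spatially equal reporting, `r` cancels and `Q = m` — the
#' non-identifiability that motivates integrating other data sources.
#'
#' @inheritParams cell_probs_known
#' @return Length-4 probability vector summing to 1.
#' @export
cond_cell_probs_unknown <- function(m_row, r) {
  stopifnot(length(m_row) == 4L, length(r) == 4L)
  p <- m_row * r
  s <- sum(p)
  if (s <= 0) stop("all cell probabilities are zero; Q is undefined")
  p / s
}

#' Multinomial log likelihood of one unknown-totals reencounter row
#'
#' The observed total `sum(R_row)` is the multinomial size; an all-zero row
#' contributes exactly 0 (no information).
#'
#' @param R_row Length-4 counts.
#' @inheritParams cell_probs_known
#' @return Log pmf.
#' @export
loglik_unknown <- function(R_row, m_row, r) {
  stopifnot(length(R_row) == 4L)
  if (sum(R_row) == 0) return(0)
  dmultinom_log(R_row, cond_cell_probs_unknown(m_row, r))
}

# log of the bivariate normal density at (x, y)
dbvnorm_log <- function(x, y, mu_x, mu_y, sigma_x, sigma_y, rho) {
  if (sigma_x <= 0 || sigma_y <= 0 || abs(rho) >= 1) {
    stop("covariance is not positive definite")
  }
  zx <- (x - mu_x) / sigma_x
  zy <- (y - mu_y) / sigma_y
  q <- (zx^2 - 2 * rho * zx * zy + zy^2) / (1 - rho^2)
  -log(2 * pi) - log(sigma_x) - log(sigma_y) - 0.5 * log(1 - rho^2) - q / 2
}

#' Isotope mixture log likelihood
#'
#' Each standardized (d13C, d15N) pair is a draw from a two-component
#' bivariate-normal mixture whose weights come from the bird's breeding
#' population's connectivity row: the pooled Western/Central/Eastern
#' component gets `m_1 + m_2 + m_3`, the Southern component `m_4`.  The
#' latent area indicator is marginalized analytically by default; passing
#' `W` (1 = WCE, 2 = Southern per individual) instead evaluates the
#' complete-data log likelihood `log P(y | W) + log P(W)`, the sampled-
#' indicator route used for cross-validation of the marginalization.
#'
#' @param data An [isotope_data()].
#' @param iso Isotope parameter list as in [model_state()].
#' @param m 8x4 connectivity matrix (rows for the three populations are
#'   used, see [population_rows()]).
#' @param W Optional integer vector of latent assignments.
#' @return Scalar log likelihood.
#' @export
isotope_loglik <- function(data, iso, m, W = NULL) {
  stopifnot(inherits(data, "isotope_data"))
  y <- data$standardized
  rho <- rho_from_rho0(iso$rho0)
  mu_WCE_C <- iso$mu_S_d13C + iso$theta
  ld_wce <- dbvnorm_log(y[, 1L], y[, 2L], mu_WCE_C, iso$mu_WCE_d15N,
                        iso$sigma_C[1L], iso$sigma_N[1L], rho[1L])
  ld_s <- dbvnorm_log(y[, 1L], y[, 2L], iso$mu_S_d13C, iso$mu_S_d15N,
                      iso$sigma_C[2L], iso$sigma_N[2L], rho[2L])
  mp <- m[population_rows(), , drop = FALSE]
  v1 <- rowSums(mp[, 1:3, drop = FALSE])[data$pop]
  v2 <- mp[, 4L][data$pop]
  if (is.null(W)) {
    # log(v1 e^a + v2 e^b) computed stably
    hi <- pmax(ld_wce, ld_s)
    return(sum(hi + log(v1 * exp(ld_wce - hi) + v2 * exp(ld_s - hi))))
  }
  stopifnot(length(W) == nrow(y), all(W %in% 1:2))
  sum(ifelse(W == 1L, ld_wce + log_or_neg_inf(v1), ld_s + log_or_neg_inf(v2)))
}

#' Breeding-population prevalences implied by the mixing equation
#'
#' `f_b[i, p] = a * sum_k f_nb[k, p] * m[i, k]` over the three breeding
#' populations' connectivity rows.
#'
#' @param f_nb 4x5 wintering-area prevalences.
#' @param a Prevalence ratio.
#' @param m 8x4 connectivity matrix.
#' @return 3x5 matrix of implied breeding prevalences.
#' @export
breeding_prevalence <- function(f_nb, a, m) {
  out <- a * (m[population_rows(), , drop = FALSE] %*% f_nb)
  dimnames(out) <- list(population_labels(), colnames(f_nb))
  out
}

#' Parasite log likelihood
#'
#' Independent binomials for every wintering-area x lineage cell with
#' prevalence `f_nb`, plus binomials for every breeding-population x
#' lineage cell at the mixed prevalence `f_b` from
#' [breeding_prevalence()].  States in which any `f_b` with a positive
#' sample size falls outside (0,1) have zero likelihood (`-Inf`), mirroring
#' automatic rejection in a BUGS-family sampler (reachable because `a` is
#' unbounded above).
#'
#' @param data A [parasite_data()].
#' @param par Parasite parameter list (`f_nb`, `a`) as in [model_state()].
#' @param m 8x4 connectivity matrix.
#' @return Scalar log likelihood.
#' @export
parasite_loglik <- function(data, par, m) {
  stopifnot(inherits(data, "parasite_data"))
  f_b <- breeding_prevalence(par$f_nb, par$a, m)
  obs <- data$H_b > 0
  if (any(obs & (f_b <= 0 | f_b >= 1))) return(-Inf)
  ll <- sum(stats::dbinom(data$G_nb, data$H_nb, par$f_nb, log = TRUE))
  ll + sum(stats::dbinom(data$G_b[obs], data$H_b[obs], f_b[obs], log = TRUE))
}

#' Joint log posterior
#'
#' Sum of [log_prior()] and the log likelihoods of the active data sources
#' (the four reencounter matrices count as the single source `"rings"`).
#' Deactivating a source removes exactly its term, which is what the
#' single-dataset contribution analysis exploits.
#'
#' @param state A [model_state()].
#' @param data An [mc_bundle()].
#' @param active Non-empty subset of `c("rings", "isotopes", "parasites")`.
#' @param priors A [mc_priors()].
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(state, data,
                          active = c("rings", "isotopes", "parasites"),
                          priors = mc_priors()) {
  if (length(active) == 0L) stop("at least one data source must be active")
  active <- match.arg(active, c("rings", "isotopes", "parasites"),
                      several.ok = TRUE)
  lp <- log_prior(state, priors)
  if (!is.finite(lp)) return(-Inf)
  if ("rings" %in% active) {
    if (is.null(data$rings)) stop("rings active but no reencounter data supplied")
    rg <- data$rings
    for (i in seq_len(n_groups())) {
      lp <- lp + loglik_known(rg$R_ad_known[i, ], state$m[i, ], expand_r(state$r_ad))
      lp <- lp + loglik_known(rg$R_juv_known[i, ], state$m[i, ], expand_r(state$r_juv))
      lp <- lp + loglik_unknown(rg$R_ad_unknown[i, ], state$m[i, ], expand_r(state$r_ad))
      lp <- lp + loglik_unknown(rg$R_juv_unknown[i, ], state$m[i, ], expand_r(state$r_juv))
    }
  }
  if ("isotopes" %in% active) {
    if (is.null(data$isotopes)) stop("isotopes active but no isotope data supplied")
    lp <- lp + isotope_loglik(data$isotopes, state$iso, state$m)
  }
  if ("parasites" %in% active) {
    if (is.null(data$parasites)) stop("parasites active but no parasite data supplied")
    lp <- lp + parasite_loglik(data$parasites, state$par, state$m)
  }
  as.numeric(lp)
}
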