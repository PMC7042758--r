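# Posterior sampling, convergence diagnostics, and summaries.

#' Sampler configuration
#'
#' Defaults mirror the study protocol: three chains of 120,000 iterations,
#' burn-in 60,000, thinning by six.  Adaptation of the per-block proposal
#' scales runs during burn-in only (batched Robbins–Monro targeting
#' `target_accept`) and is frozen afterwards, preserving chain validity.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param burn_in Discarded initial iterations (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Integer seed; every chain derives its own sub-seed from it.
#' @param init_scale Initial random-walk scale on the unconstrained scale.
#' @param adapt_batch Proposals per adaptation batch.
#' @param target_accept Acceptance-rate target in the 20--40% band.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 3L, n_iter = 120000L, burn_in = 60000L,
                           thin = 6L, seed = 1L, init_scale = 0.1,
                           adapt_batch = 50L, target_accept = 0.28) {
  stopifnot(n_chains >= 1L, burn_in < n_iter, thin >= 1L,
            init_scale > 0, target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), init_scale = init_scale,
                 adapt_batch = as.integer(adapt_batch),
                 target_accept = target_accept),
            class = "sampler_config")
}

# Deterministic per-chain sub-seed, kept within 32-bit integer range
chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) + 7919 * (chain - 1)) %% 2147483647)
}

empty_rings <- function() {
  z4 <- matrix(0L, n_groups(), n_areas())
  reencounter_data(z4, rep(0L, 8), z4, rep(0L, 8), z4, z4)
}
empty_parasites <- function() {
  z45 <- matrix(0L, n_areas(), n_lineages())
  z35 <- matrix(0L, n_pops(), n_lineages())
  parasite_data(z45, z45, z35, z35)
}

# Assemble the flat data list handed to the compiled code
cpp_data <- function(data, active) {
  rg <- if (!is.null(data$rings)) data$rings else empty_rings()
  pa <- if (!is.null(data$parasites)) data$parasites else empty_parasites()
  if (!is.null(data$isotopes)) {
    Y <- data$isotopes$standardized
    pop <- data$isotopes$pop
  } else {
    Y <- matrix(numeric(0), 0L, 2L)
    pop <- integer(0)
  }
  list(R_ad_known = rg$R_ad_known, R_juv_known = rg$R_juv_known,
       R_ad_unknown = rg$R_ad_unknown, R_juv_unknown = rg$R_juv_unknown,
       Y = Y, pop = as.integer(pop), pop_rows = as.integer(population_rows()),
       G_nb = pa$G_nb, H_nb = pa$H_nb, G_b = pa$G_b, H_b = pa$H_b)
}

active_flags <- function(sources) {
  c("rings" %in% sources, "isotopes" %in% sources, "parasites" %in% sources)
}

#' Compiled joint log posterior on the unconstrained scale
#'
#' Equals `log_posterior(unconstrained_to_state(u), ...) + log_jacobian(u)`;
#' the agreement of the two routes is part of the test suite.  With
#' `sources = character(0)` the value is the (reparameterized) log prior
#' alone, which is what prior-only runs sample.
#'
#' @param u Length-69 unconstrained vector.
#' @param data An [mc_bundle()] (entries for inactive sources may be
#'   `NULL`).
#' @param sources Subset of `c("rings", "isotopes", "parasites")`.
#' @param priors A [mc_priors()].
#' @return Scalar log density.
#' @export
log_posterior_unconstrained <- function(u, data = mc_bundle(),
                                        sources = c("rings", "isotopes", "parasites"),
                                        priors = mc_priors()) {
  lp_unconstrained_cpp(u, cpp_data(data, sources), unclass(priors),
                       active_flags(sources))
}

#' Sample the joint posterior
#'
#' Adaptive Metropolis-within-Gibbs on the unconstrained scale with block
#' updates per parameter group (each connectivity row, the two
#' reporting-probability triples, the isotope block, the parasite block).
#' Initial states are drawn from the prior and redrawn (up to 100 times)
#' until the log posterior is finite.  Runs are deterministic given
#' `(seed, config, data)`.
#'
#' @param data An [mc_bundle()]; entries for inactive sources may be `NULL`.
#' @param sources Active data sources.  `character(0)` requests a prior-only
#'   run (used by identifiability checks); [log_posterior()] itself rejects
#'   an empty active set.
#' @param config A [sampler_config()].
#' @param priors A [mc_priors()].
#' @param verbose Print acceptance summaries.
#' @return An object of class `posterior_draws`: per-chain matrices of
#'   natural-scale draws (columns [param_names()]), acceptance rates, the
#'   retained log-posterior values, and the run configuration.
#' @export
run_mcmc <- function(data = mc_bundle(),
                     sources = c("rings", "isotopes", "parasites"),
                     config = sampler_config(), priors = mc_priors(),
                     verbose = FALSE) {
  if (length(sources)) {
    sources <- match.arg(sources, c("rings", "isotopes", "parasites"),
                         several.ok = TRUE)
    if ("rings" %in% sources && is.null(data$rings)) {
      stop("rings active but no reencounter data supplied")
    }
    if ("isotopes" %in% sources && is.null(data$isotopes)) {
      stop("isotopes active but no isotope data supplied")
    }
    if ("parasites" %in% sources && is.null(data$parasites)) {
      stop("parasites active but no parasite data supplied")
    }
  }
  dl <- cpp_data(data, sources)
  act <- active_flags(sources)
  chains <- vector("list", config$n_chains)
  theta_chains <- vector("list", config$n_chains)
  accept <- matrix(NA_real_, config$n_chains, 13L)
  lps <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seed(config$seed, ch))
    u0 <- NULL
    for (try in 1:100) {
      cand <- state_to_unconstrained(sample_prior_state(priors))
      if (is.finite(lp_unconstrained_cpp(cand, dl, unclass(priors), act))) {
        u0 <- cand
        break
      }
    }
    if (is.null(u0)) stop("no finite starting point found after 100 prior draws")
    res <- run_chain_cpp(u0, config$n_iter, config$burn_in, config$thin,
                         dl, unclass(priors), act, config$init_scale,
                         config$adapt_batch, config$target_accept)
    chains[[ch]] <- unconstrained_draws_to_natural(res$draws)
    theta_chains[[ch]] <- NULL
    accept[ch, ] <- res$accept
    lps[[ch]] <- res$lp
    if (verbose) {
      message(sprintf("chain %d: acceptance %.2f-%.2f", ch,
                      min(res$accept), max(res$accept)))
    }
  }
  colnames(accept) <- c(paste0("m_row_", seq_len(8L)), "r_ad", "r_juv",
                        "isotope", "parasite", "joint")
  structure(list(chains = chains, accept = accept, lp = lps,
                 config = config, priors = priors, sources = sources,
                 param_names = param_names()),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chains x", nrow(x$chains[[1L]]),
      "retained draws x", length(x$param_names), "parameters\n")
  cat("  sources:", if (length(x$sources)) paste(x$sources, collapse = ", ")
      else "(prior only)", "\n")
  cat("  mean acceptance:", sprintf("%.2f", mean(x$accept, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Stack all chains into one draws matrix
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return Matrix with one column per parameter.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Brooks–Gelman–Rubin potential scale reduction factor
#'
#' Computed from between- and within-chain variances:
#' `R-hat = sqrt(((n-1)/n + B/(n W)))` with `B/n` the variance of the chain
#' means and `W` the mean within-chain variance.  Identical chains give
#' exactly `sqrt((n-1)/n)`; values well above 1.1 flag non-convergence.
#'
#' @param draws A `posterior_draws` object or a list of equal-length
#'   numeric vectors (one per chain).
#' @param parameter Optional parameter name(s); default all.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(draws, parameter = NULL) {
  if (inherits(draws, "posterior_draws")) {
    if (length(draws$chains) < 2L) stop("need at least 2 chains")
    pars <- if (is.null(parameter)) draws$param_names else parameter
    bad <- setdiff(pars, draws$param_names)
    if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
    out <- vapply(pars, function(p) {
      gelman_rubin(lapply(draws$chains, function(ch) ch[, p]))
    }, numeric(1))
    return(out)
  }
  chains <- draws
  m <- length(chains)
  if (m < 2L) stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L || n < 2L) stop("chains must share a length of at least 2")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (W == 0) return(if (B_over_n == 0) sqrt((n - 1) / n) else Inf)
  sqrt((n - 1) / n + B_over_n / W)
}

#' Posterior summary table
#'
#' Mean, standard deviation and the central 95% credible interval for every
#' parameter, pooled over chains.
#'
#' @param draws A `posterior_draws` object.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `median`, `q97.5`.
#' @export
summarize_draws <- function(draws) {
  X <- as.matrix(draws)
  qs <- t(apply(X, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE))
  data.frame(parameter = colnames(X), mean = colMeans(X),
             sd = apply(X, 2, stats::sd),
             q2.5 = qs[, 1L], median = qs[, 2L], q97.5 = qs[, 3L],
             row.names = NULL)
}

#' @export
summary.posterior_draws <- function(object, ...) summarize_draws(object)

#' Write or read retained draws as CSV
#'
#' The CSV carries `chain` and `iteration` columns followed by one column
#' per parameter, so external tools (and [read_draws()]) can rebuild the
#' chain structure.
#'
#' @param draws A `posterior_draws` object.
#' @param path Output file.
#' @return `write_draws()` the path invisibly; `read_draws()` a
#'   `posterior_draws`-like object (chains and parameter names only).
#' @export
write_draws <- function(draws, path) {
  tabs <- lapply(seq_along(draws$chains), function(ch) {
    data.frame(chain = ch, iteration = seq_len(nrow(draws$chains[[ch]])),
               draws$chains[[ch]], check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("chain", "iteration") %in% names(df))) {
    stop(path, ": missing chain/iteration columns")
  }
  pars <- setdiff(names(df), c("chain", "iteration"))
  chains <- lapply(sort(unique(df$chain)), function(ch) {
    as.matrix(df[df$chain == ch, pars, drop = FALSE])
  })
  structure(list(chains = chains, accept = NULL, lp = NULL, config = NULL,
                 priors = NULL, sources = NULL, param_names = pars),
            class = "posterior_draws")
}
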