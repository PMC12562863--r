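# Gaussian mixture with known per-observation variances.
#
# The consensus-locus model: projected QTL positions x_i on one chromosome
# are draws from K Gaussian components centred on the (unknown) consensus
# positions mu_k, with per-observation standard deviations s_i fixed at the
# values derived from each QTL's projected 95% CI. Only the K means and the
# K-1 free mixing proportions are estimated, so the free-parameter count is
# p = 2K - 1.

# One EM run from a given mean initialization. Returns means/weights/
# responsibilities/loglik trace. log-sum-exp throughout.
.em_run <- function(x, s, K, mu0, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  mu <- mu0
  pi_k <- rep(1 / K, K)
  w <- 1 / s^2
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  logphi <- function(mu) {
    # n x K matrix of log N(x_i; mu_k, s_i^2)
    matrix(vapply(mu, function(m) stats::dnorm(x, m, s, log = TRUE),
                  numeric(n)), nrow = n, ncol = K)
  }
  r <- matrix(1 / K, n, K)
  for (iter in seq_len(max_iter)) {
    lp <- logphi(mu)
    lj <- sweep(lp, 2, log(pmax(pi_k, 1e-300)), "+")
    m <- apply(lj, 1, max)
    lse <- m + log(rowSums(exp(lj - m)))
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    r <- exp(lj - lse)
    # M-step: precision-weighted means, mean responsibilities
    denom <- colSums(r * w)
    num <- colSums(r * w * x)
    upd <- denom > 0
    mu[upd] <- num[upd] / denom[upd]
    pi_k <- colMeans(r)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(means = mu, weights = pi_k, responsibilities = r,
       loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, converged = converged)
}

#' Fit a K-component consensus-position mixture by EM
#'
#' Maximizes `sum_i log sum_k pi_k N(x_i; mu_k, s_i^2)` over the component
#' means and mixing proportions, with the per-observation variances fixed.
#' The E step computes responsibilities `r_ik`; the M step sets each mean to
#' the precision-weighted average of its soft members and each weight to the
#' mean responsibility. The first run starts from the weighted
#' `k/(K+1)`-quantiles of `x` (weights `1/s^2`); `n_restarts` further runs
#' start from seeded jitters of that initialization, and the best run by
#' log-likelihood is returned.
#'
#' @param x Projected positions (cM).
#' @param s Per-observation standard deviations (cM), > 0.
#' @param K Number of components, `1 <= K <= length(x)`.
#' @param seed Integer seed for the jittered restarts.
#' @param n_restarts Number of jittered restarts beyond the deterministic one.
#' @param max_iter,tol EM stopping rule: stop at `|delta loglik| < tol` or
#'   after `max_iter` iterations.
#' @param s_floor Lower clamp on `s` (cM), guarding against singular
#'   likelihoods from zero-width intervals.
#' @return Object of class `mixture_fit`: `K`, sorted `means`, `weights`,
#'   `loglik`, `loglik_trace`, `responsibilities`, `n_obs`, `converged`,
#'   `degenerate` (an empty component at convergence), `n_restarts_used`.
#' @export
fit_mixture <- function(x, s, K, seed = 1L, n_restarts = 10L,
                        max_iter = 500L, tol = 1e-8, s_floor = 0.01) {
  n <- length(x)
  stopifnot(length(s) == n)
  if (K > n) stop("K (", K, ") exceeds the number of observations (", n, ")")
  if (K < 1) stop("K must be >= 1")
  if (any(s <= 0)) stop("all s must be > 0")
  n_clamped <- sum(s < s_floor)
  if (n_clamped > 0) {
    message(n_clamped, " observation sd value(s) clamped to the ", s_floor,
            " cM floor")
  }
  s <- pmax(s, s_floor)
  w <- 1 / s^2

  base_mu <- weighted_quantile(x, w, seq_len(K) / (K + 1))
  jitter_scale <- if (n > 1) max(stats::sd(x), 1e-3) else 1e-3

  set.seed(seed)
  inits <- c(list(base_mu),
             lapply(seq_len(n_restarts),
                    function(r) base_mu + stats::rnorm(K, 0, jitter_scale)))
  best <- NULL
  for (mu0 in inits) {
    run <- .em_run(x, s, K, mu0, max_iter = max_iter, tol = tol)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  ord <- order(best$means)
  means <- best$means[ord]
  weights <- best$weights[ord]
  resp <- best$responsibilities[, ord, drop = FALSE]
  hard <- max.col(resp, ties.method = "first")
  degenerate <- length(unique(hard)) < K

  structure(list(
    K = as.integer(K), means = means, weights = weights,
    loglik = best$loglik, loglik_trace = best$loglik_trace,
    responsibilities = resp, x = x, s = s, n_obs = n,
    converged = best$converged, degenerate = degenerate,
    n_restarts_used = length(inits) - 1L
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian mixture fit (known per-observation variances)\n")
  cat("  K =", x$K, " n =", x$n_obs, " loglik =", format(x$loglik), "\n")
  cat("  means (cM):", paste(format(x$means, digits = 4), collapse = ", "), "\n")
  cat("  weights:   ", paste(format(x$weights, digits = 3), collapse = ", "), "\n")
  if (x$degenerate) cat("  [degenerate: empty component]\n")
  invisible(x)
}

#' Information criteria for a mixture fit
#'
#' With `p = 2K - 1` free parameters (K means, K-1 weights; variances are
#' known) and `n` observations: `AIC = -2l + 2p`;
#' `AICc = AIC + 2p(p+1)/(n-p-1)` (infinite when `n <= p+1`);
#' `AIC3 = -2l + 3p`; `BIC = -2l + p log n`; and
#' `AWE = -2l_c + 2p(3/2 + log n)`, where `l_c` is the classification
#' log-likelihood (the complete-data log-likelihood at the hard MAP
#' assignments, following the Banfield-Raftery convention).
#'
#' @param fit A `mixture_fit`.
#' @return Named numeric vector `AIC`, `AICc`, `AIC3`, `BIC`, `AWE`.
#' @export
information_criteria <- function(fit) {
  K <- fit$K
  n <- fit$n_obs
  p <- 2 * K - 1
  ll <- fit$loglik
  hard <- max.col(fit$responsibilities, ties.method = "first")
  ll_c <- sum(log(pmax(fit$weights[hard], 1e-300)) +
                stats::dnorm(fit$x, fit$means[hard], fit$s, log = TRUE))
  aic <- -2 * ll + 2 * p
  aicc <- if (n > p + 1) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
  c(AIC = aic, AICc = aicc, AIC3 = -2 * ll + 3 * p,
    BIC = -2 * ll + p * log(n), AWE = -2 * ll_c + 2 * p * (3 / 2 + log(n)))
}

#' Select the number of consensus loci by an information criterion
#'
#' @param fits List of `mixture_fit` objects for K = 1..K_max on one
#'   chromosome.
#' @param criterion One of `"AIC"` (default), `"AICc"`, `"AIC3"`, `"BIC"`,
#'   `"AWE"`.
#' @param chromosome Chromosome label used in error messages.
#' @return The selected `mixture_fit` (minimum criterion; ties break toward
#'   smaller K; degenerate fits are excluded).
#' @export
select_model <- function(fits, criterion = "AIC", chromosome = "?") {
  criterion <- match.arg(criterion, c("AIC", "AICc", "AIC3", "BIC", "AWE"))
  ok <- !vapply(fits, function(f) isTRUE(f$degenerate), logical(1))
  if (!any(ok)) {
    stop("all mixture fits degenerate on chromosome ", chromosome)
  }
  fits <- fits[ok]
  Ks <- vapply(fits, function(f) f$K, integer(1))
  fits <- fits[order(Ks)]
  crit <- vapply(fits, function(f) information_criteria(f)[[criterion]],
                 numeric(1))
  fits[[which.min(crit)]]
}

#' Build MQTLs from a selected mixture fit
#'
#' Each QTL is hard-assigned to its maximum-responsibility component (ties
#' toward the lower-indexed component). Per non-empty component:
#' consensus position = fitted mean; consensus sd =
#' `sqrt(1 / sum_i 1/s_i^2)` over hard members; 95% CI = mean +/- 1.96 sd.
#' MQTLs are numbered `MQTL<chrom>.<index>` in ascending position.
#'
#' @param fit Selected `mixture_fit`.
#' @param projected Projected catalog rows (same order as the positions the
#'   fit was run on) supplying `qtl_id` and `trait`.
#' @param chromosome Chromosome id.
#' @return List with `mqtls` (tibble) and `assignments`
#'   (tibble `qtl_id` -> `mqtl_id`).
#' @export
build_mqtls <- function(fit, projected, chromosome) {
  hard <- max.col(fit$responsibilities, ties.method = "first")
  comp_ids <- sort(unique(hard))
  ord <- comp_ids[order(fit$means[comp_ids])]
  rows <- list()
  assign_mqtl <- rep(NA_character_, length(hard))
  for (idx in seq_along(ord)) {
    k <- ord[idx]
    members <- which(hard == k)
    sd_k <- sqrt(1 / sum(1 / fit$s[members]^2))
    id <- paste0("MQTL", chromosome, ".", idx)
    assign_mqtl[members] <- id
    rows[[idx]] <- tibble::tibble(
      mqtl_id = id,
      chromosome = chromosome,
      consensus_cm = fit$means[k],
      sd_cm = sd_k,
      ci95_lower_cm = fit$means[k] - 1.96 * sd_k,
      ci95_upper_cm = fit$means[k] + 1.96 * sd_k,
      n_initial_qtls = length(members),
      member_qtl_ids = paste(projected$qtl_id[members], collapse = ","),
      traits = paste(sort(unique(projected$trait[members])), collapse = ",")
    )
  }
  list(
    mqtls = dplyr::bind_rows(rows),
    assignments = tibble::tibble(qtl_id = projected$qtl_id,
                                 mqtl_id = assign_mqtl)
  )
}

#' Per-chromosome meta-analysis of a projected QTL catalog
#'
#' For every chromosome carrying projected QTLs: fit the mixture for
#' K = 1..K_max, select K by the chosen criterion, and build the MQTLs.
#' A chromosome with a single projected QTL yields a single (flagged) MQTL
#' with K = 1 forced. Deterministic given `seed`; invariant to the input
#' row order.
#'
#' @param projected Output of [project_qtl_catalog()]; only rows with
#'   `status == "projected"` are used.
#' @param K_max Maximum K per chromosome; default `min(n_obs, 10)`.
#' @param criterion Model-selection criterion (default `"AIC"`).
#' @param seed Root seed; per-chromosome seeds are derived from it.
#' @param n_restarts Jittered EM restarts per fit.
#' @return List: `mqtls` (tibble over all chromosomes), `assignments`,
#'   `diagnostics` (per chromosome and K: loglik and the five criteria,
#'   selection and degeneracy flags).
#' @export
run_meta_analysis <- function(projected, K_max = NULL, criterion = "AIC",
                              seed = 1L, n_restarts = 10L) {
  proj <- projected[projected$status == "projected", ]
  proj <- proj[order(proj$chromosome, proj$ref_peak_cm, proj$qtl_id), ]
  chroms <- sort(unique(proj$chromosome))
  all_mqtls <- list()
  all_assign <- list()
  diags <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    rows <- proj[proj$chromosome == chrom, ]
    x <- rows$ref_peak_cm
    s <- rows$position_sd_cm
    n <- length(x)
    kmax <- if (is.null(K_max)) min(n, 10L) else min(K_max, n)
    chrom_seed <- derive_seed(seed, ci)
    fits <- lapply(seq_len(kmax), function(K) {
      fit_mixture(x, s, K, seed = derive_seed(chrom_seed, K),
                  n_restarts = n_restarts)
    })
    diags[[ci]] <- dplyr::bind_rows(lapply(fits, function(f) {
      crit <- information_criteria(f)
      tibble::tibble(chromosome = chrom, K = f$K, loglik = f$loglik,
                     AIC = crit[["AIC"]], AICc = crit[["AICc"]],
                     AIC3 = crit[["AIC3"]], BIC = crit[["BIC"]],
                     AWE = crit[["AWE"]], degenerate = f$degenerate,
                     converged = f$converged)
    }))
    if (n == 1) {
      chosen <- fits[[1]]
      forced <- TRUE
    } else {
      chosen <- select_model(fits, criterion = criterion, chromosome = chrom)
      forced <- FALSE
    }
    diags[[ci]]$selected <- diags[[ci]]$K == chosen$K
    diags[[ci]]$k_forced <- forced
    built <- build_mqtls(chosen, rows, chrom)
    built$mqtls$k_forced <- forced
    all_mqtls[[ci]] <- built$mqtls
    all_assign[[ci]] <- built$assignments
  }
  list(mqtls = dplyr::bind_rows(all_mqtls),
       assignments = dplyr::bind_rows(all_assign),
       diagnostics = dplyr::bind_rows(diags))
}
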