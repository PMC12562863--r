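test_that("K = 1 EM equals the inverse-variance weighted mean in closed form", {
  # hand evaluation: (0/1 + 10/4) / (1 + 1/4) = 2
  fit <- fit_mixture(c(0, 10), c(1, 2), K = 1)
  expect_equal(fit$means, 2.0, tolerance = 1e-9)
  # symmetric case
  expect_equal(fit_mixture(c(0, 10), c(1, 1), K = 1)$means, 5.0,
               tolerance = 1e-9)
  # property: matches the closed form on random instances to 1e-9
  for (seed in 1:20) {
    set.seed(seed)
    x <- rnorm(sample(3:12, 1), 50, 10)
    s <- runif(length(x), 0.5, 4)
    fit <- fit_mixture(x, s, K = 1, seed = seed)
    expect_equal(fit$means, sum(x / s^2) / sum(1 / s^2), tolerance = 1e-9)
  }
})

test_that("EM log-likelihood is monotone and saturated fits dominate", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:15, 1)
    x <- c(rnorm(ceiling(n / 2), 20, 2), rnorm(floor(n / 2), 60, 2))
    s <- runif(n, 0.5, 4)
    K <- sample(1:3, 1)
    fit <- fit_mixture(x, s, K, seed = seed, n_restarts = 2)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
  # nested dominance: more components never fit worse
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(8, 30, 5)
    s <- runif(8, 1, 3)
    f1 <- fit_mixture(x, s, 1, seed = seed)
    f2 <- fit_mixture(x, s, 2, seed = seed)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
  }
  # K = n with tiny s: means sit on the data
  x <- c(10, 20, 30)
  fit <- fit_mixture(x, rep(0.05, 3), K = 3, seed = 1)
  expect_equal(fit$means, x, tolerance = 1e-3)
  expect_error(fit_mixture(x, rep(1, 3), K = 4), "exceeds")
})

test_that("EM attains the grid-search optimum for small n and K <= 2", {
  # independent oracle: exhaustive search over means on a 0.01 cM lattice
  # and mixing proportion on a 0.01 lattice
  grid_best <- function(x, s, K) {
    mu_grid <- seq(min(x), max(x), by = 0.01)
    phi <- vapply(mu_grid, function(m) dnorm(x, m, s), numeric(length(x)))
    if (K == 1) return(max(colSums(log(phi))))
    best <- -Inf
    for (p in seq(0.01, 0.99, by = 0.01)) {
      # loglik for all (mu1, mu2) pairs at mixing proportion p
      ll <- matrix(0, length(mu_grid), length(mu_grid))
      for (i in seq_along(x)) {
        ll <- ll + log(outer(p * phi[i, ], (1 - p) * phi[i, ], "+"))
      }
      best <- max(best, max(ll))
    }
    best
  }
  cases <- list(
    list(x = c(0.2, 0.9, 2.1, 2.6), s = c(0.3, 0.4, 0.3, 0.5)),
    list(x = c(1.0, 1.2, 3.0, 3.3, 3.1), s = rep(0.25, 5)),
    list(x = c(0.5, 1.5, 2.5), s = c(0.6, 0.6, 0.6)))
  for (cs in cases) {
    for (K in 1:2) {
      fit <- fit_mixture(cs$x, cs$s, K, seed = 11)
      expect_gte(fit$loglik, grid_best(cs$x, cs$s, K) - 1e-4)
    }
  }
})

test_that("information criteria follow their formulas with p = 2K - 1", {
  set.seed(3)
  x <- rnorm(10, 50, 3)
  s <- runif(10, 1, 2)
  f1 <- fit_mixture(x, s, 1, seed = 1)
  crit <- information_criteria(f1)
  expect_equal(crit[["AIC"]], -2 * f1$loglik + 2)
  expect_equal(crit[["BIC"]], -2 * f1$loglik + log(10))
  # AIC3 - AIC = p for any fit
  f2 <- fit_mixture(x, s, 2, seed = 1)
  for (f in list(f1, f2)) {
    cr <- information_criteria(f)
    expect_equal(cr[["AIC3"]] - cr[["AIC"]], 2 * f$K - 1)
  }
  # AICc blows up when n <= p + 1
  f_sat <- fit_mixture(x[1:3], s[1:3], 3, seed = 1)
  expect_true(is.infinite(information_criteria(f_sat)[["AICc"]]))
  # K = 1: classification and mixture loglik coincide, so
  # AWE = -2l + 2p(3/2 + log n)
  expect_equal(crit[["AWE"]], -2 * f1$loglik + 2 * (3 / 2 + log(10)))
})

test_that("model selection picks the supported K and breaks ties downward", {
  # single tight cluster -> K = 1
  set.seed(101)
  x <- rnorm(12, 50, 0.5)
  s <- rep(0.5, 12)
  fits <- lapply(1:4, function(K) fit_mixture(x, s, K, seed = K))
  expect_equal(select_model(fits)$K, 1L)

  # two clusters 40 cM apart -> K = 2
  set.seed(102)
  x <- c(rnorm(10, 30, 1), rnorm(10, 70, 1))
  s <- rep(1, 20)
  fits <- lapply(1:5, function(K) fit_mixture(x, s, K, seed = K))
  expect_equal(select_model(fits)$K, 2L)

  # exact criterion ties resolve toward smaller K: AIC = -2l + 2(2K - 1)
  # is equal for the two fits when the K = 3 fit gains exactly 2 loglik
  fa <- fit_mixture(x, s, 2, seed = 1)
  fb <- fa
  fb$K <- 3L
  fb$loglik <- fa$loglik + 2
  expect_equal(select_model(list(fa, fb))$K, 2L)

  # all-degenerate input errors with the chromosome name
  fd <- fa
  fd$degenerate <- TRUE
  expect_error(select_model(list(fd), chromosome = "7"), "7")
})

test_that("MQTL construction uses hard members, precision-pooled sd and 1.96 CIs", {
  proj <- tibble::tibble(qtl_id = c("a", "b", "c"),
                         trait = c("PH", "RPR", "PH"))
  # single member with s = 1: sd = 1, CI width = 3.92
  f <- fit_mixture(c(10), c(1), K = 1)
  b <- build_mqtls(f, proj[1, ], "3")
  expect_equal(b$mqtls$sd_cm, 1)
  expect_equal(b$mqtls$ci95_upper_cm - b$mqtls$ci95_lower_cm, 3.92)
  expect_equal(b$mqtls$ci95_upper_cm,
               b$mqtls$consensus_cm + 1.96 * b$mqtls$sd_cm, tolerance = 1e-9)

  # two members with s = (1, 1): sd = 1/sqrt(2)
  f <- fit_mixture(c(10, 10.2), c(1, 1), K = 1)
  b <- build_mqtls(f, proj[1:2, ], "3")
  expect_equal(b$mqtls$sd_cm, 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(b$mqtls$n_initial_qtls, 2L)
  # traits are the union of member traits
  expect_equal(b$mqtls$traits, "PH,RPR")
  # ids are numbered by chromosome and ascending position
  expect_equal(b$mqtls$mqtl_id, "MQTL3.1")
})

test_that("meta-analysis recovers planted loci and ignores input order", {
  sim <- simulate_mixture_instance(seed = 5)
  proj <- tibble::tibble(
    qtl_id = sprintf("Q%03d", seq_along(sim$x)), trait = "PH",
    chromosome = "1", status = "projected",
    ref_peak_cm = sim$x, position_sd_cm = sim$s)
  res <- run_meta_analysis(proj, seed = 9)
  expect_equal(nrow(res$mqtls), length(sim$mu_true))
  expect_lt(max(abs(sort(res$mqtls$consensus_cm) - sim$mu_true)), 1.5)
  # members map back to their generating locus
  ord <- order(res$mqtls$consensus_cm)
  lookup <- setNames(seq_along(ord), res$mqtls$mqtl_id[ord])
  got_z <- lookup[res$assignments$mqtl_id[match(proj$qtl_id,
                                                res$assignments$qtl_id)]]
  expect_gte(mean(got_z == sim$z_true), 0.9)

  # permuting the input rows leaves the MQTLs unchanged
  perm <- proj[sample(nrow(proj)), ]
  res2 <- run_meta_analysis(perm, seed = 9)
  expect_equal(res2$mqtls, res$mqtls)

  # a single-QTL chromosome yields one flagged MQTL without model selection
  single <- proj[1, ]
  single$chromosome <- "9"
  res3 <- run_meta_analysis(dplyr::bind_rows(proj, single), seed = 9)
  m9 <- res3$mqtls[res3$mqtls$chromosome == "9", ]
  expect_equal(nrow(m9), 1)
  expect_true(m9$k_forced)
  expect_equal(m9$n_initial_qtls, 1L)
})
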