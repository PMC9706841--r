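make_hmm_par <- function(fit) {
  list(shape = fit$shape, scale = fit$scale, mu = fit$mu, kappa = fit$kappa,
       trans = fit$transition)
}

test_that("forward likelihood equals the brute-force path sum on short tracks", {
  set.seed(41)
  for (K in 2:3) {
    states <- lapply(seq_len(K), function(k)
      list(shape = 2, scale = 100 * 3^(k - 1), mu = 0, kappa = 0.5 * k))
    G <- matrix(0.1 / (K - 1), K, K); diag(G) <- 0.9
    sim <- simulate_hmm_track(states, G, n_steps = 10, seed = 40 + K)
    fit <- fit_hmm(data.frame(sl = sim$sl, ta = sim$ta),
                   list(n_states = K, shape0 = rep(2, K),
                        scale0 = 100 * 3^(seq_len(K) - 1), mu0 = rep(0, K),
                        kappa0 = rep(0.5, K), label = "t"),
                   max_iter = 5, seed = 1)
    dens <- bearmove:::hmm_dens(fit$sl, fit$ta, make_hmm_par(fit))
    ll_fast <- hmm_loglik(fit)
    ll_slow <- brute_forward(dens, fit$transition, as.numeric(fit$delta))
    expect_equal(ll_fast, ll_slow, tolerance = 1e-8)
  }
})

test_that("Viterbi equals the exhaustive argmax on short tracks", {
  set.seed(43)
  states <- list(list(shape = 2, scale = 80, mu = 0, kappa = 0.3),
                 list(shape = 2, scale = 900, mu = 0, kappa = 1.5))
  G <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  sim <- simulate_hmm_track(states, G, n_steps = 10, seed = 44)
  fit <- fit_hmm(data.frame(sl = sim$sl, ta = sim$ta),
                 list(n_states = 2, shape0 = c(2, 2), scale0 = c(80, 900),
                      mu0 = c(0, 0), kappa0 = c(0.3, 1.5), label = "t"),
                 max_iter = 30, seed = 2)
  dens <- bearmove:::hmm_dens(fit$sl, fit$ta, make_hmm_par(fit))
  expect_equal(viterbi(fit), brute_viterbi(dens, fit$transition,
                                           as.numeric(fit$delta)))
})

test_that("one-state fit recovers gamma parameters within 3 SE", {
  set.seed(45)
  n <- 2000
  sl <- rgamma(n, shape = 2, scale = 300)
  fit <- fit_hmm(data.frame(sl = sl, ta = runif(n, -pi, pi)),
                 list(n_states = 1, shape0 = 1.5, scale0 = 400, mu0 = 0,
                      kappa0 = 0.1, label = "1s"), seed = 3)
  # asymptotic SE of the gamma shape MLE
  se_shape <- sqrt(1 / (n * (trigamma(2) - 1 / 2)))
  expect_lt(abs(fit$shape - 2), 3 * se_shape)
  expect_lt(abs(fit$shape * fit$scale - 600), 3 * 600 / sqrt(n))
  expect_true(all(viterbi(fit) == 1))
})

test_that("richer state spaces never lose likelihood (nesting)", {
  states <- list(list(shape = 2, scale = 60, mu = 0, kappa = 0.3),
                 list(shape = 2, scale = 700, mu = 0, kappa = 1.5))
  G <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  sim <- simulate_hmm_track(states, G, n_steps = 500, seed = 46)
  d <- data.frame(sl = sim$sl, ta = sim$ta)
  f1 <- fit_hmm(d, list(n_states = 1, shape0 = 2, scale0 = 300, mu0 = 0,
                        kappa0 = 0.5, label = "1s"), seed = 4)
  f2 <- fit_hmm(d, list(n_states = 2, shape0 = c(2, 2), scale0 = c(60, 700),
                        mu0 = c(0, 0), kappa0 = c(0.3, 1.5), label = "2s"), seed = 4)
  expect_gte(f2$log_likelihood, f1$log_likelihood)
  # and AIC prefers the 2-state model on well-separated data
  expect_lt(f2$aic, f1$aic)
})

test_that("AIC ordering is invariant to a constant likelihood shift", {
  aic <- function(ll, k) 2 * k - 2 * ll
  ll <- c(-100, -90, -95); k <- c(4, 10, 6)
  expect_equal(order(aic(ll, k)), order(aic(ll - 1234, k)))
})

test_that("model selection prefers parsimony on single-state data", {
  set.seed(47)
  wins <- 0L
  for (r in 1:8) {
    sl <- rgamma(400, shape = 2, scale = 250)
    d <- data.frame(sl = sl, ta = runif(400, -pi, pi))
    specs <- list(
      list(n_states = 1, shape0 = 2, scale0 = 250, mu0 = 0, kappa0 = 0.1,
           label = "1s"),
      list(n_states = 2, shape0 = c(2, 2), scale0 = c(150, 400),
           mu0 = c(0, 0), kappa0 = c(0.1, 0.1), label = "2s"))
    best <- suppressWarnings(select_hmm(d, specs, seed = r))
    if (best$n_states == 1) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("well-separated two-state data is recovered by the candidate set", {
  states <- list(list(shape = 2, scale = 50, mu = 0, kappa = 0.3),
                 list(shape = 2, scale = 750, mu = 0, kappa = 2))
  G <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  sim <- simulate_hmm_track(states, G, n_steps = 1000, seed = 48)
  best <- suppressWarnings(select_hmm(data.frame(sl = sim$sl, ta = sim$ta), seed = 5))
  expect_gte(best$n_states, 2)
})

test_that("dispersal window delineation follows the merge-and-threshold rule", {
  h <- 3600
  t0 <- as.POSIXct("2015-05-01 00:00:00", tz = "UTC")
  # all transit: window spans the full track
  n <- 300
  tt <- t0 + h * (0:(n - 1))
  w <- delineate_dispersal(rep(2L, n), tt, transit_state = 2)
  expect_equal(w$onset, tt[1]); expect_equal(w$end, tt[n])
  # 30-day and 3-day transit runs separated by 10 encamped days: long run wins
  st <- c(rep(2L, 30 * 24), rep(1L, 10 * 24), rep(2L, 3 * 24))
  tt2 <- t0 + h * (seq_along(st) - 1)
  w2 <- delineate_dispersal(st, tt2, transit_state = 2)
  expect_equal(w2$onset, tt2[1])
  expect_equal(w2$end, tt2[30 * 24])
  # short gaps (<= 48 h) are merged into one window
  st3 <- c(rep(2L, 10 * 24), rep(1L, 24), rep(2L, 10 * 24))
  tt3 <- t0 + h * (seq_along(st3) - 1)
  w3 <- delineate_dispersal(st3, tt3, transit_state = 2)
  expect_equal(as.numeric(difftime(w3$end, w3$onset, units = "days")),
               21, tolerance = 0.05)
  # no transit state: no dispersal
  expect_null(delineate_dispersal(rep(1L, 100), t0 + h * (0:99), transit_state = 2))
})
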