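test_that("step construction counts steps and turning angles correctly", {
  # 4 contiguous hourly fixes: 3 steps, 2 with a turning angle
  tr <- make_track(c(0, 100, 250, 300), c(0, 0, 50, 120))
  st <- build_steps(tr)
  expect_equal(nrow(st), 3)
  expect_equal(sum(!is.na(st$ta)), 2)

  # a bed fix in the middle breaks the strata
  tr2 <- make_track(c(0, 100, 200, 300, 400), c(0, 0, 0, 0, 0))
  tr2$bed_site <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  st2 <- build_steps(tr2)
  expect_equal(nrow(st2), 2)          # 1-2 and 4-5 only
  expect_true(all(is.na(st2$ta)))     # neither has a contiguous previous step

  # collinear eastward fixes: TA = 0, cos TA = 1
  tr3 <- make_track(c(0, 100, 200, 300), c(0, 0, 0, 0))
  st3 <- build_steps(tr3)
  expect_equal(st3$ta[2:3], c(0, 0))
  expect_equal(cos(st3$ta[2:3]), c(1, 1))
})

test_that("tentative gamma MLE recovers parameters and is scale equivariant", {
  set.seed(71)
  sl <- rgamma(5000, shape = 2, scale = 300)
  k <- fit_tentative_gamma(sl)
  expect_lt(abs(k$shape - 2), 0.12)
  expect_lt(abs(k$scale - 300), 25)
  # MLE close to method of moments at large n
  mom_shape <- mean(sl)^2 / var(sl)
  expect_lt(abs(k$shape - mom_shape) / mom_shape, 0.05)
  # scale equivariance
  k2 <- fit_tentative_gamma(2 * sl)
  expect_equal(k2$scale, 2 * k$scale, tolerance = 1e-6)
  expect_equal(k2$shape, k$shape, tolerance = 1e-6)
  # degenerate input
  expect_error(fit_tentative_gamma(rep(100, 50)), "degenerate|constant")
})

test_that("available-step generation produces exact 20:1 strata", {
  set.seed(72)
  tr <- make_track(cumsum(c(0, rgamma(101, 2, scale = 200))),
                   cumsum(c(0, rnorm(101, 0, 150))))
  st <- build_steps(tr)
  k <- gamma_kernel(2, 200)
  ss <- generate_available_steps(st[1:101, ], k, ratio = 20, seed = 3)
  n_strata <- length(unique(ss$stratum))
  expect_equal(nrow(ss), n_strata * 21)
  expect_true(all(tapply(ss$case, ss$stratum, sum) == 1))
  expect_true(all(table(ss$stratum) == 21))

  # available turning angles uniform; step lengths match the kernel mean
  av <- ss[ss$case == 0, ]
  chi <- suppressWarnings(chisq.test(table(cut(av$ta, seq(-pi, pi, length.out = 9)))))
  expect_gt(chi$p.value, 0.01)
  se <- sqrt(2) * 200 / sqrt(nrow(av))
  expect_lt(abs(mean(av$sl) - 400), 3 * se)
})

test_that("conditional logit solves the hand-derived score equation", {
  # two strata, one binary covariate:
  #  stratum 1: used z=0, available z=1, z=0; stratum 2: used z=1, available z=0, z=0
  # score: -u/(u+2) + (1 - u/(u+2)) = 1 - 2u/(u+2) = 0  =>  u = e^beta = 2
  d <- data.frame(stratum = c(1, 1, 1, 2, 2, 2),
                  case = c(1, 0, 0, 1, 0, 0),
                  z = c(0, 1, 0, 1, 0, 0))
  f <- fit_clogit(d, "z")
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-8)
})

test_that("conditional logit matches a generic-optimizer maximization", {
  set.seed(73)
  ns <- 40
  d <- data.frame(stratum = rep(seq_len(ns), each = 6),
                  case = rep(c(1, 0, 0, 0, 0, 0), ns),
                  a = rnorm(6 * ns), b = runif(6 * ns))
  f <- fit_clogit(d, c("a", "b"))
  X <- cbind(d$a, d$b)
  opt <- optim(c(0, 0), function(b) -brute_clogit_loglik(b, X, d$case, d$stratum),
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(coef(f)), opt$par, tolerance = 1e-6)
  expect_equal(f$log_likelihood, -opt$value, tolerance = 1e-9)
  # score max-norm at the optimum
  expect_lt(f$score_norm, 1e-6)
})

test_that("conditional likelihood is invariant to stratum-constant shifts", {
  set.seed(74)
  ns <- 30
  d <- data.frame(stratum = rep(seq_len(ns), each = 5),
                  case = rep(c(1, 0, 0, 0, 0), ns),
                  a = rnorm(5 * ns))
  f1 <- fit_clogit(d, "a")
  d2 <- d
  d2$a <- d$a + rep(rnorm(ns, 0, 10), each = 5)  # arbitrary per-stratum constant
  f2 <- fit_clogit(d2, "a")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
})

test_that("stratum-constant covariates are rejected as rank deficient", {
  ns <- 20
  d <- data.frame(stratum = rep(seq_len(ns), each = 4),
                  case = rep(c(1, 0, 0, 0), ns),
                  a = rnorm(4 * ns))
  d$const <- rep(rnorm(ns), each = 4)  # constant within every stratum
  expect_error(fit_clogit(d, c("a", "const")), "const")
})

test_that("clogit cross-checks against the survival package", {
  suppressPackageStartupMessages(library(survival))
  set.seed(75)
  ns <- 50
  d <- data.frame(stratum = rep(seq_len(ns), each = 8),
                  case = rep(c(1, rep(0, 7)), ns),
                  a = rnorm(8 * ns), b = rnorm(8 * ns))
  f <- fit_clogit(d, c("a", "b"))
  cf <- survival::clogit(case ~ a + b + strata(stratum), data = d)
  expect_equal(unname(coef(f)), unname(coef(cf)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(cf)))), tolerance = 1e-6)
})
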