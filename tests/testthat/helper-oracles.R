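# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by enumeration or all-pairs search and never call
# the implementation they check.

# O(n^2) all-pairs Euclidean distance transform on a 0/1 matrix.
brute_distance <- function(m, res) {
  feat <- which(m == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (ix in seq_len(nrow(m))) for (iy in seq_len(ncol(m))) {
    out[ix, iy] <- sqrt(min((feat[, 1] - ix)^2 + (feat[, 2] - iy)^2)) * res
  }
  out
}

# Exhaustive contiguous-window bed-site checker: window validity is tested
# directly on the full pairwise distance matrix; emission mirrors the
# left-to-right maximal, non-overlapping rule.
brute_bed_sites <- function(track, max_pairwise = 50, max_consecutive = 30,
                            min_fixes = 5) {
  n <- nrow(track)
  D <- as.matrix(stats::dist(cbind(track$x, track$y)))
  valid <- function(i, j) {
    if (j > n) return(FALSE)
    w <- i:j
    cons <- if (length(w) > 1) all(D[cbind(w[-length(w)], w[-1])] <= max_consecutive) else TRUE
    cons && all(D[w, w] <= max_pairwise)
  }
  clusters <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (valid(i, j + 1L)) j <- j + 1L
    if (j - i + 1L >= min_fixes) {
      clusters[[length(clusters) + 1]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  clusters
}

# Brute-force HMM likelihood: sum of joint densities over all K^n state paths.
brute_forward <- function(dens, trans, delta) {
  n <- nrow(dens); K <- ncol(dens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- delta[s[1]] * dens[1, s[1]]
    if (n > 1) for (i in 2:n) p <- p * trans[s[i - 1], s[i]] * dens[i, s[i]]
    tot <- tot + p
  }
  log(tot)
}

# Brute-force Viterbi: argmax joint density over all enumerated paths.
brute_viterbi <- function(dens, trans, delta) {
  n <- nrow(dens); K <- ncol(dens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  best <- -Inf; best_s <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(delta[s[1]]) + log(dens[1, s[1]])
    if (n > 1) for (i in 2:n) p <- p + log(trans[s[i - 1], s[i]]) + log(dens[i, s[i]])
    if (p > best) { best <- p; best_s <- s }
  }
  unname(as.integer(best_s))
}

# Conditional-logit log-likelihood written independently (per-stratum loop),
# for generic-optimizer cross-checks.
brute_clogit_loglik <- function(beta, X, y, strata) {
  eta <- drop(X %*% beta)
  ll <- 0
  for (s in unique(strata)) {
    w <- strata == s
    ll <- ll + eta[w][y[w] == 1] - log(sum(exp(eta[w])))
  }
  ll
}

# Shared small landscape, built once per test run.
test_stack <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_landscape(landscape_config(extent_m = 5000, seed = 7))
    cache
  }
})

# Hourly track builder for preprocessing tests.
make_track <- function(x, y, t0 = as.POSIXct("2015-05-01 00:00:00", tz = "UTC"),
                       dop = 2, id = "by1") {
  data.frame(bear_year_id = id, t = t0 + 3600 * (seq_along(x) - 1),
             x = x, y = y, dop = dop)
}
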