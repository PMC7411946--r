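# Shared fixtures and independent oracle implementations used across tests.

# small rectangular arena without obstacles
arena_map <- function(xmax = 4, ymax = 5, resolution = 1,
                      stations = NULL, obstacles = list(), zones = list()) {
  if (is.null(stations))
    stations <- data.frame(id = sprintf("S%02d", 1:4),
                           x = c(0, xmax, 0, xmax),
                           y = c(0, 0, ymax, ymax),
                           z = 3)
  barn_map(list(xmin = 0, xmax = xmax, ymin = 0, ymax = ymax),
           stations, obstacles = obstacles, zones = zones,
           resolution = resolution, name = "arena")
}

path_to_fixture <- function(name) {
  system.file("extdata", name, package = "barnloc")
}

# brute-force moving-window filters: direct definition, O(n^2)
naive_window_filter <- function(t, x, window, fun) {
  vapply(seq_along(x), function(i) {
    fun(x[abs(t - t[i]) <= window / 2 + 1e-9])
  }, numeric(1))
}

# textbook Kalman recursion with explicit matrix algebra (independent of the
# scalarized implementation in the package)
matrix_kalman <- function(x, q, dt = 0.2, r = 1) {
  F <- matrix(c(1, 0, dt, 1), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  Q <- diag(q, 2)
  s <- matrix(c(x[1], 0), 2, 1)
  P <- diag(2)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- F %*% s
    P <- F %*% P %*% t(F) + Q
    S <- H %*% P %*% t(H) + r
    K <- P %*% t(H) %*% solve(S)
    s <- s + K %*% (x[i] - H %*% s)
    P <- (diag(2) - K %*% H) %*% P
    out[i] <- s[1, 1]
  }
  out
}

# exhaustive MAP path search over all K^T paths (log domain)
brute_force_viterbi <- function(emissions, tm, prior = NULL) {
  TT <- nrow(emissions); K <- ncol(emissions)
  if (is.null(prior)) prior <- rep(1 / K, K)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), TT)))
  score <- log(prior[paths[, 1]]) + log(emissions[cbind(1L, paths[, 1])])
  if (TT > 1L) {
    for (t in 2:TT) {
      score <- score + log(tm[cbind(paths[, t - 1L], paths[, t])]) +
        log(emissions[cbind(t, paths[, t])])
    }
  }
  as.integer(paths[which.max(score), ])
}

# hand expansion of the per-window squared-error surface
naive_error_surface <- function(m, rss_map, shifted) {
  vapply(seq_len(nrow(rss_map)), function(k) {
    r <- rss_map[k, names(m)]
    if (shifted) sum(((m - mean(m)) - (r - mean(r)))^2)
    else sum((m - r)^2)
  }, numeric(1))
}
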