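# Shared fixtures: tiny banks and brute-force oracles kept deliberately
# independent of the package's own likelihood/estimation code paths.

tiny_bank <- function(n = 5, a = NULL, b = NULL, cc = 0) {
  if (is.null(a)) a <- seq(0.8, 1.6, length.out = n)
  if (is.null(b)) b <- seq(-1.5, 1, length.out = n)
  itemBank(sprintf("t%02d", seq_len(n)), a, b, cc)
}

# literal 3PL, written independently of the package internals
oracle_p <- function(a, b, cc, theta) cc + (1 - cc) / (1 + exp(-a * (theta - b)))

# Eq-3 style literal product of per-item probabilities
oracle_pattern_lik <- function(u, a, b, cc, theta) {
  p <- oracle_p(a, b, cc, theta)
  prod(ifelse(u == 1, p, 1 - p))
}

# exhaustive grid-search argmax of the pattern log likelihood
oracle_grid_mle <- function(u, a, b, cc, grid = seq(-4, 4, by = 0.001)) {
  ll <- vapply(grid, function(th) {
    p <- oracle_p(a, b, cc, th)
    sum(u * log(p) + (1 - u) * log(1 - p))
  }, numeric(1))
  grid[which.max(ll)]
}

random_pattern <- function(bank, theta) {
  df <- as.data.frame(bank)
  p <- oracle_p(df$discrimination, df$difficulty, df$guessing, theta)
  stats::setNames(rbinom(nrow(df), 1, p), df$item_id)
}

# direct hand evaluation of the Welch formula
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
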