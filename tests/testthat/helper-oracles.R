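# Brute-force oracles: explicit double loops over pixels and tiles, kept
# deliberately independent of the package's vectorized implementations.

oracle_intensity <- function(px, mask) {
  s <- 0; n <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) { s <- s + px[i, j]; n <- n + 1 }
  }
  m <- s / n
  ss <- 0
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) ss <- ss + (px[i, j] - m)^2
  }
  c(mean = m, sd = sqrt(ss / n), n = n)
}

oracle_michelson <- function(px, mask) {
  mx <- -Inf; mn <- Inf
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) {
      if (px[i, j] > mx) mx <- px[i, j]
      if (px[i, j] < mn) mn <- px[i, j]
    }
  }
  if (mx == 0) 0 else (mx - mn) / (mx + mn)
}

# per-tile means and Michelson contrasts under the bounding-box grid with
# the >=50% coverage rule
oracle_blocks <- function(px, mask, bs, min_cov = 0.5) {
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    if (mask[i, j]) {
      if (i < rmin) rmin <- i
      if (i > rmax) rmax <- i
      if (j < cmin) cmin <- j
      if (j > cmax) cmax <- j
    }
  }
  means <- c(); contrasts <- c()
  for (r0 in seq(rmin, rmax, by = bs)) {
    for (c0 in seq(cmin, cmax, by = bs)) {
      vals <- c()
      for (i in r0:min(r0 + bs - 1, nrow(px))) {
        for (j in c0:min(c0 + bs - 1, ncol(px))) {
          if (mask[i, j]) vals <- c(vals, px[i, j])
        }
      }
      if (length(vals) >= min_cov * bs^2) {
        means <- c(means, mean(vals))
        mx <- max(vals); mn <- min(vals)
        contrasts <- c(contrasts, if (mx == 0) 0 else (mx - mn) / (mx + mn))
      }
    }
  }
  list(means = means, contrasts = contrasts)
}

# random test image with a random (always nonempty) rectangular-ish mask
random_case <- function(seed, max_side = 60) {
  set.seed(seed)
  nr <- sample(8:max_side, 1)
  nc <- sample(8:max_side, 1)
  px <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) < 0.8, nr, nc)
  r0 <- sample(seq_len(max(nr - 4, 1)), 1)
  c0 <- sample(seq_len(max(nc - 4, 1)), 1)
  mask[r0:min(r0 + 3, nr), c0:min(c0 + 3, nc)] <- TRUE  # guarantee a core
  list(px = px, mask = mask)
}

# exhaustive threshold-sweep oracle for the perfect/non-perfect classifier
oracle_best_threshold <- function(predicted, perfect) {
  thresholds <- sort(unique(c(0, predicted, 1)))
  best_acc <- -1; best_t <- NA
  for (t in thresholds) {
    correct <- 0
    for (i in seq_along(predicted)) {
      if ((predicted[i] >= t) == perfect[i]) correct <- correct + 1
    }
    acc <- correct / length(predicted)
    if (acc >= best_acc) { best_acc <- acc; best_t <- t }  # tie -> higher t
  }
  list(threshold = best_t, accuracy = best_acc)
}

# simulate a crossed-design trial table directly from the logistic model
simulate_crossed <- function(n_pairs, experts_per_pair, beta0, slopes,
                             var_print, var_expert, seed,
                             x = NULL) {
  set.seed(seed)
  p <- length(slopes)
  if (is.null(x)) x <- matrix(rnorm(n_pairs * p), n_pairs, p)
  colnames(x) <- paste0("x", seq_len(p))
  u <- rnorm(n_pairs, 0, sqrt(var_print))
  v <- rnorm(experts_per_pair, 0, sqrt(var_expert))
  d <- expand.grid(pair = seq_len(n_pairs), expert = seq_len(experts_per_pair))
  eta <- beta0 + as.numeric(x %*% slopes)[d$pair] + u[d$pair] + v[d$expert]
  d$y <- rbinom(nrow(d), 1, plogis(eta))
  d$pair_id <- factor(d$pair)
  d$expert_id <- factor(d$expert)
  for (k in seq_len(p)) d[[paste0("x", k)]] <- x[d$pair, k]
  list(data = d, x = x, u = u, v = v)
}
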