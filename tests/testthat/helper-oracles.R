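# brute-force oracles, deliberately written as direct enumerations so they
# stay independent of the package's solvers

# exhaustive basic-solution search: the optimal tau-quantile line passes
# through two data points
oracle_lqr <- function(x, y, tau) {
  n <- length(y)
  best <- NULL; bestloss <- Inf
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    if (x[i] == x[j]) next
    sl <- (y[i] - y[j]) / (x[i] - x[j])
    ic <- y[i] - sl * x[i]
    r <- y - (ic + sl * x)
    loss <- sum(ifelse(r >= 0, tau * r, (tau - 1) * r)) / n
    if (loss < bestloss) { bestloss <- loss; best <- c(ic, sl) }
  }
  list(coef = best, loss = bestloss)
}

# Krippendorff's alpha by explicit within-unit pair enumeration
oracle_alpha <- function(codes, metric = "ordinal") {
  codes <- as.matrix(codes)
  lev <- sort(unique(codes[!is.na(codes)]))
  units <- lapply(seq_len(nrow(codes)), function(u) {
    v <- codes[u, ]; v[!is.na(v)]
  })
  units <- units[vapply(units, length, 0L) >= 2]
  # marginal counts of pairable values
  nmarg <- vapply(lev, function(l) sum(vapply(units, function(v) sum(v == l), 0L)), 0)
  ntot <- sum(nmarg)
  d2 <- function(c1, c2) {
    if (c1 == c2) return(0)
    if (metric == "nominal") return(1)
    i1 <- which(lev == c1); i2 <- which(lev == c2)
    lo <- min(i1, i2); hi <- max(i1, i2)
    (sum(nmarg[lo:hi]) - (nmarg[i1] + nmarg[i2]) / 2)^2
  }
  Do <- 0
  for (v in units) {
    m <- length(v)
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
      Do <- Do + d2(v[i], v[j]) / (m - 1)
  }
  Do <- Do / ntot
  De <- 0
  for (i1 in seq_along(lev)) for (i2 in seq_along(lev)) if (i1 != i2)
    De <- De + nmarg[i1] * nmarg[i2] * d2(lev[i1], lev[i2])
  De <- De / (ntot * (ntot - 1))
  list(alpha = 1 - Do / De, D_o = Do, D_e = De)
}

# pool-adjacent-violators, textbook sequential pooling
oracle_pava <- function(y) {
  blocks <- lapply(seq_along(y), function(i) list(sum = y[i], n = 1L))
  i <- 1L
  while (i < length(blocks)) {
    m1 <- blocks[[i]]$sum / blocks[[i]]$n
    m2 <- blocks[[i + 1]]$sum / blocks[[i + 1]]$n
    if (m1 > m2) {
      blocks[[i]] <- list(sum = blocks[[i]]$sum + blocks[[i + 1]]$sum,
                          n = blocks[[i]]$n + blocks[[i + 1]]$n)
      blocks[[i + 1]] <- NULL
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  unlist(lapply(blocks, function(b) rep(b$sum / b$n, b$n)))
}
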