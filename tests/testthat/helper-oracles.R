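# Independent R-level oracles for the compiled energy kernels and the
# analysis stack. These deliberately re-derive every quantity with naive
# loops / closed forms so they share no code path with the implementation.

oracleKernel <- function(r, mu, rc) 0.5 * (1 + tanh(mu * (rc - r)))

oracleWca <- function(r, eps, sigma) {
  cut <- 2^(1 / 6) * sigma
  ifelse(r < cut, 4 * eps * ((sigma / r)^12 - (sigma / r)^6) + eps, 0)
}

oracleFene <- function(r, k, r0) -0.5 * k * r0^2 * log(1 - (r / r0)^2)

oracleGamma <- function(d, p) {
  g <- p@idealGamma
  ifelse(d >= p@dMin & d <= p@dMax,
         g[1] / log(d) + g[2] / d + g[3] / d^2, 0)
}

# brute-force per-term energies over an n-bead single chain
oracleEnergies <- function(pos, types, loops, p) {
  n <- nrow(pos)
  rij <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))
  eb <- 0
  for (i in seq_len(n - 1)) {
    r <- rij(i, i + 1)
    eb <- eb + oracleFene(r, p@feneK, p@feneR0) +
      oracleWca(r, p@stericEpsilon, p@stericSigma)
  }
  ec <- 0
  for (i in seq_len(n)) {
    r <- sqrt(sum(pos[i, ]^2))
    if (r > p@confinementRadius)
      ec <- ec + p@confinementK * (r - p@confinementRadius)^2
  }
  ei <- 0; et <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- rij(i, j); d <- j - i
    ei <- ei + oracleGamma(d, p) * oracleKernel(r, p@contactMu, p@contactRc)
    if (d >= 2)
      et <- et + p@typeMatrix[types[i] + 1, types[j] + 1] *
        oracleKernel(r, p@contactMu, p@contactRc) +
        oracleWca(r, p@stericEpsilon, p@stericSigma)
  }
  el <- 0
  if (!is.null(loops) && nrow(loops))
    for (l in seq_len(nrow(loops)))
      el <- el + p@loopChi *
        oracleKernel(rij(loops[l, 1], loops[l, 2]), p@contactMu, p@contactRc)
  c(bonded = eb, confinement = ec, ideal = ei, type = et, loops = el)
}

# brute-force contact map: triple loop over frames x pairs
oracleContactMap <- function(models, rc) {
  n <- nrow(models[[1]])
  m <- matrix(0, n, n)
  for (fr in models)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (sqrt(sum((fr[i, ] - fr[j, ])^2)) <= rc) m[i, j] <- m[i, j] + 1
  m / length(models)
}

# per-diagonal mean, naive
oraclePs <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n - 1), function(s) {
    vals <- c()
    for (i in seq_len(n - s)) vals <- c(vals, m[i, i + s])
    mean(vals)
  }, numeric(1))
}

# textbook Pearson correlation
oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# homotypic vs heterotypic mean contact frequency among non-bonded pairs
contactFractionsByType <- function(map, types) {
  m <- if (is(map, "ContactMap")) contactMatrix(map) else map
  n <- nrow(m)
  same <- outer(types, types, "==")
  sep <- abs(outer(seq_len(n), seq_len(n), "-")) >= 2
  c(homotypic = mean(m[same & sep]), heterotypic = mean(m[!same & sep]))
}

# agreement of an eigenvector's sign pattern with planted two-class labels,
# maximised over the global sign
signAgreement <- function(v, labels) {
  ok <- !is.na(v)
  ref <- ifelse(labels == labels[1], 1, -1)
  a <- mean(sign(v[ok]) == ref[ok])
  max(a, 1 - a)
}
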