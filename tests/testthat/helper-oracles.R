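# Independent brute-force oracles used across the suite.  They are
# deliberately written as explicit loops over definitions, separate from
# the vectorized implementations in the package.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

chars_of <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# population z-normalization of a 20-value scale
znorm <- function(s) {
  s <- s[AA]
  (s - mean(s)) / sqrt(mean((s - mean(s))^2))
}

# direct-summation autocorrelation at a single (scale, lag)
oracle_ac <- function(seq, scale, d, kind) {
  p <- unname(znorm(scale)[chars_of(seq)])
  L <- length(p)
  pairs <- seq_len(L - d)
  if (kind == "moreau_broto") {
    s <- 0
    for (i in pairs) s <- s + p[i] * p[i + d]
    return(unname(s / (L - d)))
  }
  pbar <- mean(p)
  if (kind == "moran") {
    num <- 0
    for (i in pairs) num <- num + (p[i] - pbar) * (p[i + d] - pbar)
    den <- mean((p - pbar)^2)
    return(unname((num / (L - d)) / den))
  }
  num <- 0
  for (i in pairs) num <- num + (p[i] - p[i + d])^2
  unname((num / (2 * (L - d))) / (sum((p - pbar)^2) / (L - 1)))
}

# double-loop quasi-sequence-order for one distance matrix
oracle_qso_one <- function(seq, M, maxlag, w) {
  ch <- chars_of(seq)
  L <- length(ch)
  f <- vapply(AA, function(a) sum(ch == a), numeric(1)) / L
  tau <- numeric(maxlag)
  for (d in seq_len(maxlag)) {
    for (i in seq_len(L - d)) {
      tau[d] <- tau[d] + M[ch[i], ch[i + d]]^2
    }
  }
  den <- sum(f) + w * sum(tau)
  unname(c(f / den, w * tau / den))
}

# direct-summation type-1 pseudo-amino-acid composition
oracle_paac <- function(seq, lam, w, scales) {
  ch <- chars_of(seq)
  L <- length(ch)
  zs <- lapply(scales, znorm)
  theta <- numeric(lam)
  for (k in seq_len(lam)) {
    acc <- 0
    for (i in seq_len(L - k)) {
      corr <- 0
      for (z in zs) corr <- corr + (z[ch[i]] - z[ch[i + k]])^2
      acc <- acc + corr / length(zs)
    }
    theta[k] <- acc / (L - k)
  }
  f <- vapply(AA, function(a) sum(ch == a), numeric(1)) / L
  den <- sum(f) + w * sum(theta)
  unname(c(f / den, w * theta / den))
}

# direct-summation amphiphilic pseudo-amino-acid composition
oracle_apaac <- function(seq, lam, w, scales) {
  ch <- chars_of(seq)
  L <- length(ch)
  z1 <- znorm(scales[[1]]); z2 <- znorm(scales[[2]])
  tau <- numeric(2 * lam)
  for (k in seq_len(lam)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - k)) {
      s1 <- s1 + z1[ch[i]] * z1[ch[i + k]]
      s2 <- s2 + z2[ch[i]] * z2[ch[i + k]]
    }
    tau[2 * k - 1] <- s1 / (L - k)
    tau[2 * k] <- s2 / (L - k)
  }
  f <- vapply(AA, function(a) sum(ch == a), numeric(1)) / L
  den <- sum(f) + w * sum(tau)
  unname(c(f / den, w * tau / den))
}

# step-up Benjamini-Hochberg by the direct definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j_set <- which(rank(p, ties.method = "first") >= i)
    # q for the i-th smallest p: min over j >= i of m * p_(j) / j
    q[ord[i]] <- min(vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1)))
  }
  pmin(q, 1)
}

# pairwise-comparison AUC with half credit for ties
oracle_auc <- function(truth, prob) {
  pos <- prob[as.logical(truth)]
  neg <- prob[!as.logical(truth)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# neuron-by-neuron forward pass for a csf_mlp parameter set
oracle_forward <- function(params, x) {
  h <- x
  L <- length(params$layers)
  for (l in seq_len(L - 1)) {
    ly <- params$layers[[l]]
    out <- numeric(ncol(ly$W))
    for (j in seq_along(out)) {
      acc <- ly$b[j]
      for (i in seq_along(h)) acc <- acc + h[i] * ly$W[i, j]
      out[j] <- max(0, acc)
    }
    h <- out
  }
  ly <- params$layers[[L]]
  o <- numeric(2)
  for (j in 1:2) {
    acc <- ly$b[j]
    for (i in seq_along(h)) acc <- acc + h[i] * ly$W[i, j]
    o[j] <- acc
  }
  unname(exp(o[2]) / (exp(o[1]) + exp(o[2])))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}
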