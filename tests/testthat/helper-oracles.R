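# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive: loops and enumeration,
# no shared code with the implementation under test.

# small synthetic table for module tests
tinyTable <- function(nSubjects = 10, recordingsPerSubject = 5, seed = 1, ...) {
  generateTelemonitoring(syntheticConfig(
    nSubjects = nSubjects, recordingsPerSubject = recordingsPerSubject,
    seed = seed, ...))
}

# co-association by explicit double loop over row pairs
bruteCoassoc <- function(labelList) {
  n <- length(labelList[[1]])
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    agree <- 0
    for (l in labelList) if (l[i] == l[j]) agree <- agree + 1
    S[i, j] <- agree / length(labelList)
  }
  S
}

# ARI by explicit pair counting over all row pairs
bruteARI <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / tot
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# naive loop-based metrics (spreadsheet-style arithmetic)
oracleMetrics <- function(p, o, m) {
  n <- length(o)
  se <- 0; ae <- 0
  for (i in seq_len(n)) {
    se <- se + (p[i] - o[i])^2
    ae <- ae + abs(p[i] - o[i])
  }
  ob <- sum(o) / n
  den <- 0
  for (i in seq_len(n)) den <- den + (abs(p[i] - ob) + abs(o[i] - ob))^2
  pb <- sum(p) / n
  num <- 0; vp <- 0; vo <- 0
  for (i in seq_len(n)) {
    num <- num + (p[i] - pb) * (o[i] - ob)
    vp <- vp + (p[i] - pb)^2
    vo <- vo + (o[i] - ob)^2
  }
  pa <- num / sqrt(vp * vo)
  list(rmse = sqrt(se / n), mae = ae / n, ia = 1 - se / den, pa = pa,
       r2a = 1 - (1 - pa^2) * (n - 1) / (n - m - 1))
}

# exhaustive minimum hyperedge cut over bipartitions with part sizes in
# [lo, hi]; edges is a list of integer vertex sets
bruteMinBipartitionCut <- function(edges, n, lo, hi) {
  best <- Inf
  for (sz in lo:min(hi, n - lo)) {
    combos <- utils::combn(n, sz)
    for (ci in seq_len(ncol(combos))) {
      inA <- logical(n)
      inA[combos[, ci]] <- TRUE
      if ((n - sz) < lo || (n - sz) > hi) next
      cut <- 0
      for (e in edges) {
        ia <- inA[e]
        if (any(ia) && !all(ia)) cut <- cut + 1
      }
      if (cut < best) best <- cut
    }
  }
  best
}

# random ensemble of B labelings over n rows with up to kmax clusters
randomEnsemble <- function(n, B, kmax, seed) {
  withr::with_seed(seed, lapply(seq_len(B), function(b) {
    k <- sample(2:kmax, 1)
    # guarantee every label in 1..k appears
    l <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    sample(l)
  }))
}

asPartitions <- function(labelList)
  lapply(labelList, function(l) Partition(l, k = max(l)))

`%||%` <- function(a, b) if (is.null(a)) b else a
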