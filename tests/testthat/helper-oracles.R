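# Independent, deliberately naive transcriptions of the quantities under
# test. These stay loop-based and never call the package's vectorized
# implementations.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracleAssign <- function(x, protos) {
  vapply(seq_len(nrow(x)), function(i) {
    d <- vapply(seq_len(nrow(protos)),
                function(j) euclid(x[i, ], protos[j, ]), numeric(1))
    which(d == min(d))[1L]
  }, integer(1))
}

oracleF1 <- function(protos, labels) {
  k <- nrow(protos)
  zbar <- colMeans(protos)
  total <- 0
  for (i in seq_len(k)) {
    ni <- sum(labels == i)
    total <- total + ni * euclid(protos[i, ], zbar)
  }
  total
}

oracleF2 <- function(x, protos, labels) {
  total <- 0
  for (i in seq_len(nrow(x)))
    total <- total + euclid(x[i, ], protos[labels[i], ])
  total
}

oracleDBI <- function(x, protos, labels) {
  k <- nrow(protos)
  counts <- tabulate(labels, k)
  nonEmpty <- which(counts > 0)
  if (length(nonEmpty) < 2) return(Inf)
  s <- numeric(k)
  for (i in nonEmpty) {
    members <- which(labels == i)
    s[i] <- mean(vapply(members,
                        function(m) euclid(x[m, ], protos[i, ]),
                        numeric(1)))
  }
  ratios <- numeric(0)
  for (i in nonEmpty) {
    worst <- -Inf
    for (j in nonEmpty) {
      if (j == i) next
      r <- (s[i] + s[j]) / euclid(protos[i, ], protos[j, ])
      if (r > worst) worst <- r
    }
    ratios <- c(ratios, worst)
  }
  mean(ratios)
}

oracleSilhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) euclid(x[i, ], x[j, ]), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      m <- mean(vapply(members, function(j) euclid(x[i, ], x[j, ]),
                       numeric(1)))
      if (m < b) b <- m
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracleNMI <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  pa <- vapply(ua, function(v) sum(a == v) / n, numeric(1))
  pb <- vapply(ub, function(v) sum(b == v) / n, numeric(1))
  ha <- -sum(pa * log2(pa)); hb <- -sum(pb * log2(pb))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    pij <- sum(a == ua[i] & b == ub[j]) / n
    if (pij > 0) mi <- mi + pij * log2(pij / (pa[i] * pb[j]))
  }
  2 * mi / (ha + hb)
}

# explicit pair-counting ARI: classify every cell pair as agreeing or
# disagreeing in each partition
oracleARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sameA <- a[i] == a[j]; sameB <- b[i] == b[j]
    if (sameA && sameB) n11 <- n11 + 1
    else if (!sameA && !sameB) n00 <- n00 + 1
    else if (sameA) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxIdx <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxIdx == expected) return(1)
  (n11 - expected) / (maxIdx - expected)
}

oracleNDS <- function(objs) {
  remaining <- seq_len(nrow(objs))
  fronts <- list()
  while (length(remaining)) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && dominates(objs[j, ], objs[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

oracleCrowding <- function(objs) {
  m <- nrow(objs)
  if (m <= 2) return(rep(Inf, m))
  cd <- numeric(m)
  for (j in 1:2) {
    ord <- order(objs[, j])
    cd[ord[1]] <- Inf
    cd[ord[m]] <- Inf
    rng <- objs[ord[m], j] - objs[ord[1], j]
    if (rng > 0)
      for (p in 2:(m - 1))
        cd[ord[p]] <- cd[ord[p]] +
          (objs[ord[p + 1], j] - objs[ord[p - 1], j]) / rng
  }
  cd
}

# hypervolume dominated by a 2-D front (f1 maximized, f2 minimized)
# relative to a reference point worse than every front member
hypervolume2d <- function(objs, ref) {
  fr <- objs[oracleNDS(objs)[[1L]], , drop = FALSE]
  fr <- unique(fr[order(-fr[, 1L]), , drop = FALSE])  # f1 desc, f2 desc
  hv <- 0
  f2prev <- ref[2L]
  for (i in seq_len(nrow(fr))) {
    hv <- hv + (fr[i, 1L] - ref[1L]) * (f2prev - fr[i, 2L])
    f2prev <- fr[i, 2L]
  }
  hv
}

randomObjectives <- function(m, seed) {
  set.seed(seed)
  cbind(f1 = round(runif(m, 0, 10), 2), f2 = round(runif(m, 0, 10), 2))
}
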