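# Independent brute-force oracles.  These enumerate elementary events
# directly and stay deliberately separate from the package's closed-form /
# factorized implementations.

# emission oracle: enumerate per-copy outcomes (drop, or each shown allele)
oracleEmission <- function(obs, g, error, labels) {
  d <- error@dropout; e <- error@falseAllele; f <- error@failure
  k <- length(labels)
  copyOutcomes <- function(t) {
    out <- list(list(val = NA_integer_, pr = d))
    for (a in labels) {
      pr <- (1 - d) * (if (a == t) 1 - e else e / (k - 1))
      out[[length(out) + 1L]] <- list(val = a, pr = pr)
    }
    out
  }
  target <- if (is.null(obs) || anyNA(obs)) NULL else sort(obs)
  total <- 0
  for (o1 in copyOutcomes(g[1])) for (o2 in copyOutcomes(g[2])) {
    shown <- c(o1$val, o2$val); shown <- shown[!is.na(shown)]
    seenAs <- if (!length(shown)) NULL else {
      u <- sort(unique(shown))
      if (length(u) == 1L) c(u, u) else u
    }
    pr <- (1 - f) * o1$pr * o2$pr
    match <- (is.null(target) && is.null(seenAs)) ||
      (!is.null(target) && !is.null(seenAs) && all(seenAs == target))
    if (match) total <- total + pr
  }
  if (is.null(target)) total <- total + f
  total
}

# exhaustive trio likelihood at one locus: sum over true genotype triples
# and transmission events; NULL parent observation = unknown parent
oracleTrioLikLocus <- function(obsO, obsD, obsS, p, error) {
  labels <- as.integer(names(p))
  genos <- list()
  for (i in seq_along(labels)) for (j in i:length(labels))
    genos[[length(genos) + 1L]] <- c(labels[i], labels[j])
  hw <- function(g) {
    pa <- p[as.character(g[1])]; pb <- p[as.character(g[2])]
    unname(if (g[1] == g[2]) pa * pb else 2 * pa * pb)
  }
  trans <- function(go, gd, gs) {
    pr <- 0
    for (x in gd) for (y in gs)
      if (all(sort(c(x, y)) == sort(go))) pr <- pr + 0.25
    pr
  }
  num <- 0; den <- 0
  for (gd in genos) for (gs in genos) {
    wD <- hw(gd) * (if (is.null(obsD)) 1
                    else oracleEmission(obsD, gd, error, labels))
    wS <- hw(gs) * (if (is.null(obsS)) 1
                    else oracleEmission(obsS, gs, error, labels))
    if (wD == 0 || wS == 0) next
    den <- den + wD * wS
    for (go in genos) {
      tp <- trans(go, gd, gs)
      if (tp == 0) next
      num <- num + wD * wS * tp * oracleEmission(obsO, go, error, labels)
    }
  }
  num / den
}

# brute-force Bayes posterior that `conf` (pair) is the true genotype given
# replicate observations at one locus
oracleReliabilityLocus <- function(conf, obsList, p, error) {
  labels <- as.integer(names(p))
  genos <- list()
  for (i in seq_along(labels)) for (j in i:length(labels))
    genos[[length(genos) + 1L]] <- c(labels[i], labels[j])
  w <- vapply(genos, function(g) {
    pa <- p[as.character(g[1])]; pb <- p[as.character(g[2])]
    prior <- unname(if (g[1] == g[2]) pa * pb else 2 * pa * pb)
    lik <- 1
    for (o in obsList) lik <- lik * oracleEmission(o, g, error, labels)
    prior * lik
  }, 0)
  hit <- vapply(genos, function(g) all(sort(g) == sort(conf)), TRUE)
  sum(w[hit]) / sum(w)
}

# hand-rolled IRLS for logistic regression (intercept prepended)
oracleIRLS <- function(y, X = NULL, tol = 1e-12, maxit = 200) {
  Xm <- cbind(1, if (is.null(X)) NULL else as.matrix(X))
  beta <- rep(0, ncol(Xm))
  for (it in seq_len(maxit)) {
    eta <- as.vector(Xm %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    betaNew <- solve(crossprod(Xm, W * Xm), crossprod(Xm, W * z))
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  as.vector(beta)
}

# dense simplex-grid maximizer of the dyadic IBD likelihood; returns r
oracleGridMLr <- function(P, step = 0.005) {
  best <- -Inf; bk <- c(1, 0, 0)
  for (k0 in seq(0, 1, by = step)) for (k1 in seq(0, 1 - k0, by = step)) {
    kk <- c(k0, k1, 1 - k0 - k1)
    v <- sum(log(as.vector(P %*% kk)))
    if (is.finite(v) && v > best) { best <- v; bk <- kk }
  }
  bk[3] + bk[2] / 2
}

# plain-language restatement of the consensus rule, per locus, applied to a
# list of per-replicate observed pairs (NULL = failure)
oracleConsensusLocus <- function(pairs) {
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) return(list(status = "missing"))
  keys <- vapply(pairs, function(p) paste(sort(p), collapse = "/"), "")
  hetKeys <- keys[vapply(pairs, function(p) p[1] != p[2], TRUE)]
  if (length(hetKeys)) {
    tab <- table(hetKeys)
    if (max(tab) >= 2) {
      win <- sort(names(tab)[tab == max(tab)])[1]
      ab <- as.integer(strsplit(win, "/")[[1]])
      return(list(status = "het", a = ab[1], b = ab[2]))
    }
  }
  homs <- unlist(lapply(pairs, function(p) if (p[1] == p[2]) p[1]))
  if (!is.null(homs)) {
    tab <- sort(table(homs), decreasing = TRUE)
    cand <- as.integer(names(tab)[1])
    alleleReps <- table(unlist(lapply(pairs, unique)))
    others <- alleleReps[names(alleleReps) != as.character(cand)]
    if (tab[1] >= 3 && (!length(others) || max(others) < 2))
      return(list(status = "hom", a = cand, b = cand))
  }
  list(status = "missing")
}

# restatement of the dropout-tolerant matching rule over two status/allele
# data.frames (columns status, a1, a2)
oracleMatch <- function(s1, s2, minShared) {
  shared <- which(s1$status != "missing" & s2$status != "missing")
  if (length(shared) < minShared) return("indeterminate")
  nDrop <- 0
  for (i in shared) {
    p1 <- c(s1$a1[i], s1$a2[i]); p2 <- c(s2$a1[i], s2$a2[i])
    if (identical(sort(p1), sort(p2))) next
    homFirst <- s1$status[i] == "hom" && s2$status[i] == "het" && p1[1] %in% p2
    homSecond <- s2$status[i] == "hom" && s1$status[i] == "het" && p2[1] %in% p1
    if (homFirst || homSecond) nDrop <- nDrop + 1 else return("different")
  }
  if (nDrop <= 1) "same-individual" else "different"
}
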