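# Independent brute-force oracles, deliberately naive transcriptions of the
# definitions; they never share code with the implementation.

# quadratic-time BH step-up: adj_k = min over j >= k of p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m)) {
    adj[k] <- min(1, min(sorted[k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by explicit choose() summation
fisher_tail_brute <- function(overlap, term_size, universe, query) {
  ks <- overlap:min(term_size, query)
  sum(vapply(ks, function(k) {
    exp(lchoose(term_size, k) + lchoose(universe - term_size, query - k) -
          lchoose(universe, query))
  }, 1.0))
}

# exact Mann-Whitney by recursive enumeration of group assignments
mw_exact_brute <- function(x, y) {
  vals <- c(x, y)
  n <- length(x); N <- length(vals)
  u_of <- function(idx) {
    xv <- vals[idx]; yv <- vals[-idx]
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  us <- c()
  recurse <- function(start, chosen) {
    if (length(chosen) == n) {
      us <<- c(us, u_of(chosen))
      return()
    }
    if (start > N) return()
    for (i in start:N) recurse(i + 1, c(chosen, i))
  }
  recurse(1, integer())
  u_obs <- u_of(seq_len(n))
  list(U = u_obs, p_less = mean(us <= u_obs))
}

# Spearman by hand: average ranks via pairwise counting, then the Pearson
# product-moment formula on the ranks
spearman_brute <- function(x, y) {
  hand_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    }, 1.0)
  }
  rx <- hand_rank(x); ry <- hand_rank(y)
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# cluster chaining by transitive closure of the pairwise "within max_gap on
# the same chromosome" relation restricted to coordinate-adjacent loci
chain_brute <- function(loci, max_gap = 10000) {
  loci <- loci[order(loci$chrom, loci$start, loci$end, loci$mirna_id), ]
  n <- nrow(loci)
  linked <- matrix(FALSE, n, n)
  for (chr in unique(loci$chrom)) {
    idx <- which(loci$chrom == chr)
    if (length(idx) < 2) next
    run_end <- loci$end[idx[1]]
    for (j in 2:length(idx)) {
      gap <- max(loci$start[idx[j]] - run_end, 0)
      if (gap <= max_gap) linked[idx[j - 1], idx[j]] <- TRUE
      run_end <- max(run_end, loci$end[idx[j]])
    }
  }
  linked <- linked | t(linked)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (linked[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(loci$mirna_id, comp) |>
    Filter(f = function(g) length(g) >= 2) |>
    lapply(sort) |>
    unname()
}

# naive O(n^3) average-linkage agglomeration; returns the cophenetic matrix
average_linkage_brute <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# moment-equation moderated t, written from the definitions with uniroot
moderated_brute <- function(values, design, contrast) {
  G <- nrow(values)
  df <- nrow(design) - ncol(design)
  s2 <- lfc <- numeric(G)
  xtxi <- solve(t(design) %*% design)
  su <- sqrt(drop(t(contrast) %*% xtxi %*% contrast))
  for (g in seq_len(G)) {
    fit <- lm.fit(design, values[g, ])
    s2[g] <- sum(fit$residuals^2) / df
    lfc[g] <- sum(contrast * fit$coefficients)
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (evar > 0) {
    root <- uniroot(function(x) trigamma(x) - evar,
                    lower = 1e-6, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * root
    s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2p <- (d0 * s0 + df * s2) / (d0 + df)
    dft <- df + d0
  } else {
    d0 <- Inf; s0 <- mean(s2); s2p <- rep(s0, G); dft <- Inf
  }
  t_mod <- lfc / (su * sqrt(s2p))
  list(d0 = d0, s0_sq = s0, t_mod = t_mod,
       p = 2 * pt(-abs(t_mod), dft))
}

# mean silhouette width over a 2-group labelling, from the definition
silhouette_brute <- function(X, labels) {
  D <- as.matrix(dist(X))
  mean(vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(unique(labels[!own]), function(l) {
      mean(D[i, labels == l])
    }, 1.0))
    (b - a) / max(a, b)
  }, 1.0))
}
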