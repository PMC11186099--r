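# Independent brute-force oracles used across the suite. These never call
# the implementation paths they check.

# Exact hypergeometric upper tail P(X >= i) for X ~ Hyper(G, ka, kb),
# computed by direct summation of binomial-coefficient ratios.
hyper_tail_enum <- function(G, ka, kb, i) {
  hi <- min(ka, kb)
  if (i <= max(0, ka + kb - G)) return(1)
  if (i > hi) return(0)
  js <- i:hi
  sum(exp(lchoose(ka, js) + lchoose(G - ka, kb - js) - lchoose(G, kb)))
}

# All set partitions of 1..n as restricted growth strings.
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# Community counts of all maximum-modularity partitions of a small graph.
brute_modularity_counts <- function(g, tol = 1e-12) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- set_partitions(n)
  mods <- vapply(parts, function(m) igraph::modularity(g, m), numeric(1))
  best <- max(mods)
  counts <- vapply(parts[mods >= best - tol],
                   function(m) length(unique(m)), integer(1))
  sort(unique(counts))
}

# Best average cosine between columns of A and B over all column
# permutations (brute force, for small k) -- the planted-factor matching
# oracle.
perm_match_cosine <- function(A, B) {
  stopifnot(ncol(A) == ncol(B), ncol(A) <= 7)
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  cosm <- crossprod(An, Bn)
  perms <- all_perms(ncol(A))
  best <- -Inf; best_cos <- NULL
  for (p in perms) {
    v <- cosm[cbind(seq_len(ncol(A)), p)]
    if (mean(v) > best) { best <- mean(v); best_cos <- v }
  }
  best_cos
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Greedy one-to-one matching on a cosine matrix (for k too large to
# enumerate): repeatedly take the largest remaining entry.
greedy_match_cosine <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  cosm <- crossprod(An, Bn)
  out <- numeric(0)
  while (nrow(cosm) >= 1 && ncol(cosm) >= 1) {
    ij <- which(cosm == max(cosm), arr.ind = TRUE)[1, ]
    out <- c(out, cosm[ij[1], ij[2]])
    cosm <- cosm[-ij[1], -ij[2], drop = FALSE]
  }
  out
}

# Exact one-sided (greater) rank-sum p-value by exhausting all marker rank
# placements; w must have no ties.
wilcox_enum_p <- function(w, is_marker) {
  stopifnot(!any(duplicated(w)))
  n <- length(w); m <- sum(is_marker)
  r <- rank(w)
  obs <- sum(r[is_marker])
  combs <- combn(n, m)
  sums <- colSums(matrix(seq_len(n)[combs], nrow = m))
  mean(sums >= obs)
}

# Two-sided Fisher exact p by enumeration (minimum-likelihood convention).
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), numeric(1))
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
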