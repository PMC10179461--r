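# Brute-force graph oracles, independent of the igraph-based implementation.
# Distances and shortest-path counts come from adjacency-matrix powers: the
# distance d(s,t) is the smallest k with (A^k)[s,t] > 0, and every walk of
# that minimal length is a shortest path, so (A^d)[s,t] counts them.

oracle_paths <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  sigma <- diag(1, n)
  P <- diag(1, n)
  for (k in seq_len(max(n - 1L, 1L))) {
    P <- P %*% A
    hit <- is.infinite(d) & P > 0
    d[hit] <- k
    sigma[hit] <- P[hit]
  }
  list(d = d, sigma = sigma)
}

oracle_betweenness <- function(A) {
  o <- oracle_paths(A)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (s == v || t == v || !is.finite(o$d[s, t])) next
      if (o$d[s, v] + o$d[v, t] == o$d[s, t])
        acc <- acc + o$sigma[s, v] * o$sigma[v, t] / o$sigma[s, t]
    }
    out[v] <- acc
  }
  out
}

oracle_stress <- function(A) {
  o <- oracle_paths(A)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (s == v || t == v || !is.finite(o$d[s, t])) next
      if (o$d[s, v] + o$d[v, t] == o$d[s, t])
        acc <- acc + o$sigma[s, v] * o$sigma[v, t]
    }
    out[v] <- acc
  }
  out
}

oracle_harmonic_closeness <- function(A) {
  d <- oracle_paths(A)$d
  diag(d) <- Inf
  rowSums(1 / d)
}

oracle_eccentricity_centrality <- function(A) {
  d <- oracle_paths(A)$d
  vapply(seq_len(nrow(A)), function(v) {
    reach <- is.finite(d[v, ]) & seq_len(nrow(A)) != v
    if (!any(reach)) return(0)
    1 / max(d[v, reach])
  }, numeric(1))
}

oracle_radiality <- function(A) {
  d <- oracle_paths(A)$d
  n <- nrow(A)
  comp_of <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp_of[v])) next
    cid <- cid + 1L
    comp_of[is.finite(d[v, ])] <- cid
  }
  out <- numeric(n)
  for (c_id in seq_len(cid)) {
    mem <- which(comp_of == c_id)
    if (length(mem) < 2L) next
    dc <- d[mem, mem, drop = FALSE]
    diam <- max(dc)
    for (i in seq_along(mem))
      out[mem[i]] <- sum(diam + 1 - dc[i, -i]) / (length(mem) - 1)
  }
  out
}

# maximal cliques of size >= 2 by exhaustive subset enumeration (n <= ~14)
oracle_cliques <- function(A, names) {
  n <- nrow(A)
  res <- list()
  for (mask in seq_len(2^n - 1L)) {
    mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(mem) < 2L) next
    sub <- A[mem, mem, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    others <- setdiff(seq_len(n), mem)
    if (any(vapply(others, function(o) all(A[o, mem] > 0), logical(1)))) next
    res[[length(res) + 1L]] <- sort(names[mem])
  }
  res[order(vapply(res, paste, "", collapse = "\r"))]
}

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A <- A + t(A)
  nm <- sprintf("n%02d", seq_len(n))
  dimnames(A) <- list(nm, nm)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  list(A = A, g = g, names = nm)
}
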