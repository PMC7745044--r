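# Independent brute-force oracles, deliberately written with different
# algorithms than the package (path enumeration, triple loops, step-up by
# hand) so agreement is informative.

# all-pairs shortest paths by exhaustive simple-path enumeration (small N)
oracle_shortest_enum <- function(l) {
  n <- nrow(l)
  best <- l
  best_path <- vector("list", n * n)
  idx <- function(i, j) (i - 1) * n + j
  for (i in seq_len(n)) for (j in seq_len(n))
    best_path[[idx(i, j)]] <- c(i, j)
  explore <- function(i, j) {
    # enumerate permutations of intermediate nodes
    others <- setdiff(seq_len(n), c(i, j))
    for (k in seq_along(others)) {
      combos <- utils::combn(others, k, simplify = FALSE)
      for (mid in combos) {
        perms <- perm_all(mid)
        for (p in perms) {
          path <- c(i, p, j)
          len <- sum(l[cbind(path[-length(path)], path[-1])])
          if (len < best[i, j] - 1e-15) {
            best[i, j] <<- len
            best_path[[idx(i, j)]] <<- path
          }
        }
      }
    }
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    explore(i, j)
    best[j, i] <- best[i, j]
  }
  list(dist = best, path = best_path, idx = idx)
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perm_all(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# igraph-based shortest-path distances (independent algorithm family)
oracle_shortest_igraph <- function(l) {
  g <- igraph::graph_from_adjacency_matrix(l, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, algorithm = "dijkstra")
}

# triple-loop weighted clustering (geometric-mean triangle intensity)
oracle_clustering <- function(w) {
  n <- nrow(w)
  diag(w) <- 0
  wn <- w / max(w)
  per <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    per[i] <- acc / (k * (k - 1))
  }
  list(cc = mean(per), per_node = per)
}

# efficiency and path length by double loops over a distance matrix
oracle_lambda <- function(d) {
  n <- nrow(d)
  tot <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i) s <- s + d[i, j]
    tot <- tot + s / (n - 1)
  }
  tot / n
}

oracle_eglobal <- function(d) {
  n <- nrow(d)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j != i) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracle_elocal <- function(w, to_dist) {
  n <- nrow(w)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0 & seq_len(n) != i)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    d <- oracle_shortest_igraph(to_dist(sub))
    per[i] <- oracle_eglobal(d)
  }
  mean(per)
}

# Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- val
    prev <- val
  }
  adj
}

# closed-form sums of squares for a balanced two-way mixed design
# (one between factor g, one within factor s, n subjects per group)
oracle_mixed_anova_2x2 <- function(d) {
  # d: data.frame subject, group, state, value; balanced complete
  mu <- mean(d$value)
  subj <- unique(d$subject)
  groups <- unique(d$group)
  states <- unique(d$state)
  a <- length(groups); b <- length(states)
  n <- length(subj) / a
  m_g <- as.vector(tapply(d$value, d$group, mean))
  names(m_g) <- sort(unique(as.character(d$group)))
  m_s <- as.vector(tapply(d$value, d$state, mean))
  m_gs <- matrix(tapply(d$value, list(d$group, d$state), mean), a, b)
  m_subj <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, function(x) x[1])
  ss_g <- b * n * sum((m_g - mu)^2)
  ss_subj_within <- b * sum((m_subj - m_g[subj_group[names(m_subj)]])^2)
  ss_s <- a * n * sum((m_s - mu)^2)
  ss_gs <- n * sum((m_gs - outer(m_g, rep(1, b)) -
                      outer(rep(1, a), m_s) + mu)^2)
  ss_tot <- sum((d$value - mu)^2)
  ss_err <- ss_tot - ss_g - ss_subj_within - ss_s - ss_gs
  df_subj <- a * (n - 1)
  df_err <- a * (n - 1) * (b - 1)
  list(
    F_group = (ss_g / (a - 1)) / (ss_subj_within / df_subj),
    F_state = (ss_s / (b - 1)) / (ss_err / df_err),
    F_inter = (ss_gs / ((a - 1) * (b - 1))) / (ss_err / df_err),
    pes_group = ss_g / (ss_g + ss_subj_within),
    pes_state = ss_s / (ss_s + ss_err),
    pes_inter = ss_gs / (ss_gs + ss_err))
}
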