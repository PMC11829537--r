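# Independent brute-force oracles used to check the package's statistics.
# Each one recomputes the quantity from first principles (enumeration or
# the literal defining formula) and deliberately shares no code with the
# implementation it checks.

# Gwet AC1 / wAC from the defining sums
ac1_oracle <- function(a, b, w = rep(1, length(a)), cats = c("+", "-", "0")) {
  W <- sum(w)
  pa <- 0
  for (i in seq_along(a)) if (a[i] == b[i]) pa <- pa + w[i]
  pa <- pa / W
  pe <- 0
  for (q in cats) {
    piq <- (sum(w[a == q]) + sum(w[b == q])) / (2 * W)
    pe <- pe + piq * (1 - piq)
  }
  pe <- pe / (length(cats) - 1)
  list(pa = pa, pe = pe, ac1 = (pa - pe) / (1 - pe))
}

# hypergeometric upper tail P(X >= q) by direct summation of the pmf
hyper_tail_oracle <- function(N, m, k, q) {
  xs <- seq(max(0, q), min(m, k))
  sum(choose(m, xs) * choose(N - m, k - xs)) / choose(N, k)
}

# exact one-sided (greater) Wilcoxon rank-sum p by enumerating all
# assignments of ranks to the first group (tie-free data only)
wilcox_enum_oracle <- function(x, y) {
  all_v <- c(x, y)
  stopifnot(!anyDuplicated(all_v))
  r <- rank(all_v)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  cmb <- utils::combn(length(all_v), nx)
  stats <- apply(cmb, 2, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

# normalized betweenness by explicit shortest-path enumeration
brute_betweenness_oracle <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(d[s, t]) || d[s, t] <= 1) next
      total <- 0
      through <- numeric(n)
      rec <- function(v, interior) {
        if (v == t) {
          total <<- total + 1
          for (u in interior) through[u] <<- through[u] + 1
          return(invisible())
        }
        for (u in adj[[v]]) {
          if (d[s, u] == d[s, v] + 1 && d[u, t] == d[s, t] - d[s, v] - 1) {
            rec(u, if (u == t) interior else c(interior, u))
          }
        }
      }
      rec(s, integer(0))
      btw <- btw + through / total
    }
  }
  stats::setNames(btw / ((n - 1) * (n - 2) / 2), igraph::V(g)$name)
}
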