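# independent oracles used across test files

# brute-force spanning-subtree length: materialize the root-to-leaf edge set
# for every present species and sum the union (deliberately different from
# the package's descendant-set algorithm)
bf_branch_length <- function(tree, present) {
  if (length(present) == 0L) return(0)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_edge <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) parent_edge[tree$edge[e, 2L]] <- e
  used <- logical(nrow(tree$edge))
  for (sp in present) {
    node <- match(sp, tree$tip.label)
    while (node != root) {
      e <- parent_edge[node]
      used[e] <- TRUE
      node <- tree$edge[e, 1L]
    }
  }
  sum(tree$edge.length[used])
}

# direct counting percent rank: (# strictly more constrained + half the
# other ties) over n - 1, times 100
count_percentile_oracle <- function(values, orientation) {
  s <- if (orientation == "low_is_constrained") -values else values
  n <- length(s)
  vapply(s, function(v)
    (sum(s < v) + 0.5 * (sum(s == v) - 1)) / (n - 1) * 100, 0)
}

# explicit hypergeometric upper-tail sum
hyper_tail_oracle <- function(k, size_a, size_b, universe) {
  i <- k:min(size_a, size_b)
  sum(choose(size_a, i) * choose(universe - size_a, size_b - i)) /
    choose(universe, size_b)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
# (untied data, small groups only)
mw_exact_oracle <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  obs <- u_stat(seq_len(n))
  all_u <- combn(length(pooled), n, u_stat)
  lo <- mean(all_u <= obs)
  hi <- mean(all_u >= obs)
  min(1, 2 * min(lo, hi))
}

# mean-1 log-normal noise matching the generators' parameterization
lnorm_mean1 <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
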