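# Independent oracles, kept deliberately separate from the package's own
# algorithms: a lattice-graph shortest path via igraph, exhaustive sign-flip
# and permutation enumerations for the rank tests, and the textbook
# chi-square formula.

# igraph shortest-path oracle on a water grid, using the same move set
# (orthogonal / diagonal / guarded knight) but an entirely different
# path algorithm and graph representation.
oracle_grid_distance <- function(water, cell, connectivity, from_rc, to_rc) {
  nr <- nrow(water); nc <- ncol(water)
  id <- function(r, c) (c - 1L) * nr + r
  edges <- NULL
  weights <- NULL
  add_move <- function(dr, dc, w, guards = NULL) {
    rs <- seq_len(nr)
    cs <- seq_len(nc)
    r1 <- rep(rs, times = nc); c1 <- rep(cs, each = nr)
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- water[cbind(r1[ok], c1[ok])] & water[cbind(r2[ok], c2[ok])]
    if (!is.null(guards)) {
      for (g in guards) {
        rg <- r1 + g[1]; cg <- c1 + g[2]
        gok <- rg >= 1 & rg <= nr & cg >= 1 & cg <= nc
        gval <- rep(FALSE, length(r1))
        gval[gok] <- water[cbind(rg[gok], cg[gok])]
        ok <- ok & gval
      }
    }
    if (any(ok)) {
      edges <<- rbind(edges, cbind(id(r1[ok], c1[ok]), id(r2[ok], c2[ok])))
      weights <<- c(weights, rep(w, sum(ok)))
    }
  }
  add_move(1, 0, cell); add_move(0, 1, cell)
  add_move(1, 1, cell * sqrt(2)); add_move(1, -1, cell * sqrt(2))
  if (connectivity == 16) {
    add_move(1, 2, cell * sqrt(5), list(c(0, 1), c(1, 1)))
    add_move(1, -2, cell * sqrt(5), list(c(0, -1), c(1, -1)))
    add_move(2, 1, cell * sqrt(5), list(c(1, 0), c(1, 1)))
    add_move(2, -1, cell * sqrt(5), list(c(1, 0), c(1, -1)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  igraph::distances(g, v = id(from_rc[1], from_rc[2]),
                    to = id(to_rc[1], to_rc[2]), weights = weights)[1, 1]
}

# exhaustive sign-flip null for the signed-rank statistic
oracle_wilcoxon_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- signs %*% r
  mu <- sum(r) / 2
  switch(alternative,
    less = mean(vs <= v_obs + 1e-9),
    greater = mean(vs >= v_obs - 1e-9),
    two.sided = mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-9)
  )
}

# permutation generation by iterative insertion (distinct from the package's
# recursive generator)
oracle_perms <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    p <- do.call(rbind, lapply(seq_len(k), function(pos) {
      cbind(p[, seq_len(pos - 1), drop = FALSE], k,
            p[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    }))
  }
  p
}

# tau-b by outer-product sign counting
oracle_tau <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  S <- sum(sx * sy * upper.tri(sx))
  n1 <- sum((sx != 0) & upper.tri(sx))
  n2 <- sum((sy != 0) & upper.tri(sy))
  S / sqrt(n1 * n2)
}

oracle_kendall_p <- function(x, y, alternative = "two.sided") {
  n <- length(x)
  perms <- oracle_perms(n)
  tau_obs <- oracle_tau(x, y)
  taus <- apply(perms, 1, function(idx) oracle_tau(x, y[idx]))
  switch(alternative,
    two.sided = mean(abs(taus) >= abs(tau_obs) - 1e-12),
    greater = mean(taus >= tau_obs - 1e-12),
    less = mean(taus <= tau_obs + 1e-12)
  )
}

oracle_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - E)^2 / E)
}
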