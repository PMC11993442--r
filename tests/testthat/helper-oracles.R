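# Independent oracles used to cross-check the package implementations.
# These deliberately use brute-force / direct-formula routes and share no
# code with the package.

# Minimal single-component PLS1: centre, one NIPALS component, predict.
pls1Oracle <- function(xTrain, yCoded, xNew) {
  xc <- colMeans(xTrain)
  yc <- mean(yCoded)
  e <- sweep(xTrain, 2, xc)
  y0 <- yCoded - yc
  w <- drop(crossprod(e, y0))
  w <- w / sqrt(sum(w^2))
  t <- drop(e %*% w)
  cc <- sum(y0 * t) / sum(t^2)
  drop(sweep(xNew, 2, xc) %*% w) * cc + yc
}

# Brute-force BH step-up from the definition.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m / seq_len(m) * p[o]
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# All ten topology metrics from an adjacency matrix, via BFS and direct
# triangle counting. Row/column order of `adj` defines the vertex order
# (must be the sorted node order used by PeriodNetwork).
bruteGraphMetrics <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  nE <- sum(adj) / 2
  density <- if (n >= 2) 2 * nE / (n * (n - 1)) else 0

  localCC <- vapply(seq_len(n), function(i) {
    if (deg[i] < 2) return(0)
    nb <- which(adj[i, ] == 1)
    links <- sum(adj[nb, nb]) / 2
    links / (deg[i] * (deg[i] - 1) / 2)
  }, numeric(1))

  bfs <- function(start) {
    d <- rep(Inf, n)
    d[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in which(adj[v, ] == 1)) {
        if (!is.finite(d[u])) {
          d[u] <- d[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    d
  }
  dist <- t(vapply(seq_len(n), bfs, numeric(n)))

  seen <- rep(FALSE, n)
  compId <- integer(n)
  nComp <- 0L
  for (v in seq_len(n)) {
    if (!seen[v]) {
      nComp <- nComp + 1L
      members <- which(is.finite(dist[v, ]))
      seen[members] <- TRUE
      compId[members] <- nComp
    }
  }
  sizes <- tabulate(compId)
  largest <- which(compId == which.max(sizes))
  ecc <- vapply(largest, function(v) max(dist[v, largest]), numeric(1))

  ut <- dist[upper.tri(dist)]
  finite <- ut[is.finite(ut)]
  cpl <- if (length(finite)) mean(finite) else NA_real_

  meanDeg <- mean(deg)
  het <- if (meanDeg > 0) sqrt(mean(deg^2) - meanDeg^2) / meanDeg else 0
  central <- if (n >= 3) (n / (n - 2)) * (max(deg) / (n - 1) - density) else 0

  data.frame(
    n_nodes = n, n_edges = nE, avg_neighbors = 2 * nE / n,
    diameter = max(ecc), radius = min(ecc), char_path_length = cpl,
    clustering_coefficient = mean(localCC), density = density,
    heterogeneity = het, centralization = central, n_components = nComp
  )
}

# Build a PeriodNetwork from a 0/1 adjacency matrix (sorted node names),
# keeping isolated nodes in the node set.
networkFromAdjacency <- function(adj, period = "toy") {
  n <- nrow(adj)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- if (nrow(idx)) {
    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
               r = 0.9, p = 1e-6, fdr = 1e-4, sign = "pos",
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), r = numeric(0),
               p = numeric(0), fdr = numeric(0), sign = character(0),
               stringsAsFactors = FALSE)
  }
  methods::new("PeriodNetwork", period = period, nodes = nodes, edges = edges)
}

# Hand-built PeriodNetwork from an explicit edge list (from/to vectors).
networkFromEdges <- function(from, to, period = "toy", r = 0.9,
                             extraNodes = character(0)) {
  stopifnot(length(from) == length(to))
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  o <- order(from, to)
  edges <- data.frame(from = from[o], to = to[o],
                      r = rep_len(r, length(from))[o],
                      p = 1e-6, fdr = 1e-4,
                      sign = ifelse(rep_len(r, length(from))[o] >= 0, "pos", "neg"),
                      stringsAsFactors = FALSE)
  methods::new("PeriodNetwork", period = period,
               nodes = sort(unique(c(from, to, extraNodes))), edges = edges)
}
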