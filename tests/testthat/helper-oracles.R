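# Shared fixtures and independent oracles for the test suite.

# tiny graphs built in code
triangleGraph <- function() {
  f <- tempfile()
  writeLines(c("1 2", "2 3", "3 1"), f)
  readEdgelist(f)
}

pathGraph <- function(n) {
  f <- tempfile()
  writeLines(paste(seq_len(n - 1), seq_len(n - 1) + 1), f)
  readEdgelist(f)
}

starGraph <- function(nLeaves) {
  f <- tempfile()
  writeLines(paste("0", seq_len(nLeaves)), f)
  readEdgelist(f)
}

completeGraph <- function(n) {
  pairs <- t(combn(n, 2))
  f <- tempfile()
  writeLines(paste(pairs[, 1], pairs[, 2]), f)
  readEdgelist(f)
}

# independent breadth-first-search distances (adjacency-list queue walk;
# no igraph machinery)
bfsDistances <- function(g) {
  nodes <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (!is.finite(dist[nb])) {
          dist[nb] <- dist[cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# textbook reimplementation of WGSS via mean pairwise squared distances:
# WGSS(c) = (1 / (2 n_c)) * sum_{i,j in c} ||x_i - x_j||^2
wgssOracle <- function(x, labels) {
  x <- x[names(labels), , drop = FALSE]
  cls <- sort(unique(labels))
  out <- vapply(cls, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    if (nrow(xc) == 1L) return(0)
    d2 <- as.matrix(dist(xc))^2
    sum(d2) / (2 * nrow(xc))
  }, numeric(1))
  setNames(out, as.character(cls))
}

# textbook CH from the total/within decomposition: BGSS = TSS - WGSS
chOracle <- function(x, labels) {
  x <- x[names(labels), , drop = FALSE]
  n <- nrow(x)
  K <- length(unique(labels))
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  within <- sum(wgssOracle(x, labels))
  ((tss - within) / (K - 1)) / (within / (n - K))
}

# small random connected-ish graph for oracle sweeps
randomGraph <- function(n, pEdge, seed) {
  pairs <- t(combn(n, 2))
  set.seed(seed)
  keep <- runif(nrow(pairs)) < pEdge
  if (!any(keep)) keep[1] <- TRUE
  f <- tempfile()
  writeLines(paste(pairs[keep, 1], pairs[keep, 2]), f)
  readEdgelist(f)
}

karateCache <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- karateFixture()
    g
  }
})

# the 10-seed karate experiment is used by several acceptance checks;
# compute it once per test run
karateComparisonCache <- local({
  res <- NULL
  function() {
    if (is.null(res)) res <<- karateComparison(seeds = 1:10,
                                               fusionRatio = 0.5)
    res
  }
})
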