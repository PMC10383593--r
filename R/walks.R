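#' Generate a random-walk corpus
#'
#' Starts \code{walksPerNode} truncated walks of length \code{walkLength}
#' from every node; the node start order is reshuffled on every pass.
#' The uniform strategy picks a uniformly random neighbor each step; the
#' biased strategy is a second-order walk with unnormalized transition
#' weights 1/returnP (step back), 1 (stay at distance 1 from the previous
#' node), and 1/inoutQ (move to distance 2). Walks stop early at
#' isolated or dead-end-free nodes (an isolated node yields a length-1
#' walk). Deterministic given the configuration seed.
#'
#' @param g a non-empty igraph.
#' @param cfg a \linkS4class{WalkConfig}.
#' @return A \linkS4class{WalkCorpus}.
#' @examples
#' corp <- generateWalks(karateFixture(),
#'   walkConfig(walksPerNode = 2, walkLength = 5, seed = 1))
#' length(corp@walks)  # 68
#' @export
generateWalks <- function(g, cfg) {
  if (vcount(g) == 0L) stop("graph has no nodes")
  validObject(cfg)
  nodes <- V(g)$name
  adj <- lapply(as_adj_list(g, mode = "all"), function(vs) as.integer(vs))
  names(adj) <- NULL
  n <- length(nodes)
  walks <- withSeed(cfg@seed, {
    out <- vector("list", n * cfg@walksPerNode)
    k <- 0L
    for (pass in seq_len(cfg@walksPerNode)) {
      for (start in sample.int(n)) {
        k <- k + 1L
        out[[k]] <- if (cfg@strategy == "uniform")
          uniformWalk(start, adj, cfg@walkLength)
        else
          biasedWalk(start, adj, cfg@walkLength, cfg@returnP, cfg@inoutQ)
      }
    }
    out
  })
  new("WalkCorpus", walks = lapply(walks, function(w) nodes[w]),
      nodes = nodes, config = cfg)
}

uniformWalk <- function(start, adj, len) {
  walk <- integer(len)
  walk[1] <- start
  cur <- start
  for (i in seq_len(len - 1L)) {
    nb <- adj[[cur]]
    if (length(nb) == 0L) return(walk[seq_len(i)])
    cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    walk[i + 1L] <- cur
  }
  walk
}

biasedWalk <- function(start, adj, len, returnP, inoutQ) {
  walk <- integer(len)
  walk[1] <- start
  if (len == 1L) return(walk)
  nb <- adj[[start]]
  if (length(nb) == 0L) return(walk[1])
  cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
  walk[2] <- cur
  prev <- start
  for (i in seq_len(len - 2L)) {
    nb <- adj[[cur]]
    if (length(nb) == 0L) return(walk[seq_len(i + 1L)])
    w <- numeric(length(nb))
    prevNb <- adj[[prev]]
    for (j in seq_along(nb)) {
      x <- nb[j]
      w[j] <- if (x == prev) 1 / returnP
              else if (x %in% prevNb) 1
              else 1 / inoutQ
    }
    nxt <- nb[sample.int(length(nb), 1L, prob = w)]
    prev <- cur; cur <- nxt
    walk[i + 2L] <- cur
  }
  walk
}

#' Extract (center, context) training pairs from a walk corpus
#'
#' For every position in every walk, an effective window b is drawn
#' uniformly from 1..m when \code{shrink = TRUE} (the word2vec shrinking
#' window), else b = m; the position's node is paired with every node
#' within b positions on either side. Deterministic given the seed.
#'
#' @param corpus a \linkS4class{WalkCorpus}.
#' @param m window size (defaults to the corpus config's window).
#' @param seed integer seed for the shrinking-window draws.
#' @param shrink logical; draw a random effective window per position.
#' @return Integer matrix with columns \code{center}, \code{context}
#'   holding row indices into \code{corpus@nodes}.
#' @examples
#' corp <- new("WalkCorpus", walks = list(c("1", "2", "3")),
#'             nodes = c("1", "2", "3"), config = walkConfig())
#' contextPairs(corp, m = 1, shrink = FALSE)
#' @export
contextPairs <- function(corpus, m = NULL, seed = 1, shrink = TRUE) {
  if (is.null(m)) m <- corpus@config@window
  m <- as.integer(m)
  if (m < 1L) stop("'m' must be >= 1")
  nodeIndex <- seq_along(corpus@nodes)
  names(nodeIndex) <- corpus@nodes
  walksIdx <- lapply(corpus@walks, function(w) unname(nodeIndex[w]))
  res <- withSeed(as.integer(seed), {
    centers <- vector("list", length(walksIdx))
    contexts <- vector("list", length(walksIdx))
    for (wi in seq_along(walksIdx)) {
      w <- walksIdx[[wi]]
      T <- length(w)
      if (T < 2L) next
      b <- if (shrink) sample.int(m, T, replace = TRUE) else rep(m, T)
      cs <- vector("list", T)
      xs <- vector("list", T)
      for (i in seq_len(T)) {
        lo <- max(1L, i - b[i]); hi <- min(T, i + b[i])
        ctx <- w[setdiff(lo:hi, i)]
        ctx <- ctx[ctx != w[i]]   # a walk may revisit the center node
        cs[[i]] <- rep.int(w[i], length(ctx))
        xs[[i]] <- ctx
      }
      centers[[wi]] <- unlist(cs, use.names = FALSE)
      contexts[[wi]] <- unlist(xs, use.names = FALSE)
    }
    cbind(center = unlist(centers, use.names = FALSE),
          context = unlist(contexts, use.names = FALSE))
  })
  if (is.null(res) || nrow(res) == 0L)
    res <- cbind(center = integer(0), context = integer(0))
  res
}

#' Per-node sampling statistics from a training run
#'
#' Counts of how often each node appeared as the walk center (PosV), as a
#' context word (PosC), and as a negative sample (Neg) during training.
#' These counts track node degree closely: high-degree hubs are sampled
#' (and therefore updated) far more often than peripheral nodes.
#'
#' @param fit a training result from \code{\link{trainEmbeddings}} run
#'   with \code{statsEnabled = TRUE}.
#' @return A data.frame with columns \code{node}, \code{PosV},
#'   \code{PosC}, \code{Neg}.
#' @export
samplingStatistics <- function(fit) {
  st <- attr(fit, "stats")
  if (is.null(st))
    stop("training was run without statistics; set statsEnabled = TRUE")
  st
}
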