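#' Node degrees
#'
#' Degree = number of incident edges (edge multiplicity 1 in the simple
#' graphs this package uses; weights do not enter).
#'
#' @param g an igraph.
#' @return Named integer vector of degrees in the graph's node order.
#' @export
computeDegrees <- function(g) {
  d <- degree(g, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' Shortest-path matrix
#'
#' Hop counts on unweighted graphs, Dijkstra path lengths on weighted
#' ones; unreachable pairs get \code{Inf}. With \code{sources} given,
#' only those rows are computed.
#'
#' @param g an igraph (positive weights if weighted).
#' @param sources optional character vector of source node names.
#' @return Numeric matrix of distances (rows = sources or all nodes).
#' @export
computeShortestPaths <- function(g, sources = NULL) {
  if (is.null(sources)) distances(g)
  else distances(g, v = sources)
}

#' Estimate the shortest-path length distribution by source sampling
#'
#' Computes single-source distances from \code{nSourceSamples} uniformly
#' sampled sources (without replacement, capped at |V|) and returns the
#' normalized histogram over finite positive distances. Used to choose
#' the distance scale when the full matrix is too costly.
#'
#' @param g an igraph with at least one node.
#' @param nSourceSamples number of source nodes to sample (>= 1).
#' @param seed integer seed.
#' @return Named numeric vector: distance value -> relative frequency
#'   (sums to 1).
#' @export
estimateDistanceDistribution <- function(g, nSourceSamples = 10, seed = 1) {
  if (vcount(g) == 0L) stop("graph has no nodes")
  if (nSourceSamples < 1L) stop("'nSourceSamples' must be >= 1")
  nodes <- V(g)$name
  src <- withSeed(as.integer(seed),
                  sample(nodes, size = min(nSourceSamples, length(nodes))))
  D <- distances(g, v = src)
  vals <- D[is.finite(D) & D > 0]
  if (length(vals) == 0L)
    return(setNames(numeric(0), character(0)))
  tab <- table(vals)
  h <- as.numeric(tab) / sum(tab)
  names(h) <- names(tab)
  h
}

#' Choose the distance scale from a path-length histogram
#'
#' Returns (maximum observed finite distance) + 1, so that every
#' reachable pair satisfies \eqn{P_{un} \le p - 1} and the distance term
#' \eqn{2 - 2 P_{un} / p} of the structure function stays positive.
#'
#' @param hist histogram from \code{\link{estimateDistanceDistribution}}
#'   (values named by distance).
#' @return The distance scale p (a single numeric).
#' @examples
#' chooseDistanceScale(c(`1` = 0.4, `2` = 0.5, `6` = 0.1))  # 7
#' @export
chooseDistanceScale <- function(hist) {
  if (length(hist) == 0L) stop("empty distance histogram")
  max(as.numeric(names(hist))) + 1
}

#' Precompute structure information for a graph
#'
#' Bundles degrees, the dense shortest-path matrix and the structure
#' parameters into a \linkS4class{StructureInfo} for use by the
#' graph-mode trainer.
#'
#' @param g an igraph.
#' @param params a \linkS4class{StructureParams}; when
#'   \code{autoScale = TRUE} the distance scale is replaced by the value
#'   chosen from the full distance distribution of \code{g}.
#' @param autoScale logical; pick the distance scale from the graph.
#' @return A \linkS4class{StructureInfo}.
#' @examples
#' info <- structureInfo(karateFixture(), structureParams(w = 0.8,
#'   distanceScale = 5, a = 1))
#' @export
structureInfo <- function(g, params = structureParams(), autoScale = FALSE) {
  P <- computeShortestPaths(g)
  if (autoScale) {
    fin <- P[is.finite(P) & P > 0]
    if (length(fin) == 0L) stop("graph has no reachable pairs")
    params@distanceScale <- max(fin) + 1
  }
  new("StructureInfo", degrees = computeDegrees(g), distMatrix = P,
      params = params)
}

#' Reachability indicator
#'
#' L(u,n) = 1 when a finite positive-length path joins u and n, else 0
#' (self pairs and cross-component pairs). Pairs observed as positive
#' samples in a walk are reachable by construction, so the trainer's
#' forced L = 1 for positive pairs coincides with this definition.
#'
#' @param u,n node names.
#' @param info a \linkS4class{StructureInfo}.
#' @return 0 or 1.
#' @export
reachability <- function(u, n, info) {
  d <- info@distMatrix[u, n]
  as.integer(is.finite(d) && d > 0)
}

#' The graph-structure information function W(n, u)
#'
#' For a reachable center/context pair (u = center), the closeness score
#' \deqn{W = w \cdot \mathrm{clamp}(D_u / D_n,\ [l, h]) +
#'   (1 - w) \cdot \max(0,\ 2 - 2 P_{un} / p)^a}
#' plus \eqn{w' \cdot \mathrm{weight}(u, n)} when \code{g} is weighted
#' and the edge exists. Larger for close pairs and for centers of higher
#' degree than their context (within the clamp interval). The base of the
#' distance term is floored at 0 so fractional exponents never see a
#' negative base.
#'
#' @param u center node name; \code{n} context node name.
#' @param n context node name.
#' @param info a \linkS4class{StructureInfo}.
#' @param g optional igraph, needed only for the edge-weight term of
#'   weighted graphs (\code{wPrime > 0}).
#' @return A single nonnegative finite numeric.
#' @examples
#' info <- structureInfo(karateFixture(),
#'   structureParams(w = 0.8, distanceScale = 5, a = 1))
#' structureWeight("34", "8", info)
#' @export
structureWeight <- function(u, n, info, g = NULL) {
  p <- info@params
  d <- info@distMatrix[u, n]
  if (!is.finite(d) || d <= 0)
    stop("structureWeight() requires a reachable pair (u != n); ",
         "unreachable pairs take multiplier 1 via the reachability exponent")
  ratio <- info@degrees[[u]] / info@degrees[[n]]
  ratio <- min(max(ratio, p@degreeRatioBounds[1]), p@degreeRatioBounds[2])
  distTerm <- max(0, 2 - 2 * d / p@distanceScale)^p@a
  W <- p@w * ratio + (1 - p@w) * distTerm
  if (p@wPrime > 0 && !is.null(g) && "weight" %in% igraph::edge_attr_names(g)) {
    eid <- get_edge_ids(g, c(u, n), error = FALSE)
    if (eid > 0) W <- W + p@wPrime * E(g)$weight[eid]
  }
  W
}

# Dense |V| x |V| multiplier matrix M[u, n] = W(n, u)^L(n, u):
# the structure weight where a finite positive path exists, 1 elsewhere
# (self pairs, cross-component pairs). Rows index the walk center u.
structureMultiplier <- function(info, g = NULL) {
  p <- info@params
  P <- info@distMatrix
  D <- as.numeric(info@degrees)
  ratio <- outer(D, D, "/")  # ratio[u, n] = Du / Dn
  ratio <- pmin(pmax(ratio, p@degreeRatioBounds[1]), p@degreeRatioBounds[2])
  distTerm <- pmax(0, 2 - 2 * P / p@distanceScale)^p@a
  W <- p@w * ratio + (1 - p@w) * distTerm
  if (p@wPrime > 0 && !is.null(g) &&
      "weight" %in% igraph::edge_attr_names(g)) {
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    W <- W + p@wPrime * A
  }
  L0 <- !is.finite(P) | P <= 0
  W[L0] <- 1
  dimnames(W) <- dimnames(P)
  W
}
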