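#' @import methods
#' @importFrom stats cor setNames
#' @importFrom utils head
NULL

#' Parameters of the graph-structure information function
#'
#' Bundles the hyperparameters of the structure weight
#' \eqn{W(n,u) = w \cdot \mathrm{clamp}(D_u/D_n) + (1-w)(2 - 2 P_{un}/p)^a
#' [+ w' \cdot \mathrm{weight}(u,n)]}: the degree/distance mixing weight
#' \code{w}, the distance scale \code{p} (all reachable pairs should satisfy
#' \eqn{P_{un} \le p - 1}), the distance-term exponent \code{a}, the edge
#' weight coefficient \code{wPrime} used on weighted graphs, and the clamp
#' interval for the degree ratio (default \eqn{[1, 1.1]}).
#'
#' @slot w numeric in (0,1); weight of the degree-ratio term.
#' @slot distanceScale numeric > 1; the scale \code{p} of the distance term.
#' @slot a numeric > 0; exponent applied to the distance term.
#' @slot wPrime numeric >= 0; coefficient of the edge-weight term.
#' @slot degreeRatioBounds numeric length-2 clamp interval for \eqn{D_u/D_n}.
#' @exportClass StructureParams
setClass("StructureParams",
  representation(w = "numeric", distanceScale = "numeric", a = "numeric",
                 wPrime = "numeric", degreeRatioBounds = "numeric"),
  prototype(w = 0.8, distanceScale = 5, a = 1, wPrime = 0,
            degreeRatioBounds = c(1, 1.1)))

setValidity("StructureParams", function(object) {
  msg <- character()
  if (length(object@w) != 1L || is.na(object@w) ||
      object@w <= 0 || object@w >= 1)
    msg <- c(msg, "'w' must be a single value in (0, 1)")
  if (length(object@distanceScale) != 1L || object@distanceScale <= 1)
    msg <- c(msg, "'distanceScale' must be a single value > 1")
  if (length(object@a) != 1L || object@a <= 0)
    msg <- c(msg, "'a' must be a single positive value")
  if (length(object@wPrime) != 1L || object@wPrime < 0)
    msg <- c(msg, "'wPrime' must be a single nonnegative value")
  b <- object@degreeRatioBounds
  if (length(b) != 2L || any(is.na(b)) || b[1] > b[2])
    msg <- c(msg, "'degreeRatioBounds' must be c(lower, upper) with lower <= upper")
  if (length(msg)) msg else TRUE
})

#' Construct structure-function parameters
#'
#' @param w degree/distance mixing weight in (0,1).
#' @param distanceScale distance scale \code{p} (> 1).
#' @param a distance-term exponent (> 0).
#' @param wPrime edge-weight coefficient (>= 0); only used on weighted graphs.
#' @param degreeRatioBounds clamp interval for the degree ratio.
#' @return A \linkS4class{StructureParams} object.
#' @examples
#' structureParams(w = 0.8, distanceScale = 5, a = 1)
#' @export
structureParams <- function(w = 0.8, distanceScale = 5, a = 1, wPrime = 0,
                            degreeRatioBounds = c(1, 1.1)) {
  new("StructureParams", w = as.numeric(w),
      distanceScale = as.numeric(distanceScale), a = as.numeric(a),
      wPrime = as.numeric(wPrime),
      degreeRatioBounds = as.numeric(degreeRatioBounds))
}

#' Precomputed graph-structure information
#'
#' Holds the node degree vector \code{D}, the shortest-path matrix \code{P}
#' (hop counts on unweighted graphs; \code{Inf} marks unreachable pairs),
#' and the \linkS4class{StructureParams} used to evaluate the structure
#' weight. Created by \code{\link{structureInfo}}.
#'
#' @slot degrees integer vector of node degrees, named by node.
#' @slot distMatrix numeric matrix of shortest-path lengths; \code{Inf}
#'   for unreachable pairs, 0 on the diagonal.
#' @slot params a \linkS4class{StructureParams}.
#' @exportClass StructureInfo
setClass("StructureInfo",
  representation(degrees = "integer", distMatrix = "matrix",
                 params = "StructureParams"))

setValidity("StructureInfo", function(object) {
  msg <- character()
  P <- object@distMatrix
  if (nrow(P) != ncol(P)) msg <- c(msg, "'distMatrix' must be square")
  if (nrow(P) != length(object@degrees))
    msg <- c(msg, "'degrees' length must match 'distMatrix' dimension")
  if (nrow(P) > 0) {
    if (any(diag(P) != 0)) msg <- c(msg, "self-distances must be zero")
    fin <- P[is.finite(P)]
    if (length(fin) && any(fin < 0)) msg <- c(msg, "distances must be nonnegative")
    if (!isTRUE(all.equal(P, t(P)))) msg <- c(msg, "'distMatrix' must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' A corpus of random walks
#'
#' The node sequences produced by a walk strategy, plus the configuration
#' that generated them. Walks are character vectors of node names; pairs
#' for training are drawn from them with \code{\link{contextPairs}}.
#'
#' @slot walks list of character vectors, one per walk.
#' @slot nodes character vector: the node universe (row order of embeddings).
#' @slot config the \linkS4class{WalkConfig} used.
#' @exportClass WalkCorpus
setClass("WalkCorpus",
  representation(walks = "list", nodes = "character", config = "ANY"))

#' Random-walk configuration
#'
#' @slot walksPerNode integer r >= 1.
#' @slot walkLength integer t >= 1.
#' @slot window integer m >= 1.
#' @slot strategy "uniform" (first-order) or "biased" (second-order with
#'   return parameter \code{returnP} and in-out parameter \code{inoutQ}).
#' @slot returnP numeric > 0.
#' @slot inoutQ numeric > 0.
#' @slot seed integer.
#' @exportClass WalkConfig
setClass("WalkConfig",
  representation(walksPerNode = "integer", walkLength = "integer",
                 window = "integer", strategy = "character",
                 returnP = "numeric", inoutQ = "numeric", seed = "integer"),
  prototype(walksPerNode = 80L, walkLength = 10L, window = 10L,
            strategy = "uniform", returnP = 1, inoutQ = 1, seed = 1L))

setValidity("WalkConfig", function(object) {
  msg <- character()
  if (object@walksPerNode < 1L) msg <- c(msg, "'walksPerNode' must be >= 1")
  if (object@walkLength < 1L) msg <- c(msg, "'walkLength' must be >= 1")
  if (object@window < 1L) msg <- c(msg, "'window' must be >= 1")
  if (!object@strategy %in% c("uniform", "biased"))
    msg <- c(msg, "'strategy' must be 'uniform' or 'biased'")
  if (object@strategy == "biased" && (object@returnP <= 0 || object@inoutQ <= 0))
    msg <- c(msg, "'returnP' and 'inoutQ' must be positive for biased walks")
  if (length(msg)) msg else TRUE
})

#' Construct a walk configuration
#'
#' Defaults follow common practice for large benchmark networks
#' (window 10, 80 walks per node, walk length 10); the small-network
#' demonstrations in this package override them (window 5, 40 walks of
#' length 40).
#'
#' @param walksPerNode walks started from every node (r).
#' @param walkLength maximum walk length (t).
#' @param window context window size (m).
#' @param strategy "uniform" or "biased" (second-order) neighbor choice.
#' @param returnP,inoutQ bias parameters of the second-order walk.
#' @param seed integer seed controlling the walk randomness.
#' @return A \linkS4class{WalkConfig}.
#' @examples
#' walkConfig(walksPerNode = 40, walkLength = 40, window = 5, seed = 1)
#' @export
walkConfig <- function(walksPerNode = 80, walkLength = 10, window = 10,
                       strategy = c("uniform", "biased"),
                       returnP = 1, inoutQ = 1, seed = 1) {
  strategy <- match.arg(strategy)
  new("WalkConfig", walksPerNode = as.integer(walksPerNode),
      walkLength = as.integer(walkLength), window = as.integer(window),
      strategy = strategy, returnP = as.numeric(returnP),
      inoutQ = as.numeric(inoutQ), seed = as.integer(seed))
}

#' Training configuration for the embedding model
#'
#' @slot dim embedding dimension d.
#' @slot negatives negative samples per positive pair (k).
#' @slot alpha0 initial learning rate.
#' @slot mode "vanilla" (plain skip-gram) or "graph" (structure-modulated).
#' @slot wInside logical; if TRUE the structure weight multiplies the score
#'   inside the sigmoid instead of the sigmoid's output.
#' @slot statsEnabled logical; collect per-node sampling counts.
#' @slot seed integer.
#' @slot threads integer; only 1 is supported (deterministic training).
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(dim = "integer", negatives = "integer", alpha0 = "numeric",
                 mode = "character", wInside = "logical",
                 statsEnabled = "logical", seed = "integer",
                 threads = "integer"),
  prototype(dim = 128L, negatives = 5L, alpha0 = 0.025, mode = "vanilla",
            wInside = FALSE, statsEnabled = TRUE, seed = 1L, threads = 1L))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@dim < 1L) msg <- c(msg, "'dim' must be >= 1")
  if (object@negatives < 0L) msg <- c(msg, "'negatives' must be >= 0")
  if (object@alpha0 <= 0 || object@alpha0 > 1)
    msg <- c(msg, "'alpha0' must be in (0, 1]")
  if (!object@mode %in% c("vanilla", "graph"))
    msg <- c(msg, "'mode' must be 'vanilla' or 'graph'")
  if (object@threads != 1L)
    msg <- c(msg, "only single-threaded training is supported")
  if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' @param dim embedding dimension (default 128).
#' @param negatives negative samples per positive pair (default 5).
#' @param alpha0 initial learning rate (default 0.025; decays linearly).
#' @param mode "vanilla" or "graph".
#' @param wInside apply the structure weight inside the sigmoid
#'   (alternative reading of the scoring rule; default FALSE).
#' @param statsEnabled collect per-node PosV/PosC/Neg sampling counts.
#' @param seed integer seed for initialization and negative draws.
#' @param threads reserved; only 1 is supported.
#' @return A \linkS4class{TrainConfig}.
#' @examples
#' trainConfig(dim = 2, negatives = 1, mode = "graph")
#' @export
trainConfig <- function(dim = 128, negatives = 5, alpha0 = 0.025,
                        mode = c("vanilla", "graph"), wInside = FALSE,
                        statsEnabled = TRUE, seed = 1, threads = 1) {
  mode <- match.arg(mode)
  new("TrainConfig", dim = as.integer(dim), negatives = as.integer(negatives),
      alpha0 = as.numeric(alpha0), mode = mode, wInside = isTRUE(wInside),
      statsEnabled = isTRUE(statsEnabled), seed = as.integer(seed),
      threads = as.integer(threads))
}

#' Paired input/output node embeddings
#'
#' Skip-gram training learns two dense matrices over the same node index:
#' the input embedding \code{f} (updated when a node is the walk center)
#' and the output embedding \code{f'} (updated when it is a context or a
#' negative sample). Rows are nodes, columns are dimensions; both matrices
#' share the node order given by \code{nodes()}.
#'
#' @slot f numeric matrix |V| x d, input embedding; rownames are node names.
#' @slot fOut numeric matrix |V| x d, output embedding; same dimnames.
#' @exportClass EmbeddingSet
setClass("EmbeddingSet", representation(f = "matrix", fOut = "matrix"))

setValidity("EmbeddingSet", function(object) {
  msg <- character()
  if (!identical(dim(object@f), dim(object@fOut)))
    msg <- c(msg, "'f' and 'fOut' must have identical shape")
  if (is.null(rownames(object@f)))
    msg <- c(msg, "'f' must carry node names as rownames")
  if (!identical(rownames(object@f), rownames(object@fOut)))
    msg <- c(msg, "'f' and 'fOut' must share the same node order")
  if (ncol(object@f) < 1L) msg <- c(msg, "embedding dimension must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn EmbeddingSet-class construct an EmbeddingSet from two matrices.
#' @param f,fOut numeric matrices of identical shape; rownames = node names.
#' @export
embeddingSet <- function(f, fOut) {
  f <- as.matrix(f); fOut <- as.matrix(fOut)
  dimnames(fOut) <- dimnames(f)
  new("EmbeddingSet", f = f, fOut = fOut)
}

#' @describeIn EmbeddingSet-class the input embedding matrix f.
#' @param x an EmbeddingSet.
#' @export
inputEmbedding <- function(x) x@f

#' @describeIn EmbeddingSet-class the output embedding matrix f'.
#' @export
outputEmbedding <- function(x) x@fOut

#' @describeIn EmbeddingSet-class node names, in row order.
#' @export
embeddingNodes <- function(x) rownames(x@f)

#' @describeIn EmbeddingSet-class the embedding dimension d.
#' @export
embeddingDim <- function(x) ncol(x@f)

setMethod("show", "EmbeddingSet", function(object) {
  cat("EmbeddingSet:", nrow(object@f), "nodes x", ncol(object@f),
      "dimensions (input f + output f')\n")
  cat("  nodes:", paste(head(rownames(object@f), 5), collapse = ", "),
      if (nrow(object@f) > 5) "..." else "", "\n")
})

setMethod("show", "StructureInfo", function(object) {
  P <- object@distMatrix
  fin <- P[upper.tri(P)][is.finite(P[upper.tri(P)])]
  cat("StructureInfo:", length(object@degrees), "nodes\n")
  cat("  degree range:", min(object@degrees), "-", max(object@degrees), "\n")
  if (length(fin))
    cat("  finite shortest paths: max", max(fin), "\n")
  p <- object@params
  cat(sprintf("  params: w=%g, p=%g, a=%g, w'=%g\n",
              p@w, p@distanceScale, p@a, p@wPrime))
})

setMethod("show", "WalkCorpus", function(object) {
  cat("WalkCorpus:", length(object@walks), "walks over",
      length(object@nodes), "nodes\n")
})

setMethod("show", "StructureParams", function(object) {
  cat(sprintf("StructureParams: w=%g, p=%g, a=%g, w'=%g, ratio clamp [%g, %g]\n",
              object@w, object@distanceScale, object@a, object@wPrime,
              object@degreeRatioBounds[1], object@degreeRatioBounds[2]))
})
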