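#' @useDynLib gskipgram, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Initialize paired embeddings
#'
#' Input rows are i.i.d. uniform on [-0.5/d, 0.5/d]; the output matrix
#' starts at exactly zero. Since the two matrices converge toward each
#' other during training, this asymmetric start (random f, zero f')
#' accelerates early training.
#'
#' @param nodes character vector of node names (defines row order).
#' @param d embedding dimension.
#' @param seed integer seed.
#' @return An \linkS4class{EmbeddingSet}.
#' @examples
#' emb <- initEmbeddings(c("a", "b"), d = 4, seed = 1)
#' all(outputEmbedding(emb) == 0)  # TRUE
#' @export
initEmbeddings <- function(nodes, d, seed = 1) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  f <- withSeed(as.integer(seed),
                matrix(runif(n * d, -0.5 / d, 0.5 / d), n, d))
  rownames(f) <- nodes
  embeddingSet(f, matrix(0, n, d))
}

#' Build the negative-sampling noise distribution
#'
#' Node probability proportional to its corpus frequency raised to
#' \code{exponent} (default 0.75, the word2vec convention that flattens
#' the frequency distribution). Nodes absent from the corpus get
#' probability 0.
#'
#' @param corpus a \linkS4class{WalkCorpus}.
#' @param exponent frequency-smoothing exponent.
#' @return Numeric probability vector over \code{corpus@nodes}
#'   (sums to 1).
#' @examples
#' corp <- new("WalkCorpus", walks = list(rep("a", 16), "b"),
#'             nodes = c("a", "b"), config = walkConfig())
#' buildNoiseDistribution(corp)  # 8/9, 1/9
#' @export
buildNoiseDistribution <- function(corpus, exponent = 0.75) {
  if (length(corpus@walks) == 0L) stop("empty walk corpus")
  counts <- table(factor(unlist(corpus@walks, use.names = FALSE),
                         levels = corpus@nodes))
  p <- as.numeric(counts)^exponent
  p[as.numeric(counts) == 0] <- 0
  if (sum(p) == 0) stop("no nodes appear in the corpus")
  setNames(p / sum(p), corpus@nodes)
}

#' Structure-modulated co-occurrence score
#'
#' \eqn{A = \mathrm{clip}(\sigma(f'(n) \cdot f(u)) \cdot W^L,\ -1,\ 1)}:
#' the sigmoid of the input/output dot product, multiplied by the
#' structure weight W raised to the reachability indicator L, then
#' clipped to [-1, 1]. With L = 0 the multiplier is inert and A is the
#' plain sigmoid. With \code{wInside = TRUE} the multiplier scales the
#' score before the sigmoid instead.
#'
#' @param fU input-embedding row of the center node.
#' @param fOutN output-embedding row of the context node.
#' @param W structure weight (ignored when L = 0).
#' @param L reachability indicator, 0 or 1.
#' @param wInside apply W inside the sigmoid.
#' @return A single numeric in [-1, 1].
#' @examples
#' coOccurrenceScore(c(0, 0), c(0, 0), W = 1.2, L = 1)  # 0.6
#' @export
coOccurrenceScore <- function(fU, fOutN, W = 1, L = 1, wInside = FALSE) {
  stopifnot(length(fU) == length(fOutN), L %in% c(0, 1))
  s <- sum(fU * fOutN)
  A <- if (wInside) 1 / (1 + exp(-s * W^L))
       else (1 / (1 + exp(-s))) * W^L
  min(max(A, -1), 1)
}

#' One stochastic-gradient pair update
#'
#' Reference implementation of a single training step on one
#' (center u, context-or-negative n) pair, mirroring the compiled
#' trainer exactly. Vanilla mode uses the exact negative-sampling
#' gradient \eqn{g = (\mathrm{label} - \sigma(f'(n) \cdot f(u)))
#' \cdot \mathrm{lr}}; graph mode replaces the sigmoid by the clipped
#' structure-modulated score A and scales both row updates by
#' \eqn{W^L}. The error accumulator for the center row is incremented
#' with the context row *before* that row is updated; the center row
#' itself is applied by the caller after all of the pair's negatives.
#'
#' @param fU input row of the center node (not modified).
#' @param fOutN output row of the context/negative node.
#' @param label 1 for a positive (walk-sampled) pair, 0 for a noise draw.
#' @param lr current learning rate.
#' @param mode "vanilla" or "graph".
#' @param W,L structure weight and reachability (graph mode).
#' @param wInside apply W inside the sigmoid (graph mode variant).
#' @return List with \code{fOutN} (updated output row), \code{accDelta}
#'   (increment for the center-row error accumulator), and \code{g}
#'   (the gradient scalar).
#' @export
pairUpdate <- function(fU, fOutN, label, lr, mode = c("vanilla", "graph"),
                       W = 1, L = 1, wInside = FALSE) {
  mode <- match.arg(mode)
  s <- sum(fU * fOutN)
  sig <- 1 / (1 + exp(-s))
  if (mode == "vanilla") {
    g <- (label - sig) * lr
    scale <- 1
  } else {
    m <- W^L
    A <- if (wInside) 1 / (1 + exp(-s * m)) else sig * m
    A <- min(max(A, -1), 1)
    g <- (label - A) * lr
    scale <- m
  }
  accDelta <- fOutN * g * scale
  list(fOutN = fOutN + fU * g * scale, accDelta = accDelta, g = g)
}

#' Train input/output node embeddings
#'
#' Runs negative-sampling stochastic gradient descent over the
#' (center, context) pairs of a random-walk corpus. In \code{"vanilla"}
#' mode this is the plain skip-gram objective; in \code{"graph"} mode
#' every pair's contribution is modulated by the graph-structure weight
#' \eqn{W(n,u)^{L(n,u)}} built from node degrees and shortest-path
#' distances (see \code{\link{structureWeight}}). The learning rate
#' decays linearly from \code{alpha0} to \code{alpha0 * 1e-4} over the
#' pair budget. Per positive pair, k negatives are drawn from the
#' unigram noise distribution (resampled when the draw equals the
#' center); the center row is updated once per positive pair from the
#' accumulated error. Single-threaded and bit-reproducible given the
#' seed.
#'
#' @param g an igraph.
#' @param tcfg a \linkS4class{TrainConfig}.
#' @param wcfg a \linkS4class{WalkConfig}.
#' @param info a \linkS4class{StructureInfo}; required in graph mode.
#' @param corpus optionally, a pre-generated \linkS4class{WalkCorpus}
#'   (walks are generated from \code{wcfg} when omitted).
#' @param noiseExponent smoothing exponent of the noise distribution.
#' @return An \linkS4class{EmbeddingSet}; when \code{statsEnabled}, the
#'   attribute \code{"stats"} holds the PosV/PosC/Neg sampling counts
#'   (see \code{\link{samplingStatistics}}).
#' @examples
#' g <- karateFixture()
#' emb <- trainEmbeddings(g,
#'   trainConfig(dim = 2, negatives = 1, seed = 7),
#'   walkConfig(walksPerNode = 5, walkLength = 10, window = 5, seed = 7))
#' @export
trainEmbeddings <- function(g, tcfg, wcfg, info = NULL, corpus = NULL,
                            noiseExponent = 0.75) {
  validObject(tcfg); validObject(wcfg)
  if (tcfg@mode == "graph" && is.null(info))
    stop("graph mode requires a StructureInfo; see structureInfo()")
  if (tcfg@negatives == 0L)
    warning("negatives = 0: the objective degenerates (no repulsion)")
  if (is.null(corpus)) corpus <- generateWalks(g, wcfg)
  pairs <- contextPairs(corpus, m = wcfg@window,
                        seed = tcfg@seed + 1L, shrink = TRUE)
  noise <- buildNoiseDistribution(corpus, noiseExponent)
  emb <- initEmbeddings(corpus@nodes, tcfg@dim, seed = tcfg@seed)
  mult <- NULL
  if (tcfg@mode == "graph") {
    if (!identical(rownames(info@distMatrix), corpus@nodes))
      info@distMatrix <- info@distMatrix[corpus@nodes, corpus@nodes]
    mult <- structureMultiplier(info, g)
  }
  f <- inputEmbedding(emb) + 0      # defensive copies: C++ updates in place
  fOut <- outputEmbedding(emb) + 0
  res <- withSeed(tcfg@seed + 2L,
    sgd_train_cpp(pairs, f, fOut, cumsum(noise), tcfg@negatives,
                  tcfg@alpha0, tcfg@alpha0 * 1e-4,
                  mult, tcfg@wInside))
  out <- embeddingSet(f, fOut)
  if (tcfg@statsEnabled) {
    attr(out, "stats") <- data.frame(node = corpus@nodes,
                                     PosV = res$posV, PosC = res$posC,
                                     Neg = res$neg,
                                     stringsAsFactors = FALSE)
  }
  out
}
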