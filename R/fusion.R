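#' Per-node similarity between input and output embeddings
#'
#' Cosine similarity normalizes each pair of rows by their norms (a row
#' pair containing a zero vector scores 0); "dot" is the raw inner
#' product of the two rows.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param kind "cosine" or "dot".
#' @return Named numeric vector, one score per node.
#' @examples
#' emb <- embeddingSet(matrix(c(1, 0), 1, 2, dimnames = list("a", NULL)),
#'                     matrix(c(2, 0), 1, 2))
#' similarityScores(emb, "cosine")  # 1
#' @export
similarityScores <- function(emb, kind = c("cosine", "dot")) {
  kind <- match.arg(kind)
  f <- inputEmbedding(emb); fo <- outputEmbedding(emb)
  dots <- rowSums(f * fo)
  s <- if (kind == "dot") dots else {
    nf <- sqrt(rowSums(f^2)); no <- sqrt(rowSums(fo^2))
    den <- nf * no
    ifelse(den > 0, dots / den, 0)
  }
  setNames(s, rownames(f))
}

#' Fioepn: selectively fuse input and output embeddings
#'
#' Fuses the input and output embeddings of the part of the nodes whose
#' two representations agree least. Each node is scored by the
#' similarity of its input row to its output row; the similarity
#' threshold is the score at sorted position \code{floor(ratio * |V|)}
#' (0-based), and every node scoring strictly below it receives
#' \eqn{f^* = (f + f') / 2} while all others keep \eqn{f^* = f}
#' unchanged. Ratio 0 is the identity map. The input object is not
#' modified; fusing is not idempotent (a second pass re-averages), so
#' callers fuse once.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param ratio fraction of nodes eligible for fusion, in [0, 1].
#' @param similarity "cosine" (default; scale-invariant across the two
#'   differently-scaled matrices) or "dot" for the raw inner product.
#' @return The fused input matrix \eqn{f^*} with an attribute
#'   \code{"fused"} naming the nodes that changed.
#' @examples
#' g <- karateFixture()
#' emb <- trainEmbeddings(g, trainConfig(dim = 2, negatives = 1, seed = 1),
#'   walkConfig(walksPerNode = 5, walkLength = 10, window = 5, seed = 1))
#' fStar <- fioepn(emb, ratio = 0.5)
#' @export
fioepn <- function(emb, ratio = 0.10, similarity = c("cosine", "dot")) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 0 || ratio > 1)
    stop("'ratio' must be a single value in [0, 1]")
  similarity <- match.arg(similarity)
  f <- inputEmbedding(emb); fo <- outputEmbedding(emb)
  score <- similarityScores(emb, similarity)
  nV <- length(score)
  sorted <- sort(score)
  thrIdx <- min(floor(ratio * nV), nV - 1L)  # 0-based position
  sim <- sorted[thrIdx + 1L]
  fuse <- score < sim                        # strict: ties keep f
  fStar <- f
  fStar[fuse, ] <- (f[fuse, , drop = FALSE] + fo[fuse, , drop = FALSE]) / 2
  attr(fStar, "fused") <- rownames(f)[fuse]
  fStar
}
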