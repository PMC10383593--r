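#' Structure report for a graph
#'
#' Computes degrees, the shortest-path histogram, and the automatically
#' chosen distance scale; the backbone of the \code{structure} CLI
#' subcommand.
#'
#' @param g an igraph.
#' @param nSourceSamples sources to sample for the distance histogram
#'   (defaults to all nodes).
#' @param seed integer seed for source sampling.
#' @return List with \code{degrees}, \code{histogram}, and the chosen
#'   \code{distanceScale}.
#' @examples
#' rep <- structureReport(karateFixture())
#' rep$distanceScale  # 6
#' @export
structureReport <- function(g, nSourceSamples = vcount(g), seed = 1) {
  h <- estimateDistanceDistribution(g, nSourceSamples, seed)
  list(degrees = computeDegrees(g), histogram = h,
       distanceScale = chooseDistanceScale(h))
}

#' Settings of the karate-network demonstration
#'
#' The small-network configuration used throughout the package's worked
#' example: 2-d embeddings, window 5, 40 walks of length 40 per node,
#' 1 negative sample; graph mode adds w = 0.8, distance scale 5,
#' exponent 1.
#'
#' @param mode "vanilla" or "graph".
#' @param seed integer seed.
#' @return List with elements \code{tcfg}, \code{wcfg}, \code{params}.
#' @export
karateDemoConfig <- function(mode = c("vanilla", "graph"), seed = 1) {
  mode <- match.arg(mode)
  list(tcfg = trainConfig(dim = 2, negatives = 1, mode = mode, seed = seed),
       wcfg = walkConfig(walksPerNode = 40, walkLength = 40, window = 5,
                         seed = seed),
       params = structureParams(w = 0.8, distanceScale = 5, a = 1))
}

#' Train embeddings on the karate network
#'
#' Runs the full pipeline (walks, optional structure information,
#' training) on the packaged karate graph under the demonstration
#' settings of \code{\link{karateDemoConfig}}.
#'
#' @param mode "vanilla" or "graph".
#' @param seed integer seed.
#' @return An \linkS4class{EmbeddingSet} (with sampling statistics).
#' @export
trainKarateDemo <- function(mode = c("vanilla", "graph"), seed = 1) {
  mode <- match.arg(mode)
  g <- karateFixture()
  cfg <- karateDemoConfig(mode, seed)
  info <- if (mode == "graph") structureInfo(g, cfg$params) else NULL
  trainEmbeddings(g, cfg$tcfg, cfg$wcfg, info = info)
}

#' Clustering report: CH and per-class WGSS against modularity classes
#'
#' @param emb embedding matrix (rows named by node) or an
#'   \linkS4class{EmbeddingSet} (its input matrix is used).
#' @param g the graph the embedding was trained on.
#' @param labels optional class labels; greedy modularity classes of
#'   \code{g} when omitted.
#' @return List with \code{ch}, \code{wgss} (per class), and
#'   \code{labels}.
#' @export
clusteringReport <- function(emb, g, labels = NULL) {
  if (is(emb, "EmbeddingSet")) emb <- inputEmbedding(emb)
  if (is.null(labels)) labels <- modularityClasses(g)
  list(ch = calinskiHarabasz(emb, labels),
       wgss = wgss(emb, labels), labels = labels)
}

#' Compare vanilla and graph-mode training on the karate network
#'
#' For each seed, trains both modes under the demonstration settings and
#' scores both input embeddings (CH, per-class WGSS) against the greedy
#' modularity partition; also applies Fioepn at the given ratio to the
#' vanilla embeddings and scores the fused matrix. This is the package's
#' headline desk experiment.
#'
#' @param seeds integer vector of seeds.
#' @param fusionRatio ratio for the Fioepn comparison.
#' @return A list with per-seed data.frames: \code{ch} (columns seed,
#'   vanilla, graph, pctImprovement) and \code{wgssFusion} (per-class
#'   WGSS of f and f*, plus percent reduction).
#' @export
karateComparison <- function(seeds = 1:10, fusionRatio = 0.5) {
  g <- karateFixture()
  labels <- modularityClasses(g)
  rows <- lapply(seeds, function(s) {
    vEmb <- trainKarateDemo("vanilla", seed = s)
    gEmb <- trainKarateDemo("graph", seed = s)
    chV <- calinskiHarabasz(inputEmbedding(vEmb), labels)
    chG <- calinskiHarabasz(inputEmbedding(gEmb), labels)
    fStar <- fioepn(vEmb, ratio = fusionRatio)
    wF <- wgss(inputEmbedding(vEmb), labels)
    wS <- wgss(fStar, labels)
    list(ch = data.frame(seed = s, vanilla = chV, graph = chG,
                         pctImprovement = 100 * (chG - chV) / chV),
         wg = data.frame(seed = s, class = names(wF), f = unname(wF),
                         fStar = unname(wS),
                         pctReduction = 100 * (unname(wF) - unname(wS)) /
                           unname(wF)))
  })
  list(ch = do.call(rbind, lapply(rows, `[[`, "ch")),
       wgssFusion = do.call(rbind, lapply(rows, `[[`, "wg")))
}
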