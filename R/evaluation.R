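#' @importFrom igraph cluster_fast_greedy membership
#' @importFrom glmnet glmnet
#' @importFrom stats predict runif
NULL

#' Partition nodes by greedy modularity maximization
#'
#' Agglomerative modularity clustering; class ids are relabelled
#' deterministically by each community's smallest member (in the
#' graph's node order), so class "1" contains the first node.
#'
#' @param g a connected igraph.
#' @return Named integer vector: node -> class label (1..K).
#' @examples
#' table(modularityClasses(karateFixture()))
#' @export
modularityClasses <- function(g) {
  if (!is_connected(g))
    warning("graph is not connected; communities computed per component")
  mem <- as.integer(membership(cluster_fast_greedy(g)))
  first <- match(unique(mem), mem)                 # first node of each class
  relabel <- order(order(first))                   # rank by first appearance
  out <- relabel[match(mem, unique(mem))]
  setNames(as.integer(out), V(g)$name)
}

#' Within-group sum of squares per class
#'
#' \eqn{WGSS(c) = \sum_{i \in c} \|x_i - \bar{x}_c\|^2}: the squared
#' spread of each class around its centroid; 0 for singleton classes,
#' invariant under global translation. Lower is tighter.
#'
#' @param emb numeric matrix, rows named by node.
#' @param labels named vector of class labels covering the scored nodes.
#' @return Named numeric vector, one value per class (sorted by label).
#' @examples
#' m <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), NULL))
#' wgss(m, c(a = 1, b = 1))  # 2
#' @export
wgss <- function(emb, labels) {
  emb <- as.matrix(emb)
  if (is.null(names(labels))) stop("'labels' must be named by node")
  unknown <- setdiff(names(labels), rownames(emb))
  if (length(unknown))
    stop("label for node(s) not in embedding: ",
         paste(head(unknown, 5), collapse = ", "))
  x <- emb[names(labels), , drop = FALSE]
  cls <- sort(unique(labels))
  out <- vapply(cls, function(cl) {
    xc <- x[labels == cl, , drop = FALSE]
    ctr <- colMeans(xc)
    sum(sweep(xc, 2, ctr)^2)
  }, numeric(1))
  setNames(out, as.character(cls))
}

#' Calinski-Harabasz index
#'
#' \eqn{CH = \frac{BGSS / (K - 1)}{WGSS / (n - K)}}: the ratio of
#' between-class to within-class dispersion, each scaled by its degrees
#' of freedom. Larger means better-separated, tighter classes; the
#' index is invariant to global scaling of the coordinates.
#'
#' @param emb numeric matrix, rows named by node.
#' @param labels named vector of class labels (>= 2 distinct classes,
#'   fewer classes than points).
#' @return A single numeric.
#' @export
calinskiHarabasz <- function(emb, labels) {
  emb <- as.matrix(emb)
  if (is.null(names(labels))) stop("'labels' must be named by node")
  x <- emb[names(labels), , drop = FALSE]
  n <- nrow(x)
  cls <- unique(labels)
  K <- length(cls)
  if (K < 2L) stop("need at least 2 classes")
  if (n <= K) stop("need more points than classes")
  grand <- colMeans(x)
  within <- 0; between <- 0
  for (cl in cls) {
    xc <- x[labels == cl, , drop = FALSE]
    ctr <- colMeans(xc)
    within <- within + sum(sweep(xc, 2, ctr)^2)
    between <- between + nrow(xc) * sum((ctr - grand)^2)
  }
  (between / (K - 1)) / (within / (n - K))
}

# ridge-logistic one-vs-rest probability scores (strength mirrors an L2
# penalty of 1.0 in the C = 1 parameterization: lambda = 1/nobs)
ovrProbs <- function(xTrain, yTrainList, xTest, classes) {
  probs <- matrix(0, nrow(xTest), length(classes),
                  dimnames = list(NULL, classes))
  for (cl in classes) {
    y <- vapply(yTrainList, function(ls) cl %in% ls, logical(1))
    if (length(unique(y)) < 2L) {
      probs[, cl] <- mean(y)      # degenerate split: constant prior
      next
    }
    fit <- glmnet(xTrain, factor(y, levels = c(FALSE, TRUE)),
                  family = "binomial", alpha = 0,
                  lambda = 1 / nrow(xTrain), standardize = FALSE)
    probs[, cl] <- as.numeric(predict(fit, xTest, type = "response"))
  }
  probs
}

#' Multi-label node classification with embeddings as features
#'
#' One-vs-rest ridge-logistic classifiers are trained on the embeddings
#' of a random fraction of the labeled nodes; for each test node the
#' top-\eqn{k_i} labels by predicted probability are assigned, where
#' \eqn{k_i} is the node's true label count (the standard evaluation
#' protocol for multi-label network embedding). The micro-F1 over all
#' test (node, label) decisions is averaged over repeats. A label never
#' seen in a training split is skipped with a warning. With
#' \code{topK = FALSE} labels are instead assigned by a 0.5 probability
#' threshold.
#'
#' @param emb numeric embedding matrix, rows named by node.
#' @param labels named list: node -> character vector of labels.
#' @param trainFraction fraction of labeled nodes used for training,
#'   in (0, 1).
#' @param repeats number of random splits to average over.
#' @param seed integer seed.
#' @param topK use the known-label-count top-k assignment rule.
#' @return Mean micro-F1 over repeats, with attribute \code{"scores"}
#'   holding the per-repeat values.
#' @export
multilabelEval <- function(emb, labels, trainFraction = 0.5, repeats = 10,
                           seed = 1, topK = TRUE) {
  if (!(trainFraction > 0 && trainFraction < 1))
    stop("'trainFraction' must be in (0, 1)")
  emb <- as.matrix(emb)
  nodes <- names(labels)
  if (!all(nodes %in% rownames(emb)))
    stop("every labeled node must be embedded")
  x <- emb[nodes, , drop = FALSE]
  classes <- sort(unique(unlist(labels)))
  scores <- withSeed(as.integer(seed), vapply(seq_len(repeats), function(rep) {
    idx <- sample(length(nodes), max(2L, round(trainFraction * length(nodes))))
    trainLabs <- labels[idx]
    seen <- classes[classes %in% unlist(trainLabs)]
    if (length(seen) < length(classes))
      warning("label(s) absent from a training split were skipped: ",
              paste(setdiff(classes, seen), collapse = ", "))
    probs <- ovrProbs(x[idx, , drop = FALSE], trainLabs,
                      x[-idx, , drop = FALSE], seen)
    testLabs <- labels[-idx]
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(testLabs)) {
      truth <- intersect(testLabs[[i]], seen)
      pred <- if (topK) {
        ki <- length(testLabs[[i]])
        seen[order(probs[i, ], decreasing = TRUE)[seq_len(min(ki, length(seen)))]]
      } else seen[probs[i, ] >= 0.5]
      tp <- tp + length(intersect(pred, truth))
      fp <- fp + length(setdiff(pred, truth))
      fn <- fn + length(setdiff(truth, pred))
    }
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1)))
  out <- mean(scores)
  attr(out, "scores") <- scores
  out
}

#' Edge feature vector from two node embeddings
#'
#' Symmetric elementwise operators combining the embedding rows of an
#' edge's endpoints: \code{average} = (f(u)+f(v))/2, \code{hadamard} =
#' f(u)*f(v), \code{weighted_l1} = |f(u)-f(v)|, \code{weighted_l2} =
#' (f(u)-f(v))^2.
#'
#' @param f embedding matrix, rows named by node.
#' @param u,v node names.
#' @param operator one of "average", "hadamard", "weighted_l1",
#'   "weighted_l2".
#' @return Numeric vector of length \code{ncol(f)}.
#' @examples
#' f <- rbind(u = c(1, 2), v = c(3, -1))
#' edgeFeatures(f, "u", "v", "hadamard")      # 3 -2
#' edgeFeatures(f, "u", "v", "weighted_l2")   # 4  9
#' @export
edgeFeatures <- function(f, u, v,
                         operator = c("average", "hadamard",
                                      "weighted_l1", "weighted_l2")) {
  operator <- match.arg(operator)
  a <- f[u, ]; b <- f[v, ]
  switch(operator,
         average = (a + b) / 2,
         hadamard = a * b,
         weighted_l1 = abs(a - b),
         weighted_l2 = (a - b)^2)
}

# remove ~fraction of edges one at a time, rejecting any removal that
# disconnects the residual graph
removeEdgesConnected <- function(g, fraction) {
  target <- floor(fraction * ecount(g))
  removed <- character(0)
  el <- as_edgelist(g)
  candidates <- sample(ecount(g))     # random removal order
  gi <- g
  for (eid in candidates) {
    if (length(removed) >= target) break
    ends <- el[eid, ]
    key <- paste(ends, collapse = "|")
    cur <- get_edge_ids(gi, ends, error = FALSE)
    if (cur == 0) next
    gtry <- delete_edges(gi, cur)
    if (is_connected(gtry)) {
      gi <- gtry
      removed <- c(removed, key)
    }
  }
  if (length(removed) < target)
    warning("only ", length(removed), " of ", target,
            " edges could be removed while keeping the graph connected")
  list(residual = gi,
       removed = do.call(rbind, strsplit(removed, "|", fixed = TRUE)))
}

# sample n node pairs that are NOT edges of g (and not self pairs)
sampleNonEdges <- function(g, n) {
  nodes <- V(g)$name
  out <- matrix(character(0), 0, 2)
  guard <- 0L
  while (nrow(out) < n && guard < 50L) {
    u <- sample(nodes, n, replace = TRUE)
    v <- sample(nodes, n, replace = TRUE)
    ok <- u != v & get_edge_ids(g, as.vector(t(cbind(u, v))),
                                error = FALSE) == 0
    out <- unique(rbind(out, cbind(u, v)[ok, , drop = FALSE]))
    guard <- guard + 1L
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

#' Link prediction with edge-operator features
#'
#' Removes a fraction of edges (never disconnecting the residual graph),
#' trains embeddings on the residual graph via \code{embedFun}, and
#' scores a ridge-logistic classifier on edge features. Positives are
#' the removed edges (test side) plus an equal-size sample of residual
#' edges (train side); negatives are sampled non-edges of the full
#' graph, matched in count. The classifier sees a 50/50 train/test
#' split and the returned value is the test accuracy.
#'
#' @param g a connected igraph.
#' @param embedFun function(graph) -> embedding matrix with node
#'   rownames (e.g. training and returning \code{inputEmbedding}).
#' @param removalFraction fraction of edges to hold out, in (0, 1).
#' @param operator edge operator (see \code{\link{edgeFeatures}}).
#' @param seed integer seed.
#' @return Test accuracy in [0, 1], with attribute \code{"n"} giving
#'   the number of test pairs.
#' @export
linkPredictionEval <- function(g, embedFun, removalFraction = 0.5,
                               operator = "weighted_l2", seed = 1) {
  if (!is_connected(g)) stop("graph must be connected")
  if (!(removalFraction > 0 && removalFraction < 1))
    stop("'removalFraction' must be in (0, 1)")
  operator <- match.arg(operator, c("average", "hadamard",
                                    "weighted_l1", "weighted_l2"))
  splitRes <- withSeed(as.integer(seed), {
    rem <- removeEdgesConnected(g, removalFraction)
    resEdges <- as_edgelist(rem$residual)
    nPos <- nrow(rem$removed)
    trainPos <- resEdges[sample(nrow(resEdges), min(nPos, nrow(resEdges))), ,
                         drop = FALSE]
    neg <- sampleNonEdges(g, nPos + nrow(trainPos))
    list(rem = rem, trainPos = trainPos, neg = neg)
  })
  rem <- splitRes$rem
  stopifnot(is_connected(rem$residual))
  f <- embedFun(rem$residual)

  feat <- function(pairsMat) t(apply(pairsMat, 1, function(p)
    edgeFeatures(f, p[1], p[2], operator)))
  nPos <- nrow(rem$removed)
  nNegTrain <- min(nrow(splitRes$trainPos), nrow(splitRes$neg) - nPos)
  xTrain <- rbind(feat(splitRes$trainPos),
                  feat(splitRes$neg[seq_len(nNegTrain), , drop = FALSE]))
  yTrain <- c(rep(1, nrow(splitRes$trainPos)), rep(0, nNegTrain))
  xTest <- rbind(feat(rem$removed),
                 feat(splitRes$neg[nNegTrain + seq_len(nPos), ,
                                   drop = FALSE]))
  yTest <- c(rep(1, nPos), rep(0, nPos))
  fit <- glmnet(xTrain, factor(yTrain, levels = c(0, 1)),
                family = "binomial", alpha = 0,
                lambda = 1 / nrow(xTrain), standardize = FALSE)
  pred <- as.numeric(predict(fit, xTest, type = "response")) >= 0.5
  acc <- mean(pred == (yTest == 1))
  attr(acc, "n") <- length(yTest)
  acc
}
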