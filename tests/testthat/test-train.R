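test_that("initialization is uniform-bounded input, zero output", {
  emb <- initEmbeddings(as.character(1:20), d = 4, seed = 11)
  expect_true(all(outputEmbedding(emb) == 0))
  expect_lte(max(abs(inputEmbedding(emb))), 0.5 / 4)
  emb2 <- initEmbeddings(as.character(1:20), d = 4, seed = 11)
  expect_identical(inputEmbedding(emb), inputEmbedding(emb2))
  emb3 <- initEmbeddings(as.character(1:20), d = 4, seed = 12)
  expect_false(identical(inputEmbedding(emb), inputEmbedding(emb3)))
})

test_that("the noise distribution smooths corpus frequencies", {
  mk <- function(walks, nodes)
    new("WalkCorpus", walks = walks, nodes = nodes, config = walkConfig())
  # counts 16 and 1, exponent 0.75: 16^0.75 = 8 -> 8/9, 1/9
  corp <- mk(list(rep("a", 16), "b"), c("a", "b"))
  expect_equal(unname(buildNoiseDistribution(corp, 0.75)), c(8/9, 1/9))
  # exponent 0: uniform over nodes present in the corpus
  expect_equal(unname(buildNoiseDistribution(corp, 0)), c(1/2, 1/2))
  # absent nodes get zero mass; distribution still sums to 1
  corp2 <- mk(list(c("a", "b", "a")), c("a", "b", "c"))
  p <- buildNoiseDistribution(corp2, 0.75)
  expect_equal(unname(p[["c"]]), 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("the co-occurrence score is the clipped modulated sigmoid", {
  # zero vectors: sigmoid(0) = 0.5, times W = 1.2 -> 0.6
  expect_equal(coOccurrenceScore(c(0, 0), c(0, 0), W = 1.2, L = 1), 0.6)
  # L = 0 leaves the sigmoid untouched whatever W is
  set.seed(1)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(coOccurrenceScore(a, b, W = 57, L = 0),
               1 / (1 + exp(-sum(a * b))))
  # a large positive score with W > 1 clips at 1
  expect_equal(coOccurrenceScore(rep(10, 2), rep(10, 2), W = 1.2, L = 1), 1)
})

test_that("a single pair update follows the gradient rule", {
  # zero embeddings, label 1: g = 0.5 * lr, rows stay zero
  up <- pairUpdate(c(0, 0), c(0, 0), label = 1, lr = 0.1)
  expect_equal(up$g, 0.05)
  expect_equal(up$fOutN, c(0, 0))
  expect_equal(up$accDelta, c(0, 0))

  # graph mode with W = 1, L = 1 is numerically identical to vanilla
  set.seed(3)
  fU <- rnorm(5); fOutN <- rnorm(5)
  v <- pairUpdate(fU, fOutN, 1, 0.025, mode = "vanilla")
  g <- pairUpdate(fU, fOutN, 1, 0.025, mode = "graph", W = 1, L = 1)
  expect_identical(v, g)

  # |g| never exceeds the learning rate
  for (i in 1:20) {
    fU <- rnorm(3, sd = 3); fOutN <- rnorm(3, sd = 3)
    for (lab in c(0, 1)) {
      u <- pairUpdate(fU, fOutN, lab, 0.025, mode = "graph", W = 1.3, L = 1)
      expect_lte(abs(u$g), 0.025)
      expect_true(all(is.finite(u$fOutN)))
    }
  }
})

test_that("the vanilla gradient matches central finite differences", {
  # objective: log sigmoid(f'(n).f(u)) for label 1,
  #            log sigmoid(-f'(n).f(u)) for label 0.
  # pairUpdate's g/lr times f'(n) must equal d(objective)/d f(u).
  obj <- function(fU, fOutN, label) {
    s <- sum(fU * fOutN)
    if (label == 1) log(1 / (1 + exp(-s))) else log(1 / (1 + exp(s)))
  }
  set.seed(4)
  h <- 1e-6
  for (i in 1:10) {
    d <- sample(2:6, 1)
    fU <- rnorm(d); fOutN <- rnorm(d)
    for (label in c(0, 1)) {
      up <- pairUpdate(fU, fOutN, label, lr = 1)
      analytic <- up$g * fOutN
      numeric <- vapply(seq_len(d), function(j) {
        e <- rep(0, d); e[j] <- h
        (obj(fU + e, fOutN, label) - obj(fU - e, fOutN, label)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(analytic - numeric)), 1e-5)
      # and the context-row gradient too
      analyticN <- up$g * fU
      numericN <- vapply(seq_len(d), function(j) {
        e <- rep(0, d); e[j] <- h
        (obj(fU, fOutN + e, label) - obj(fU, fOutN - e, label)) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(analyticN - numericN)), 1e-5)
    }
  }
})

test_that("the compiled trainer agrees with the reference pair update", {
  # one positive pair, k = 0: exactly one pairUpdate plus the center-row
  # application, in both modes
  nodes <- c("a", "b", "c")
  set.seed(6)
  f0 <- matrix(rnorm(6), 3, 2, dimnames = list(nodes, NULL))
  for (mode in c("vanilla", "graph")) {
    mult <- if (mode == "graph")
      matrix(1.17, 3, 3, dimnames = list(nodes, nodes)) else NULL
    f <- f0 + 0; fOut <- matrix(0.3, 3, 2)
    pairs <- cbind(center = 1L, context = 2L)
    gskipgram:::sgd_train_cpp(pairs, f, fOut, c(1/3, 2/3, 1), 0L,
                              0.025, 0.025 * 1e-4, mult, FALSE)
    ref <- pairUpdate(f0[1, ], c(0.3, 0.3), 1, 0.025, mode = mode,
                      W = 1.17, L = 1)
    expect_equal(fOut[2, ], ref$fOutN)
    expect_equal(f[1, ], f0[1, ] + ref$accDelta)
    expect_equal(f[3, ], f0[3, ])   # untouched rows stay put
  }
})

test_that("training from zero with k = 0 keeps everything at zero", {
  # with zero init everywhere, g multiplies zero vectors: nothing moves
  nodes <- c("a", "b")
  f <- matrix(0, 2, 2, dimnames = list(nodes, NULL))
  fOut <- matrix(0, 2, 2)
  gskipgram:::sgd_train_cpp(cbind(1L, 2L), f, fOut, c(0.5, 1), 0L,
                            0.025, 0.025e-4, NULL, FALSE)
  expect_true(all(f == 0))
  expect_true(all(fOut == 0))
})

test_that("training is reproducible and reduces to vanilla when W is 1", {
  g <- karateCache()
  wcfg <- walkConfig(walksPerNode = 3, walkLength = 10, window = 3, seed = 21)
  tV <- trainConfig(dim = 2, negatives = 2, mode = "vanilla", seed = 21)
  e1 <- trainEmbeddings(g, tV, wcfg)
  e2 <- trainEmbeddings(g, tV, wcfg)
  expect_identical(inputEmbedding(e1), inputEmbedding(e2))
  expect_identical(outputEmbedding(e1), outputEmbedding(e2))

  # structure info whose multiplier is exactly 1 for every pair:
  # all off-diagonal distances p/2 (distance term 1) and a degenerate
  # ratio clamp at [1, 1]
  nodes <- igraph::V(g)$name
  P <- matrix(2.5, 34, 34, dimnames = list(nodes, nodes))
  diag(P) <- 0
  infoUnit <- new("StructureInfo", degrees = computeDegrees(g),
                  distMatrix = P,
                  params = structureParams(w = 0.8, distanceScale = 5,
                                           a = 1,
                                           degreeRatioBounds = c(1, 1)))
  M <- gskipgram:::structureMultiplier(infoUnit, g)
  expect_true(all(M == 1))
  tG <- trainConfig(dim = 2, negatives = 2, mode = "graph", seed = 21)
  eG <- trainEmbeddings(g, tG, wcfg, info = infoUnit)
  expect_identical(inputEmbedding(e1), inputEmbedding(eG))
  expect_identical(outputEmbedding(e1), outputEmbedding(eG))

  # graph mode without structure info is a configuration error
  expect_error(trainEmbeddings(g, tG, wcfg), "StructureInfo")
})

test_that("training pulls positive pairs together and stays finite", {
  g <- karateCache()
  wcfg <- walkConfig(walksPerNode = 10, walkLength = 20, window = 5,
                     seed = 31)
  tcfg <- trainConfig(dim = 2, negatives = 1, seed = 31)
  emb <- trainEmbeddings(g, tcfg, wcfg)
  f <- inputEmbedding(emb); fo <- outputEmbedding(emb)
  expect_true(all(is.finite(f)) && all(is.finite(fo)))

  # mean sigmoid over positive (adjacent) pairs exceeds its 0.5 start
  el <- igraph::as_edgelist(g)
  sims <- vapply(seq_len(nrow(el)), function(i)
    1 / (1 + exp(-sum(f[el[i, 1], ] * fo[el[i, 2], ]))), numeric(1))
  expect_gt(mean(sims), 0.5)
})

test_that("per-node sampling statistics add up", {
  g <- karateCache()
  emb <- trainEmbeddings(g, trainConfig(dim = 2, negatives = 3, seed = 41),
                         walkConfig(walksPerNode = 3, walkLength = 10,
                                    window = 3, seed = 41))
  st <- samplingStatistics(emb)
  expect_named(st, c("node", "PosV", "PosC", "Neg"))
  # every pair contributes one center and one context appearance
  expect_equal(sum(st$PosV), sum(st$PosC))
  # k negatives per positive pair
  expect_equal(sum(st$Neg), 3 * sum(st$PosV))
  emb2 <- trainEmbeddings(g, trainConfig(dim = 2, negatives = 3, seed = 41,
                                         statsEnabled = FALSE),
                          walkConfig(walksPerNode = 3, walkLength = 10,
                                     window = 3, seed = 41))
  expect_error(samplingStatistics(emb2), "statsEnabled")
})
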