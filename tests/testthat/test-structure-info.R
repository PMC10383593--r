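test_that("degrees count incident edges", {
  expect_equal(unname(computeDegrees(triangleGraph())), c(2, 2, 2))
  s <- computeDegrees(starGraph(5))
  expect_equal(unname(s[["0"]]), 5)
  expect_equal(unname(s[names(s) != "0"]), rep(1L, 5))
  k <- computeDegrees(karateCache())
  expect_equal(max(k), 17L)
  expect_equal(min(k), 1L)
})

test_that("shortest paths are hop counts with Inf across components", {
  g <- pathGraph(3)
  P <- computeShortestPaths(g)
  expect_equal(P["1", "3"], 2)
  expect_equal(diag(P), setNames(rep(0, 3), c("1", "2", "3")))

  f <- tempfile()
  writeLines(c("1 2", "3 4"), f)
  g2 <- readEdgelist(f)
  P2 <- computeShortestPaths(g2)
  expect_equal(P2["1", "3"], Inf)
  expect_equal(P2["1", "2"], 1)

  # sources subset returns only those rows
  P3 <- computeShortestPaths(pathGraph(4), sources = c("1", "2"))
  expect_equal(nrow(P3), 2)
  expect_equal(P3["1", "4"], 3)
})

test_that("distance matrix equals independent BFS on random graphs", {
  for (s in 1:30) {
    n <- sample(5:30, 1)
    g <- randomGraph(n, pEdge = runif(1, 0.1, 0.5), seed = 1000 + s)
    expect_equal(computeShortestPaths(g), bfsDistances(g),
                 info = paste("graph seed", 1000 + s))
  }
})

test_that("distance distribution estimates and auto scale behave", {
  # complete graph: all mass at distance 1
  h <- estimateDistanceDistribution(completeGraph(5), 5, seed = 1)
  expect_equal(h, c(`1` = 1))
  expect_equal(chooseDistanceScale(h), 2)

  # path of 4 nodes, all sources: 6 ordered-pair distances each way;
  # exact enumeration gives {1: 1/2, 2: 1/3, 3: 1/6}
  h2 <- estimateDistanceDistribution(pathGraph(4), 4, seed = 1)
  expect_equal(h2, c(`1` = 1/2, `2` = 1/3, `3` = 1/6))

  # histogram with max distance 6 -> scale 7 (keeps all pairs <= p - 1)
  expect_equal(chooseDistanceScale(c(`1` = 0.5, `6` = 0.5)), 7)

  # karate: support within 1..5, auto scale 6
  hk <- estimateDistanceDistribution(karateCache(), 34, seed = 1)
  expect_true(all(as.numeric(names(hk)) %in% 1:5))
  expect_equal(chooseDistanceScale(hk), 6)
  expect_equal(structureReport(karateCache())$distanceScale, 6)

  # determinism given seed (sampled sources)
  ha <- estimateDistanceDistribution(karateCache(), 5, seed = 9)
  hb <- estimateDistanceDistribution(karateCache(), 5, seed = 9)
  expect_identical(ha, hb)
})

test_that("reachability is 1 exactly for finite positive distances", {
  f <- tempfile()
  writeLines(c("1 2", "3 4"), f)
  info <- structureInfo(readEdgelist(f), structureParams())
  expect_equal(reachability("1", "1", info), 0L)  # self pair
  expect_equal(reachability("1", "2", info), 1L)  # adjacent
  expect_equal(reachability("1", "3", info), 0L)  # cross-component
})

test_that("the structure weight follows the degree-ratio/distance form", {
  g <- karateCache()
  info <- structureInfo(g, structureParams(w = 0.8, distanceScale = 5, a = 1))
  # hub (deg 17) center, context of degree 4 at distance 1:
  # ratio clamps to 1.1, distance term 2 - 2/5 = 1.6
  degs <- computeDegrees(g)
  hub <- names(degs)[degs == 17][1]
  # any neighbor of the hub has degree <= 15, so the ratio clamps at 1.1
  ctx <- igraph::neighbors(g, hub)$name[1]
  expect_equal(computeShortestPaths(g)[hub, ctx], 1)
  expect_equal(structureWeight(hub, ctx, info), 0.8 * 1.1 + 0.2 * 1.6)

  # w -> 1 degenerate: adjacent equal-degree pair scores the clamp floor
  tri <- triangleGraph()
  infoT <- structureInfo(tri, structureParams(w = 1 - 1e-12,
                                              distanceScale = 5, a = 1))
  expect_equal(structureWeight("1", "2", infoT), 1, tolerance = 1e-9)

  # unreachable pairs are a contract violation
  f <- tempfile()
  writeLines(c("1 2", "3 4"), f)
  info2 <- structureInfo(readEdgelist(f), structureParams())
  expect_error(structureWeight("1", "3", info2), "reachable")
  expect_error(structureWeight("1", "1", info2), "reachable")
})

test_that("edge weights add w' * weight on weighted graphs", {
  f <- tempfile()
  writeLines(c("1 2 2.0", "2 3 1.0", "3 1 1.0", "3 4 1.0", "4 5 1.0",
               "5 1 1.0", "1 6 1.0", "6 7 1.0"), f)
  g <- readEdgelist(f, weighted = TRUE)
  params <- structureParams(w = 0.8, distanceScale = 5, a = 1, wPrime = 0.1)
  info <- structureInfo(g, params)
  paramsNoW <- structureParams(w = 0.8, distanceScale = 5, a = 1, wPrime = 0)
  infoNoW <- structureInfo(g, paramsNoW)
  base <- structureWeight("1", "2", infoNoW, g)
  expect_equal(structureWeight("1", "2", info, g), base + 0.1 * 2.0)
  # non-edges get no weight term
  P <- computeShortestPaths(g)
  expect_gt(P["1", "4"], 1)
  expect_equal(structureWeight("1", "4", info, g),
               structureWeight("1", "4", infoNoW, g))
})

test_that("structure weight is monotone and bounded", {
  params <- structureParams(w = 0.7, distanceScale = 6, a = 1)
  set.seed(5)
  for (i in 1:50) {
    Du <- sample(1:20, 1); Dn <- sample(1:20, 1)
    d1 <- sample(1:4, 1); d2 <- d1 + sample(1:3, 1)
    mkInfo <- function(d) {
      P <- matrix(c(0, d, d, 0), 2, 2,
                  dimnames = list(c("u", "n"), c("u", "n")))
      new("StructureInfo", degrees = setNames(as.integer(c(Du, Dn)),
                                              c("u", "n")),
          distMatrix = P, params = params)
    }
    wNear <- structureWeight("u", "n", mkInfo(d1))
    wFar <- structureWeight("u", "n", mkInfo(d2))
    # non-increasing in distance for fixed degrees
    expect_gte(wNear, wFar)
    # bounds: w * 1 + 0 <= W <= w * 1.1 + (1 - w) * (2 - 2/p)^a
    for (W in c(wNear, wFar)) {
      expect_gte(W, 0.7)
      expect_lte(W, 0.7 * 1.1 + 0.3 * (2 - 2 / 6))
      expect_true(is.finite(W))
    }
  }
  # non-decreasing in the degree ratio within the clamp interval
  base <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("u", "n"), c("u", "n")))
  wAt <- function(Du, Dn) {
    info <- new("StructureInfo",
                degrees = setNames(as.integer(c(Du, Dn)), c("u", "n")),
                distMatrix = base, params = params)
    structureWeight("u", "n", info)
  }
  expect_lte(wAt(10, 10), wAt(21, 20))   # ratio 1 vs 1.05
  expect_lte(wAt(21, 20), wAt(11, 10))   # 1.05 vs 1.1
  expect_equal(wAt(11, 10), wAt(20, 10)) # clamp saturates above 1.1
})

test_that("the dense multiplier matrix matches per-pair evaluation", {
  g <- karateCache()
  info <- structureInfo(g, structureParams(w = 0.8, distanceScale = 5, a = 1))
  M <- gskipgram:::structureMultiplier(info, g)
  nodes <- igraph::V(g)$name
  set.seed(2)
  for (i in 1:25) {
    u <- sample(nodes, 1); n <- sample(setdiff(nodes, u), 1)
    expect_equal(M[u, n], structureWeight(u, n, info, g))
  }
  expect_true(all(diag(M) == 1))  # self pairs: multiplier inert
})
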