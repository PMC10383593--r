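#' @importFrom igraph graph_from_data_frame vcount ecount V degree
#'   as_edgelist is_connected distances sample_sbm set_vertex_attr
#'   vertex_attr simplify E edge_attr delete_edges get_edge_ids
#'   induced_subgraph components neighbors gsize as_adj_list
NULL

# Deterministic node order: numeric when every id parses as a number
# (so "2" sorts before "10"), lexicographic otherwise.
orderNodes <- function(ids) {
  ids <- unique(as.character(ids))
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else sort(ids, method = "radix")
}

#' Read an undirected graph from a whitespace-delimited edge list
#'
#' Each non-comment line names one edge: \code{"u v"} or, when
#' \code{weighted = TRUE}, \code{"u v w"} with a strictly positive weight.
#' Comment lines start with \code{#}; spaces and tabs both separate
#' tokens. The graph is treated as undirected and simple: duplicate edges
#' collapse to the first occurrence (with a warning when weights differ in
#' count), and self-loops are dropped with a message reporting how many.
#' Node row order is deterministic (numeric when all ids are numbers,
#' lexicographic otherwise).
#'
#' @param path path to the edge-list file.
#' @param weighted logical; expect a third weight token per line.
#' @return An undirected \code{igraph} object with vertex names; weighted
#'   graphs carry an edge attribute \code{weight}.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3", "3 1"), f)
#' g <- readEdgelist(f)
#' igraph::vcount(g)  # 3
#' @export
readEdgelist <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  want <- if (weighted) 3L else 2L
  nt <- lengths(toks)
  if (any(nt != want)) {
    bad <- idx[which(nt != want)[1]]
    stop("malformed edge-list line ", bad, ": expected ", want,
         " whitespace-separated tokens")
  }
  if (length(toks) == 0L) stop("edge list is empty: ", path)
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  w <- if (weighted) {
    wn <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
    if (anyNA(wn)) stop("non-numeric edge weight at line ",
                        idx[which(is.na(wn))[1]])
    if (any(wn <= 0)) stop("non-positive edge weight at line ",
                           idx[which(wn <= 0)[1]])
    wn
  } else NULL

  nodes <- orderNodes(c(u, v))
  self <- u == v
  if (any(self))
    message("dropped ", sum(self), " self-loop line(s)")
  u2 <- u[!self]; v2 <- v[!self]
  if (!is.null(w)) w <- w[!self]
  # canonical undirected key for duplicate collapsing (keep first)
  key <- ifelse(u2 < v2, paste(u2, v2), paste(v2, u2))
  dup <- duplicated(key)
  if (any(dup)) warning("collapsed ", sum(dup),
                        " duplicate edge(s); kept first occurrence")
  df <- data.frame(from = u2[!dup], to = v2[!dup],
                   stringsAsFactors = FALSE)
  if (!is.null(w)) df$weight <- w[!dup]
  graph_from_data_frame(df, directed = FALSE,
                        vertices = data.frame(name = nodes))
}

#' The Zachary karate-club network
#'
#' Returns the standard 34-node, 78-edge karate-club graph from the
#' packaged edge list, with the canonical 1..34 node numbering. This small
#' social network is the package's worked example for visualising and
#' scoring the embedding process.
#'
#' @return An undirected \code{igraph} with vertices named "1".."34".
#' @examples
#' g <- karateFixture()
#' max(igraph::degree(g))  # 17
#' @export
karateFixture <- function() {
  path <- system.file("extdata", "karate.edgelist", package = "gskipgram",
                      mustWork = TRUE)
  readEdgelist(path, weighted = FALSE)
}

#' Sample a stochastic-block-model graph with planted communities
#'
#' Emulates community-structured networks (such as functional modules in
#' protein-interaction graphs): edges appear independently with
#' probability \code{pIn} within a block and \code{pOut} between blocks.
#' The planted block of each node is attached as the vertex attribute
#' \code{block}.
#'
#' @param blockSizes integer vector of block sizes (all >= 1).
#' @param pIn within-block edge probability.
#' @param pOut between-block edge probability; must satisfy
#'   \code{0 <= pOut < pIn <= 1}.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @return An undirected simple \code{igraph}; vertices are named
#'   "1".."n" and carry a \code{block} attribute.
#' @examples
#' g <- sbmGraph(c(5, 5), pIn = 1, pOut = 0, seed = 1)
#' igraph::ecount(g)  # two 5-cliques: 20 edges
#' @export
sbmGraph <- function(blockSizes, pIn, pOut, seed = 1) {
  blockSizes <- as.integer(blockSizes)
  if (any(blockSizes < 1L)) stop("all blocks must be non-empty")
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1))
    stop("need 0 <= pOut < pIn <= 1")
  n <- sum(blockSizes)
  K <- length(blockSizes)
  pm <- matrix(pOut, K, K); diag(pm) <- pIn
  g <- withSeed(as.integer(seed), sample_sbm(n, pref.matrix = pm,
                                             block.sizes = blockSizes))
  g <- set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  set_vertex_attr(g, "block", value = rep(seq_len(K), blockSizes))
}

# evaluate expr under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a node multi-label file
#'
#' One line per labeled node: \code{"u label1 label2 ..."}. Every node
#' must carry at least one label.
#'
#' @param path path to the label file.
#' @param graph optional igraph; when given, labeled nodes are checked to
#'   exist in the graph.
#' @return A named list mapping node name to a character vector of labels.
#' @export
readLabels <- function(path, graph = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  if (any(lengths(toks) < 2L))
    stop("label file line without labels: line ",
         which(keep)[which(lengths(toks) < 2L)[1]])
  labs <- lapply(toks, function(tk) tk[-1])
  names(labs) <- vapply(toks, `[`, "", 1L)
  if (anyDuplicated(names(labs))) stop("duplicate node in label file")
  if (!is.null(graph)) {
    missing <- setdiff(names(labs), V(graph)$name)
    if (length(missing))
      stop("labeled node(s) not in graph: ",
           paste(head(missing, 5), collapse = ", "))
  }
  labs
}

#' Write embeddings in word2vec text format
#'
#' The dialect is a header line \code{"<n_nodes> <d>"} followed by one
#' line per node: the node name then \code{d} full-precision floats.
#' With \code{which = "both"}, the input matrix goes to \code{path} and
#' the output matrix to \code{paste0(path, ".out")}.
#'
#' @param emb an \linkS4class{EmbeddingSet}.
#' @param path output file path.
#' @param which which matrix to write: "input", "output", or "both".
#' @return Invisibly, the path(s) written.
#' @export
writeEmbeddings <- function(emb, path, which = c("input", "output", "both")) {
  which <- match.arg(which)
  writeOne <- function(m, p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(paste(nrow(m), ncol(m)), con)
    body <- vapply(seq_len(nrow(m)), function(i)
      paste(rownames(m)[i],
            paste(formatC(m[i, ], format = "g", digits = 17),
                  collapse = " ")), "")
    writeLines(body, con)
    p
  }
  out <- switch(which,
    input = writeOne(inputEmbedding(emb), path),
    output = writeOne(outputEmbedding(emb), path),
    both = c(writeOne(inputEmbedding(emb), path),
             writeOne(outputEmbedding(emb), paste0(path, ".out"))))
  invisible(out)
}

#' Read one embedding matrix in word2vec text format
#'
#' @param path path written by \code{\link{writeEmbeddings}} (or any
#'   word2vec-style text embedding file).
#' @return A numeric matrix with node names as rownames.
#' @export
readEmbeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty embedding file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed embedding header: ", lines[1])
  n <- hdr[1]; d <- hdr[2]
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) != n)
    stop("embedding header promises ", n, " rows but file has ",
         length(body))
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) != d + 1L))
    stop("embedding row with wrong number of values")
  m <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(d)))
  if (d == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- vapply(toks, `[`, "", 1L)
  m
}
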