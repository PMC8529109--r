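## network: MENA-style correlation co-occurrence networks.
## Prevalence filter, pseudo-abundance fill, log transform, Pearson
## similarity, |r| threshold (fixed or random-matrix scan), greedy-modularity
## modules and the standard index panel; Cytoscape-compatible export.

#' Configure the co-occurrence network pipeline
#'
#' @param prevalenceMin features must be present (abundance > 0) in strictly
#'   more than this fraction of samples (default 0.5: "more than half").
#' @param fillValue pseudo-abundance replacing zero cells before the log
#'   transform (default 0.01).
#' @param logBase base of the log transform (default 10).
#' @param thresholdMethod `"fixed"` uses `st`; `"scan"` selects the
#'   similarity threshold from the adjacency eigenvalue-spacing statistics
#'   (random-matrix-theory transition heuristic).
#' @param st similarity threshold in (0, 1) for the fixed method.
#' @param scanRange ascending candidate thresholds for the scan.
#' @return a validated [NetworkConfig-class].
#' @export
networkConfig <- function(prevalenceMin = 0.5, fillValue = 0.01, logBase = 10,
                          thresholdMethod = c("fixed", "scan"), st = 0.8,
                          scanRange = seq(0.30, 0.99, by = 0.01)) {
  new("NetworkConfig", prevalenceMin = prevalenceMin, fillValue = fillValue,
      logBase = logBase, thresholdMethod = match.arg(thresholdMethod),
      st = st, scanRange = scanRange)
}

#' Prevalence-filter, fill and log-transform an abundance table
#'
#' Keeps features present (abundance > 0) in strictly more than
#' `prevalenceMin` of samples, replaces remaining zero cells with
#' `fillValue`, and applies the log transform.
#'
#' @param table samples x features [AbundanceTable-class] or matrix (>= 4
#'   samples).
#' @param config a [NetworkConfig-class].
#' @return the transformed samples x features matrix.
#' @export
prepareMatrix <- function(table, config = networkConfig()) {
  x <- asMatrixInput(table)
  if (nrow(x) < 4) stop("network preparation needs at least 4 samples")
  prevalence <- colMeans(x > 0)
  keep <- prevalence > config@prevalenceMin
  if (!any(keep))
    stop(sprintf(
      "no feature present in more than %.0f%% of samples; lower prevalenceMin",
      100 * config@prevalenceMin))
  x <- x[, keep, drop = FALSE]
  x[x == 0] <- config@fillValue
  log(x, base = config@logBase)
}

#' Pearson correlation matrix over features
#'
#' @param prepared samples x features matrix from [prepareMatrix()].
#' @return symmetric features x features Pearson matrix with unit diagonal.
#'   Zero-variance features (possible after the constant fill) are dropped
#'   with a warning.
#' @export
correlationMatrix <- function(prepared) {
  v <- apply(prepared, 2, var)
  if (any(v == 0)) {
    warning("zero-variance feature(s) dropped: ",
            paste(colnames(prepared)[v == 0], collapse = ", "))
    prepared <- prepared[, v > 0, drop = FALSE]
  }
  if (ncol(prepared) < 2) stop("need at least 2 features with variance")
  r <- cor(prepared)
  diag(r) <- 1
  r
}

## Nearest-neighbour eigenvalue spacing distribution of an adjacency matrix,
## normalized to unit mean spacing (global unfolding). Degenerate spectra
## (many coincident eigenvalues, typical of sparse modular graphs) pile
## spacings at zero, which is exactly the exponential (Poisson) signature.
eigenSpacings <- function(adj) {
  ev <- sort(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  s <- diff(ev)
  if (length(s) < 5 || mean(s) <= 0) return(numeric())
  s / mean(s)
}

## Chi-squared goodness of fit of unit-mean spacings against the Poisson
## (exponential) law and the Wigner surmise; smaller is a better fit.
spacingGof <- function(s) {
  s <- s[is.finite(s)]
  if (length(s) < 5) return(c(poisson = 0, wigner = Inf))
  breaks <- c(seq(0, 3, by = 0.5), Inf)
  obs <- as.numeric(table(cut(s, breaks, include.lowest = TRUE)))
  pExp <- diff(c(0, 1 - exp(-breaks[-1])))            # exponential, unit mean
  pWig <- diff(c(0, 1 - exp(-pi * breaks[-1]^2 / 4))) # Wigner surmise CDF
  n <- length(s)
  gof <- function(p) sum((obs - n * p)^2 / (n * p))
  c(poisson = gof(pExp), wigner = gof(pWig))
}

#' Select the similarity threshold
#'
#' With `thresholdMethod = "fixed"` simply returns `config@st`. With
#' `"scan"`, candidates are scanned in ascending order; at each, the
#' unweighted adjacency at that cutoff is built and the nearest-neighbour
#' spacing distribution of its eigenvalues is tested (chi-squared goodness of
#' fit) against the Poisson law versus the Wigner surmise. The smallest
#' cutoff at which the Poisson law fits better -- the random-matrix-theory
#' transition from correlated to uncorrelated spectra -- is returned; if no
#' candidate qualifies, the scan maximum is returned with a warning.
#'
#' @param corr features x features correlation matrix.
#' @param config a [NetworkConfig-class].
#' @return the selected threshold.
#' @export
selectThreshold <- function(corr, config = networkConfig()) {
  if (config@thresholdMethod == "fixed") return(config@st)
  if (nrow(corr) < 10)
    stop("scan method needs >= 10 features; use thresholdMethod = 'fixed'")
  for (st in config@scanRange) {
    adj <- (abs(corr) >= st) * 1
    diag(adj) <- 0
    if (sum(adj) == 0) return(st)  # empty spectrum is trivially Poisson-like
    gof <- spacingGof(eigenSpacings(adj))
    if (gof[["poisson"]] <= gof[["wigner"]]) return(st)
  }
  warning("no scan candidate preferred the Poisson law; returning the maximum")
  max(config@scanRange)
}

#' Build the signed co-occurrence network and its index panel
#'
#' An undirected edge joins every feature pair with `|r| >= st`; the edge
#' keeps `sign(r)` and `r` as attributes. Isolated features are excluded
#' (the node set is the set of edge endpoints). Modules come from greedy
#' modularity optimization on the unweighted, unsigned adjacency. The index
#' panel reports total nodes, total links, average connectivity
#' (`2 * links / nodes`), average local clustering coefficient (degree < 2
#' counted as 0), average geodesic distance over connected pairs, modularity
#' of the greedy partition, and the percentage of negative links.
#'
#' @param corr features x features Pearson matrix.
#' @param st similarity threshold in (0, 1).
#' @param classification optional named vector mapping feature id to a class
#'   attribute (phylum, or function level-1 category) carried into the node
#'   table.
#' @return a [NetworkResult-class]; with no qualifying edge, an empty
#'   network with all indexes 0 and a warning.
#' @export
buildNetwork <- function(corr, st, classification = NULL) {
  if (st <= 0 || st >= 1) stop("st must lie in (0, 1)")
  ids <- colnames(corr)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(corr)))
  ut <- which(upper.tri(corr) & abs(corr) >= st, arr.ind = TRUE)
  emptyIdx <- c(total_nodes = 0, total_links = 0, avg_connectivity = 0,
                avg_clustering_coefficient = 0, avg_geodesic_distance = 0,
                modularity = 0, pct_negative_links = 0)
  if (!nrow(ut)) {
    warning("no feature pair reaches the similarity threshold; empty network")
    return(new("NetworkResult",
               nodes = data.frame(id = character(),
                                  classification = character(),
                                  module = integer(), degree = integer()),
               edges = data.frame(source = character(), target = character(),
                                  sign = integer(), correlation = numeric()),
               indexes = emptyIdx, nComponents = 0, st = st))
  }
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  swap <- a > b
  src <- ifelse(swap, b, a); tgt <- ifelse(swap, a, b)
  r <- corr[ut]
  edges <- data.frame(source = src, target = tgt,
                      sign = ifelse(r >= 0, 1L, -1L), correlation = r,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges[c("source", "target")],
                                     directed = FALSE)
  comm <- igraph::cluster_fast_greedy(g)
  # cut the agglomeration at the modularity-maximizing step ourselves: the
  # default membership can return a worse cut on small graphs
  nComm <- igraph::vcount(g) - (which.max(comm$modularity) - 1L)
  membership <- igraph::cut_at(comm, no = nComm)
  names(membership) <- igraph::V(g)$name
  deg <- igraph::degree(g)
  nodes <- data.frame(id = igraph::V(g)$name,
                      classification = if (is.null(classification)) NA_character_
                        else unname(classification[igraph::V(g)$name]),
                      module = as.integer(membership),
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nNodes <- igraph::vcount(g)
  nLinks <- igraph::ecount(g)
  idx <- c(
    total_nodes = nNodes,
    total_links = nLinks,
    avg_connectivity = 2 * nLinks / nNodes,
    avg_clustering_coefficient =
      igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    avg_geodesic_distance = igraph::mean_distance(g, unconnected = TRUE),
    modularity = igraph::modularity(g, membership),
    pct_negative_links = 100 * sum(edges$sign < 0) / nLinks)
  new("NetworkResult", nodes = nodes, edges = edges, indexes = idx,
      nComponents = igraph::count_components(g), st = st)
}

#' Export a network as Cytoscape-compatible edge and node tables
#'
#' Writes `edges.tsv` (source, target, sign, correlation) and `nodes.tsv`
#' (id, classification, module, degree) in deterministic lexicographic
#' order; an empty network yields header-only files.
#'
#' @param net a [NetworkResult-class].
#' @param outDir output directory (created if missing).
#' @return character vector of the two paths, invisibly.
#' @export
exportCytoscape <- function(net, outDir) {
  stopifnot(is(net, "NetworkResult"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(outDir, "edges.tsv")
  node_path <- file.path(outDir, "nodes.tsv")
  edges <- net@edges
  edges$correlation <- formatC(edges$correlation, digits = 12, format = "g")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net@nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Re-read a Cytoscape export and rebuild the graph
#'
#' Round-trip companion to [exportCytoscape()]: reconstructs a
#' [NetworkResult-class] whose nodes, edges and index panel match the
#' exported network (indexes are recomputed from the graph).
#'
#' @param outDir directory holding `edges.tsv` and `nodes.tsv`.
#' @param st threshold annotation to attach.
#' @return a [NetworkResult-class].
#' @export
readCytoscape <- function(outDir, st = NA_real_) {
  edges <- utils::read.delim(file.path(outDir, "edges.tsv"),
                             stringsAsFactors = FALSE)
  nodes <- utils::read.delim(file.path(outDir, "nodes.tsv"),
                             stringsAsFactors = FALSE)
  n <- nrow(nodes)
  corr <- diag(1, max(n, 2))
  labels <- if (n) nodes$id else c("a", "b")
  dimnames(corr) <- list(labels, labels)
  if (nrow(edges))
    for (k in seq_len(nrow(edges))) {
      corr[edges$source[k], edges$target[k]] <- edges$correlation[k]
      corr[edges$target[k], edges$source[k]] <- edges$correlation[k]
    }
  cls <- if (n) setNames(nodes$classification, nodes$id) else NULL
  thr <- if (nrow(edges)) min(abs(edges$correlation)) else 0.99
  suppressWarnings(buildNetwork(corr, min(thr, 0.999999), cls))
}
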