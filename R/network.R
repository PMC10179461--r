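#' Build a bipartite lncRNA-mRNA interaction graph
#'
#' One node per distinct gene id and one undirected edge per distinct
#' (lncRNA, target) pair, regardless of how many modes (cis, trans) support
#' it.  Nodes carry a `node_type` attribute (`lncRNA` or `mRNA`); the
#' resulting graph is simple and bipartite.
#'
#' @param pairs Target-pair data.frame (`lncRNA_id`, `target_id`).
#' @return An `igraph` graph.
#' @export
build_network <- function(pairs) {
  if (any(pairs$lncRNA_id == pairs$target_id))
    stop2("validation_error", "pair with identical endpoint ids")
  lnc <- unique(pairs$lncRNA_id)
  mrna <- unique(pairs$target_id)
  both <- intersect(lnc, mrna)
  if (length(both) > 0L)
    stop2("validation_error", "id(s) on both sides of the bipartition: ",
          paste(head(both, 5L), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    unique(pairs[, c("lncRNA_id", "target_id")]),
    directed = FALSE,
    vertices = data.frame(name = c(lnc, mrna),
                          node_type = rep(c("lncRNA", "mRNA"),
                                          c(length(lnc), length(mrna))))
  )
  igraph::simplify(g)
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of size >= 2 (Bron-Kerbosch with pivoting), returned
#' as name vectors sorted within each clique and ordered lexicographically
#' across cliques, so the output is deterministic.
#'
#' @param g An undirected simple `igraph` graph.
#' @return A list of character vectors.
#' @export
maximal_cliques <- function(g) {
  cl <- igraph::max_cliques(g, min = 2L)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques `C` of size
#' at least 2 that contain `v`; isolated nodes score 0.  In a bipartite
#' graph every maximal clique is a single edge, so MCC equals the degree.
#'
#' @param g An undirected simple `igraph` graph.
#' @return Named numeric vector, node -> MCC.
#' @export
mcc <- function(g) {
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  for (cl in maximal_cliques(g))
    out[cl] <- out[cl] + factorial(length(cl) - 1L)
  out
}

#' Centrality computation settings
#'
#' @param dmnc_epsilon Exponent in the DMNC density (default 1.7).
#' @param epc_iterations Edge-percolation Monte-Carlo iterations (default
#'   1000).
#' @param epc_keep_prob Per-edge retention probability (default 0.5).
#' @param bottleneck_fraction Subtree-size fraction that makes a node a
#'   bottleneck in a BFS tree (default 0.25).
#' @param seed Seed for the percolation RNG.
#' @return A list of class `centrality_config`.
#' @export
centrality_config <- function(dmnc_epsilon = 1.7, epc_iterations = 1000L,
                              epc_keep_prob = 0.5, bottleneck_fraction = 0.25,
                              seed = 1L) {
  if (epc_keep_prob <= 0 || epc_keep_prob >= 1)
    stop2("config_error", "epc_keep_prob must be in (0, 1)")
  if (epc_iterations < 1L)
    stop2("config_error", "epc_iterations must be >= 1")
  structure(list(dmnc_epsilon = dmnc_epsilon,
                 epc_iterations = as.integer(epc_iterations),
                 epc_keep_prob = epc_keep_prob,
                 bottleneck_fraction = bottleneck_fraction,
                 seed = as.integer(seed)),
            class = "centrality_config")
}

# MNC / DMNC: largest connected component of the subgraph induced by N(v).
# MNC(v) is its node count; DMNC(v) = E / N^epsilon of that component,
# 0 when the neighborhood induces no edges.
mnc_dmnc <- function(g, epsilon) {
  vs <- igraph::V(g)
  mnc <- numeric(length(vs)); dmnc <- numeric(length(vs))
  for (i in seq_along(vs)) {
    nb <- igraph::neighbors(g, vs[i])
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    mnc[i] <- max(comp$csize)
    part <- igraph::induced_subgraph(sub, which(comp$membership == big))
    if (igraph::ecount(part) > 0L)
      dmnc[i] <- igraph::ecount(part) / igraph::vcount(part)^epsilon
  }
  list(mnc = mnc, dmnc = dmnc)
}

# EPC: mean over seeded edge percolations (each edge kept independently
# with probability keep_prob) of the size of v's surviving component,
# including v itself.
epc_centrality <- function(g, config) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  acc <- numeric(n)
  with_seed(config$seed, {
    for (k in seq_len(config$epc_iterations)) {
      keep <- which(runif(m) < config$epc_keep_prob)
      sub <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
      comp <- igraph::components(sub)
      acc <- acc + comp$csize[comp$membership]
    }
  })
  acc / config$epc_iterations
}

# Bottleneck: for each root s, grow the BFS shortest-path tree whose parent
# ties break lexicographically by node name; every non-root v whose subtree
# holds more than (tree size) * fraction nodes scores 1 for that tree.
bottleneck_centrality <- function(g, fraction) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  d <- igraph::distances(g)
  adj <- igraph::as_adj_list(g)
  score <- numeric(n)
  for (s in seq_len(n)) {
    reach <- which(is.finite(d[s, ]))
    tree_n <- length(reach)
    if (tree_n < 2L) next
    parent <- rep(NA_integer_, n)
    for (v in reach) {
      if (v == s) next
      cand <- as.integer(adj[[v]])
      cand <- cand[d[s, cand] == d[s, v] - 1]
      parent[v] <- cand[order(nm[cand])][1]
    }
    size <- rep(1L, n)
    for (v in reach[order(d[s, reach], decreasing = TRUE)]) {
      if (v == s) next
      size[parent[v]] <- size[parent[v]] + size[v]
    }
    hit <- reach[reach != s & size[reach] > tree_n * fraction]
    score[hit] <- score[hit] + 1
  }
  score
}

# Radiality: within v's component, sum of (diameter + 1 - d(v, t)) over the
# other members, divided by (component size - 1); 0 for isolated nodes.
radiality_centrality <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  out <- numeric(n)
  for (c_id in seq_len(comp$no)) {
    mem <- which(comp$membership == c_id)
    if (length(mem) < 2L) next
    dc <- d[mem, mem, drop = FALSE]
    diam <- max(dc)
    out[mem] <- rowSums(diam + 1 - dc) - (diam + 1)
    out[mem] <- out[mem] / (length(mem) - 1)
  }
  out
}

# Stress: number of shortest paths passing through v as an interior node,
# each unordered (s, t) pair counted once.  sigma[s, t] (shortest-path
# counts) comes from a BFS dynamic program per source.
stress_centrality <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  adj <- igraph::as_adj_list(g)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]))
    for (v in reach[order(d[s, reach])]) {
      if (v == s) next
      pred <- as.integer(adj[[v]])
      pred <- pred[d[s, pred] == d[s, v] - 1]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  out <- numeric(n)
  for (v in seq_len(n)) {
    ok <- outer(d[, v], d[v, ], "+") == d & is.finite(d)
    ok[v, ] <- FALSE; ok[, v] <- FALSE
    w <- outer(sigma[, v], sigma[v, ]) * ok
    out[v] <- sum(w) / 2
  }
  out
}

#' Full node-centrality suite
#'
#' Computes, per node, the eleven metrics of the standard hub-screening
#' table: MCC, DMNC, MNC, Degree, EPC, Bottleneck, Eccentricity (as
#' `1/ecc` within the node's component; 0 for isolated nodes), Closeness
#' (harmonic: sum of inverse distances, unreachable pairs contributing 0),
#' Radiality, Betweenness (Freeman) and Stress.  Rows are sorted by MCC
#' descending, ties by Degree descending, then node name.  EPC uses the
#' seeded RNG in `config`, so the full table is deterministic given
#' `(graph, config)`.
#'
#' @param g An undirected simple `igraph` graph.
#' @param config A [centrality_config()].
#' @return A data.frame with `node`, `node_type` (if present in `g`) and
#'   the eleven metric columns in table order.
#' @export
centrality_suite <- function(g, config = centrality_config()) {
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  md <- mnc_dmnc(g, config$dmnc_epsilon)
  ecc <- igraph::eccentricity(g)
  tab <- data.frame(
    node = nm,
    MCC = unname(mcc(g)),
    DMNC = md$dmnc,
    MNC = md$mnc,
    Degree = unname(deg),
    EPC = epc_centrality(g, config),
    Bottleneck = bottleneck_centrality(g, config$bottleneck_fraction),
    Eccentricity = ifelse(ecc > 0, 1 / ecc, 0),
    Closeness = unname(igraph::harmonic_centrality(g, normalized = FALSE)),
    Radiality = radiality_centrality(g),
    Betweenness = unname(igraph::betweenness(g)),
    Stress = stress_centrality(g),
    stringsAsFactors = FALSE
  )
  nt <- igraph::vertex_attr(g, "node_type")
  if (!is.null(nt)) tab <- cbind(tab[1], node_type = nt, tab[-1])
  tab <- tab[order(-tab$MCC, -tab$Degree, tab$node), ]
  rownames(tab) <- NULL
  tab
}

#' Select hub lncRNAs by MCC
#'
#' lncRNA nodes whose MCC is at least `min_mcc` (inclusive threshold), plus
#' the subnetwork they induce together with all their neighbors.
#'
#' @param table A centrality table from [centrality_suite()] (or any
#'   data.frame with `node` and `MCC`; rows restricted to lncRNAs when a
#'   `node_type` column is present).
#' @param g Optional graph from which to extract the hub subnetwork.
#' @param min_mcc MCC threshold (default 30, inclusive).
#' @return A list with `hubs` (character vector of node ids) and
#'   `subnetwork` (an `igraph` graph, or `NULL` when `g` is missing).
#' @export
select_hubs <- function(table, g = NULL, min_mcc = 30) {
  if (nrow(table) == 0L) stop2("empty_input", "empty centrality table")
  rows <- table
  if (!is.null(rows$node_type)) rows <- rows[rows$node_type == "lncRNA", ]
  hubs <- rows$node[rows$MCC >= min_mcc]
  sub <- NULL
  if (!is.null(g) && length(hubs) > 0L) {
    nb <- unique(unlist(lapply(hubs, function(h)
      igraph::V(g)$name[igraph::neighbors(g, h)])))
    sub <- igraph::induced_subgraph(g, c(hubs, setdiff(nb, hubs)))
  }
  list(hubs = hubs, subnetwork = sub)
}

#' Graph I/O: simple interaction format (SIF) and GraphML
#'
#' SIF lines are `source <tab> interacts <tab> target`; isolated nodes are
#' written as a bare node name.
#'
#' @param g An `igraph` graph.
#' @param path Output path.
#' @export
write_sif <- function(g, path) {
  e <- igraph::as_edgelist(g)
  lines <- character(0)
  if (nrow(e) > 0L) lines <- paste(e[, 1], "interacts", e[, 2], sep = "\t")
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges <- do.call(rbind, Filter(function(p) length(p) >= 3L, parts))
  iso <- unlist(Filter(function(p) length(p) == 1L, parts))
  g <- igraph::make_empty_graph(directed = FALSE)
  verts <- unique(c(if (!is.null(edges)) c(edges[, 1], edges[, 3]), iso))
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (!is.null(edges))
    g <- igraph::add_edges(g, rbind(match(edges[, 1], verts),
                                    match(edges[, 3], verts)))
  igraph::simplify(g)
}

#' @rdname write_sif
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a centrality table as TSV in the standard column order
#' @param table Centrality table.
#' @param path Output path.
#' @export
write_centrality_table <- function(table, path) {
  cols <- c("node", "MCC", "DMNC", "MNC", "Degree", "EPC", "Bottleneck",
            "Eccentricity", "Closeness", "Radiality", "Betweenness", "Stress")
  out <- table[, c(cols[1], intersect("node_type", names(table)), cols[-1])]
  names(out)[1] <- "Node_Name"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
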