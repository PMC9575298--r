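# Thresholded joint association network over taxa (T), functional modules
# (M) and psychopathology scores (PP), and enumeration of the tripartite
# triangle motifs that link one node of each modality.

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Deduplicate an edge list on unordered node pairs
#'
#' Identical duplicate rows are collapsed silently. When duplicate rows of
#' the same unordered pair disagree on `log10_bf` (as can happen in
#' hand-transcribed edge lists), the row with the maximum `log10_bf` is kept
#' and a warning names the conflict.
#'
#' @param edges Edge data frame with columns `node_a`, `node_b`, `log10_bf`.
#' @return The deduplicated edge data frame.
#' @export
dedup_edges <- function(edges) {
  key <- edge_key(edges$node_a, edges$node_b)
  keep <- rep(TRUE, nrow(edges))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    bfs <- edges$log10_bf[idx]
    if (diff(range(bfs)) > 0)
      warning(sprintf(
        "conflicting duplicate edge %s ~ %s (log10_bf %s); keeping maximum",
        edges$node_a[idx[1L]], edges$node_b[idx[1L]],
        paste(format(sort(unique(bfs))), collapse = " vs ")))
    keep[idx] <- FALSE
    keep[idx[which.max(bfs)]] <- TRUE
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a thresholded association network
#'
#' Binarises the joint Bayesian correlation structure: an edge enters the
#' network when its evidence reaches `log10_bf >= threshold` (inclusive, so
#' an edge at exactly the threshold is kept). Nodes whose every edge falls
#' below the threshold are retained as isolated nodes.
#'
#' @param edges Edge data frame (see [joint_edge_matrix()]), deduplicated on
#'   unordered pairs.
#' @param threshold The log10 Bayes-factor cut (default 0.5, i.e. H1 at
#'   least about three times as likely as H0).
#' @return An object of class `association_network`: a list with `nodes`
#'   (data frame `id`, `modality`), `edges` (the surviving edges) and
#'   `threshold`.
#' @export
build_network <- function(edges, threshold = 0.5) {
  req <- c("node_a", "node_b", "modality_a", "modality_b", "log10_bf", "rho")
  missing_cols <- setdiff(req, colnames(edges))
  if (length(missing_cols) > 0L)
    stop("edge list lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(edges$node_a == edges$node_b))
    stop("self-loop edge(s) are not allowed")
  if (anyDuplicated(edge_key(edges$node_a, edges$node_b)))
    stop("duplicate unordered pairs; run dedup_edges() first")
  nodes <- unique(data.frame(
    id = c(edges$node_a, edges$node_b),
    modality = c(edges$modality_a, edges$modality_b),
    stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$id))
    stop("node(s) with inconsistent modality: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  kept <- edges[edges$log10_bf >= threshold, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(nodes = nodes, edges = kept, threshold = threshold),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf(
    "association_network: %d nodes (%s), %d edges at log10(BF10) >= %g\n",
    nrow(x$nodes),
    paste(sprintf("%s=%d", names(table(x$nodes$modality)),
                  as.integer(table(x$nodes$modality))), collapse = ", "),
    nrow(x$edges), x$threshold))
  invisible(x)
}

net_neighbours <- function(net, node) {
  e <- net$edges
  c(e$node_b[e$node_a == node], e$node_a[e$node_b == node])
}

#' Enumerate tripartite triangle motifs around a psychopathology node
#'
#' A triangle motif of interest is a three-node clique with exactly one
#' taxon node, one module node and the given psychopathology node, i.e. a
#' taxon and a functional module associated with each other and each
#' associated with the symptom score. Enumeration is exhaustive over the
#' taxa and modules adjacent to the psychopathology node and deterministic:
#' motifs are sorted by taxon, then module identifier.
#'
#' @param net An `association_network`.
#' @param pp_node Identifier of a node with modality `"PP"`.
#' @return A data frame with one row per motif: `taxon`, `module`, `pp`, the
#'   three edges' statistics (`log10_bf_tm`, `rho_tm`, `log10_bf_tp`,
#'   `rho_tp`, `log10_bf_mp`, `rho_mp`) and `direction_pattern`, the signs
#'   of the three Spearman coefficients in that order.
#' @export
enumerate_tripartite_triangles <- function(net, pp_node) {
  stopifnot(inherits(net, "association_network"))
  if (!pp_node %in% net$nodes$id)
    stop(sprintf("node '%s' is not in the network", pp_node))
  if (net$nodes$modality[net$nodes$id == pp_node] != "PP")
    stop(sprintf("node '%s' does not have modality PP", pp_node))
  modality <- stats::setNames(net$nodes$modality, net$nodes$id)
  nb <- unique(net_neighbours(net, pp_node))
  taxa <- sort(nb[modality[nb] == "T"])
  mods <- sort(nb[modality[nb] == "M"])
  if (length(taxa) == 0L || length(mods) == 0L)
    return(empty_motif_df())
  keys <- edge_key(net$edges$node_a, net$edges$node_b)
  lookup <- function(a, b) {
    i <- match(edge_key(a, b), keys)
    net$edges[i, c("log10_bf", "rho")]
  }
  rows <- list()
  for (t in taxa) {
    for (m in mods) {
      if (is.na(match(edge_key(t, m), keys))) next
      tm <- lookup(t, m); tp <- lookup(t, pp_node); mp <- lookup(m, pp_node)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = t, module = m, pp = pp_node,
        log10_bf_tm = tm$log10_bf, rho_tm = tm$rho,
        log10_bf_tp = tp$log10_bf, rho_tp = tp$rho,
        log10_bf_mp = mp$log10_bf, rho_mp = mp$rho,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_motif_df())
  out <- do.call(rbind, rows)
  out$direction_pattern <- paste(
    ifelse(out$rho_tm >= 0, "+", "-"),
    ifelse(out$rho_tp >= 0, "+", "-"),
    ifelse(out$rho_mp >= 0, "+", "-"))
  out <- out[order(out$taxon, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_motif_df <- function() {
  data.frame(taxon = character(0), module = character(0), pp = character(0),
             log10_bf_tm = numeric(0), rho_tm = numeric(0),
             log10_bf_tp = numeric(0), rho_tp = numeric(0),
             log10_bf_mp = numeric(0), rho_mp = numeric(0),
             direction_pattern = character(0), stringsAsFactors = FALSE)
}

#' Long-format motif report
#'
#' Unrolls each motif into its three member associations (taxon-module,
#' taxon-symptom, module-symptom), each with its `log10_bf` and Spearman
#' `rho` - the layout of a published motif table.
#'
#' @param motifs Motif data frame from [enumerate_tripartite_triangles()].
#' @return A data frame with three rows per motif: `motif_id`, `pair`
#'   (`"taxon-module"`, `"taxon-pp"`, `"module-pp"`), `node_a`, `node_b`,
#'   `log10_bf`, `rho`.
#' @export
motif_table <- function(motifs) {
  if (nrow(motifs) == 0L)
    return(data.frame(motif_id = integer(0), pair = character(0),
                      node_a = character(0), node_b = character(0),
                      log10_bf = numeric(0), rho = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- motifs[i, ]
    data.frame(
      motif_id = i,
      pair = c("taxon-module", "taxon-pp", "module-pp"),
      node_a = c(m$taxon, m$taxon, m$module),
      node_b = c(m$module, m$pp, m$pp),
      log10_bf = c(m$log10_bf_tm, m$log10_bf_tp, m$log10_bf_mp),
      rho = c(m$rho_tm, m$rho_tp, m$rho_mp),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise motifs per psychopathology node
#'
#' @param motifs Motif data frame (possibly covering several `pp` nodes).
#' @return A data frame with one row per `pp` node: `pp`, `n_motifs`,
#'   `n_taxa` (distinct genera) and `n_modules` (distinct modules). Zero
#'   rows for an empty motif list.
#' @export
summarize_motifs <- function(motifs) {
  if (nrow(motifs) == 0L)
    return(data.frame(pp = character(0), n_motifs = integer(0),
                      n_taxa = integer(0), n_modules = integer(0),
                      stringsAsFactors = FALSE))
  pps <- sort(unique(motifs$pp))
  out <- do.call(rbind, lapply(pps, function(p) {
    m <- motifs[motifs$pp == p, , drop = FALSE]
    data.frame(pp = p, n_motifs = nrow(m),
               n_taxa = length(unique(m$taxon)),
               n_modules = length(unique(m$module)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Motif-sufficient edge screening
#'
#' Computes exactly the edges that can participate in a tripartite triangle
#' at the given threshold, without materialising the full
#' taxon x module Bayes-factor matrix: first every feature-score edge, then
#' taxon-module edges only for pairs in which both features reach the
#' threshold against a common score. The motifs enumerated from the
#' resulting edge list are identical to those from the full joint matrix,
#' because a triangle requires all three of its edges to clear the
#' threshold.
#'
#' @param taxa,modules `transformed_table`s (or matrices via `node_block`)
#'   of taxon and module values.
#' @param pp Samples x scores matrix of psychopathology scores.
#' @param rscale,method Passed to [jzs_log10_bf_from_r()].
#' @param threshold Network threshold on `log10_bf` (default 0.5).
#' @return An edge data frame in the format of [joint_edge_matrix()]
#'   containing all feature-score edges plus the screened taxon-module
#'   edges.
#' @export
screen_motif_edges <- function(taxa, modules, pp, rscale = 0.354,
                               method = c("regression", "stretched-beta"),
                               threshold = 0.5) {
  method <- match.arg(method)
  bt <- as_node_block(taxa)
  bm <- as_node_block(modules)
  bp <- node_block(pp, "PP")
  stopifnot(identical(rownames(bt$values), rownames(bp$values)),
            identical(rownames(bm$values), rownames(bp$values)))
  pair_edge <- function(vals_a, vals_b, na, nb, ma, mb) {
    frag <- tryCatch(
      pair_log10_bf(vals_a, vals_b, rscale = rscale, method = method),
      error = function(e) NULL)
    if (is.null(frag)) return(NULL)
    data.frame(node_a = na, node_b = nb, modality_a = ma, modality_b = mb,
               n_obs = frag$n_obs, log10_bf = frag$log10_bf,
               rho = spearman_rho(vals_a, vals_b), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (s in colnames(bp$values)) {
    for (t in colnames(bt$values))
      rows[[length(rows) + 1L]] <-
        pair_edge(bt$values[, t], bp$values[, s], t, s, "T", "PP")
    for (m in colnames(bm$values))
      rows[[length(rows) + 1L]] <-
        pair_edge(bm$values[, m], bp$values[, s], m, s, "M", "PP")
  }
  pp_edges <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  tm_rows <- list()
  done <- character(0)
  if (!is.null(pp_edges) && nrow(pp_edges) > 0L) {
    hot <- pp_edges[pp_edges$log10_bf >= threshold, , drop = FALSE]
    for (s in unique(hot$node_b)) {
      ts <- hot$node_a[hot$node_b == s & hot$modality_a == "T"]
      ms <- hot$node_a[hot$node_b == s & hot$modality_a == "M"]
      for (t in ts) for (m in ms) {
        k <- edge_key(t, m)
        if (k %in% done) next
        done <- c(done, k)
        tm_rows[[length(tm_rows) + 1L]] <-
          pair_edge(bt$values[, t], bm$values[, m], t, m, "T", "M")
      }
    }
  }
  out <- rbind(pp_edges,
               do.call(rbind, tm_rows[!vapply(tm_rows, is.null, TRUE)]))
  rownames(out) <- NULL
  out$evidence <- classify_evidence(out$log10_bf)
  out
}

#' Convert an association network to an igraph object
#'
#' @param net An `association_network`.
#' @return An undirected `igraph` graph with `modality` vertex attribute and
#'   `log10_bf`, `rho` edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "association_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b", "log10_bf", "rho")],
    directed = FALSE, vertices = net$nodes)
  g
}

#' Export an association network as GraphML
#'
#' @param net An `association_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
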