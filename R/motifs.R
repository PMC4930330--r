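# Circuit graphs ---------------------------------------------------------------

#' Build a circuit graph
#'
#' A weighted directed graph over neurons (or bilateral pair identities),
#' typically built from consistency-filtered edges. Node cell types drive the
#' motif queries.
#'
#' @param edges `data.frame` with columns `source`, `target`, `weight`
#'   (synapse counts) and optionally `compartment`.
#' @param node_types named character vector: node id -> cell type.
#' @return object of class `circuit_graph`.
#' @export
circuit_graph <- function(edges, node_types) {
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  nodes <- union(names(node_types), union(edges$source, edges$target))
  missing_ty <- setdiff(nodes, names(node_types))
  if (length(missing_ty)) {
    stop("no cell type for node(s): ", paste(missing_ty, collapse = ", "))
  }
  structure(list(edges = edges, node_types = node_types, nodes = nodes),
            class = "circuit_graph")
}

#' Circuit graph from kept bilateral edges
#'
#' @param kept result of [kept_edges()] (pair-level edges with per-side
#'   counts); the edge weight is the mean of the two sides' counts.
#' @param node_types named character vector: pair id -> cell type.
#' @return a [circuit_graph()].
#' @export
circuit_graph_from_kept <- function(kept, node_types) {
  edges <- data.frame(source = kept$source, target = kept$target,
                      weight = (kept$left_count + kept$right_count) / 2,
                      stringsAsFactors = FALSE)
  circuit_graph(edges, node_types)
}

#' @export
print.circuit_graph <- function(x, ...) {
  cat(sprintf("<circuit_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

has_edge <- function(graph, a, b) {
  any(graph$edges$source == a & graph$edges$target == b)
}

edge_weight <- function(graph, a, b) {
  w <- graph$edges$weight[graph$edges$source == a & graph$edges$target == b]
  if (length(w)) sum(w) else 0
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "weight")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

# Input motif census ------------------------------------------------------------

#' Census of direct / lateral / feedforward-loop input motifs
#'
#' For each source (default ORN) and a given target, classifies the source's
#' influence: *direct* if it synapses onto the target and reaches it through
#' no relay, *lateral* if it reaches the target only through a relay
#' interneuron (a path of length exactly 2 via the relay class), and
#' *feedforward loop* if both routes exist (the incoherent feedforward-loop
#' motif, an ORN exciting a target while also inhibiting it via a relay).
#' The three classes partition the sources influencing the target.
#'
#' @param graph a [circuit_graph()], already consistency-filtered.
#' @param target target node id (e.g. an mPN).
#' @param source_class,relay_class cell types of sources and relays.
#' @return `data.frame` with one row per (source, target) influence:
#'   `motif` in `{"direct", "lateral", "feedforward_loop"}`, the relays
#'   involved, and the direct-edge weight.
#' @export
input_motifs <- function(graph, target, source_class = "ORN",
                         relay_class = "PickyLN") {
  if (!target %in% graph$nodes) stop("target not in graph: ", target)
  ty <- graph$node_types
  sources <- graph$nodes[ty[graph$nodes] == source_class]
  relays <- graph$nodes[ty[graph$nodes] == relay_class]
  out <- list()
  for (s in sources) {
    direct <- has_edge(graph, s, target)
    via <- relays[vapply(relays, function(r)
      has_edge(graph, s, r) && has_edge(graph, r, target), logical(1))]
    lateral <- length(via) > 0
    if (!direct && !lateral) next
    motif <- if (direct && lateral) "feedforward_loop"
             else if (direct) "direct" else "lateral"
    out[[length(out) + 1L]] <- data.frame(
      source = s, target = target, motif = motif,
      relays = paste(via, collapse = ";"),
      direct_weight = if (direct) edge_weight(graph, s, target) else 0,
      stringsAsFactors = FALSE
    )
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(source = character(), target = character(), motif = character(),
               relays = character(), direct_weight = numeric(),
               stringsAsFactors = FALSE)
}

# Hierarchy layers ---------------------------------------------------------------

#' Layered hierarchy of a neuron class
#'
#' Operationalizes a "hierarchy" drawing: the subgraph is condensed into
#' strongly connected components (reciprocally connected neurons merge into
#' one component, reported as such), then components are ranked by
#' longest-path layering from the top (rank 0 = components with no incoming
#' edge; rank of a component = longest path from any rank-0 component).
#' "Dominant" nodes are rank-0 nodes with maximal out-reach (number of nodes
#' reachable downstream). Node pairs with no path in either direction are
#' flagged as parallel.
#'
#' @param graph a [circuit_graph()] (typically restricted to one class, e.g.
#'   the Picky LNs).
#' @param nodes optional node subset (default: all graph nodes).
#' @return list of class `hierarchy_layers`: `ranks` (named vector),
#'   `components` (membership), `reciprocal_components` (multi-node SCCs),
#'   `dominant`, `out_reach`, `parallel` (data.frame of incomparable pairs).
#' @export
hierarchy_layers <- function(graph, nodes = NULL) {
  if (is.null(nodes)) nodes <- graph$nodes
  ed <- graph$edges[graph$edges$source %in% nodes &
                      graph$edges$target %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ed[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  sc <- igraph::components(g, mode = "strong")
  memb <- sc$membership
  # condensation DAG
  cm <- unique(data.frame(from = memb[ed$source], to = memb[ed$target]))
  cm <- cm[cm$from != cm$to, , drop = FALSE]
  ncomp <- sc$no
  preds <- split(cm$from, factor(cm$to, levels = seq_len(ncomp)))
  succs <- split(cm$to, factor(cm$from, levels = seq_len(ncomp)))
  # longest-path layering over the DAG (topological order by repeated relaxation)
  rank <- rep(0L, ncomp)
  indeg <- vapply(preds, length, integer(1))
  queue <- which(indeg == 0L)
  indeg_left <- indeg
  while (length(queue)) {
    c0 <- queue[[1]]; queue <- queue[-1]
    for (s in succs[[c0]]) {
      rank[s] <- max(rank[s], rank[c0] + 1L)
      indeg_left[s] <- indeg_left[s] - 1L
      if (indeg_left[s] == 0L) queue <- c(queue, s)
    }
  }
  ranks <- stats::setNames(rank[memb], names(memb))
  # out-reach: nodes reachable downstream (excluding self)
  reach <- vapply(nodes, function(n) {
    length(igraph::subcomponent(g, n, mode = "out")) - 1L
  }, integer(1))
  top <- names(ranks)[ranks == 0L]
  dominant <- top[reach[top] == max(reach[top])]
  # parallel (incomparable) pairs
  par <- list()
  if (length(nodes) > 1) {
    for (i in seq_along(nodes)[-length(nodes)]) {
      for (j in seq((i + 1), length(nodes))) {
        a <- nodes[i]; b <- nodes[j]
        ab <- b %in% names(igraph::subcomponent(g, a, mode = "out"))
        ba <- a %in% names(igraph::subcomponent(g, b, mode = "out"))
        if (!ab && !ba) par[[length(par) + 1L]] <-
          data.frame(a = a, b = b, stringsAsFactors = FALSE)
      }
    }
  }
  parallel <- if (length(par)) do.call(rbind, par) else
    data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  recip <- split(names(memb), memb)
  recip <- recip[vapply(recip, length, integer(1)) > 1]
  structure(
    list(ranks = ranks, components = memb,
         reciprocal_components = unname(recip),
         dominant = dominant, out_reach = reach, parallel = parallel),
    class = "hierarchy_layers")
}

#' @export
print.hierarchy_layers <- function(x, ...) {
  cat("<hierarchy_layers>\n")
  for (r in sort(unique(x$ranks))) {
    cat(sprintf("  rank %d: %s\n", r,
                paste(names(x$ranks)[x$ranks == r], collapse = ", ")))
  }
  cat("  dominant:", paste(x$dominant, collapse = ", "), "\n")
  if (nrow(x$parallel)) {
    cat(sprintf("  parallel pairs: %s\n",
                paste(paste(x$parallel$a, x$parallel$b, sep = " || "),
                      collapse = "; ")))
  }
  invisible(x)
}

# Reciprocal cores ---------------------------------------------------------------

#' Reciprocally connected pairs between two classes
#'
#' Reports pairs (a, b) with a -> b and b -> a both at or above a minimum
#' weight — e.g. the core reciprocal inhibition between the Broad LN Trio and
#' Keystone.
#'
#' @param graph a [circuit_graph()] (filtered).
#' @param class_a,class_b cell types (may be equal).
#' @param min_weight minimum weight in each direction.
#' @return `data.frame` with columns `a`, `b`, `weight_ab`, `weight_ba`.
#' @export
reciprocal_cores <- function(graph, class_a, class_b, min_weight = 1) {
  ty <- graph$node_types
  as_ <- graph$nodes[ty[graph$nodes] == class_a]
  bs_ <- graph$nodes[ty[graph$nodes] == class_b]
  out <- list()
  for (a in as_) for (b in bs_) {
    if (a == b) next
    if (class_a == class_b && a > b) next  # report unordered pairs once
    wab <- edge_weight(graph, a, b); wba <- edge_weight(graph, b, a)
    if (wab >= min_weight && wba >= min_weight) {
      out[[length(out) + 1L]] <- data.frame(
        a = a, b = b, weight_ab = wab, weight_ba = wba,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a = character(), b = character(), weight_ab = numeric(),
               weight_ba = numeric(), stringsAsFactors = FALSE)
}

#' Group-level self-arrow weight
#'
#' For a group of neurons of one type, the average number of synapses one
#' member receives from the other members (the convention behind self-arrows
#' in grouped wiring-diagram cartoons).
#'
#' @param diagram a [wiring_diagram()].
#' @param members neuron ids of the group.
#' @return mean within-group input count per member.
#' @export
group_self_weight <- function(diagram, members) {
  syn <- diagram$synapses
  within <- syn$pre_neuron %in% members & syn$post_neuron %in% members &
    syn$pre_neuron != syn$post_neuron
  sum(within) / length(members)
}

# Inhibition profiles -------------------------------------------------------------

#' Per-glomerulus inhibition profile
#'
#' For each glomerulus, the percentage of compartment-restricted postsynaptic
#' sites (on the glomerulus ORN's axon terminals for presynaptic inhibition,
#' or its uPN's dendrite for postsynaptic inhibition) contributed by each
#' source group. The heterogeneity of a source group across glomeruli is
#' summarised by the coefficient of variation: a panglomerular, uniform
#' inhibitor has a low CV, a selective one that skips glomeruli a high CV.
#'
#' @param diagram a [wiring_diagram()].
#' @param source_groups named list of presynaptic neuron id groups.
#' @param target `"ORN_axon"` (presynaptic inhibition) or `"uPN_dendrite"`
#'   (postsynaptic inhibition).
#' @param side restrict target neurons to one side (default `"right"`).
#' @param compartments from [compartment_maps()]; computed when `NULL`.
#' @return list of class `inhibition_profile`: `percent` (glomeruli x
#'   groups), `counts`, `totals`, `cv` (per group), `excluded` glomeruli.
#' @export
inhibition_profile <- function(diagram, source_groups,
                               target = c("ORN_axon", "uPN_dendrite"),
                               side = "right", compartments = NULL) {
  target <- match.arg(target)
  if (is.null(compartments)) compartments <- compartment_maps(diagram)
  nr <- diagram$neurons
  ttype <- if (target == "ORN_axon") "ORN" else "uPN"
  tcomp <- if (target == "ORN_axon") "axon" else "dendrite"
  tg <- nr[nr$cell_type == ttype & nr$side == side &
             !isTRUE_vec(nr$is_fragment), , drop = FALSE]
  gloms <- tg$glomerulus
  counts <- count_matrix(diagram, rows = source_groups, cols = tg$id,
                         compartment = tcomp, compartments = compartments)
  totals <- postsynaptic_totals(diagram, tg$id, compartment = tcomp,
                                compartments = compartments)
  keep <- totals > 0
  excluded <- gloms[!keep]
  if (any(!keep)) {
    warning("glomeruli without ", tcomp, " postsynaptic sites excluded: ",
            paste(excluded, collapse = ", "))
  }
  pct <- sweep(unclass(counts)[, keep, drop = FALSE] * 100, 2,
               totals[keep], "/")
  colnames(pct) <- gloms[keep]
  pct <- t(pct)  # glomeruli x groups
  cv <- apply(pct, 2, function(x)
    if (mean(x) == 0) NA_real_ else stats::sd(x) / mean(x))
  structure(list(percent = pct, counts = t(unclass(counts)[, keep, drop = FALSE]),
                 totals = totals[keep], cv = cv, excluded = excluded),
            class = "inhibition_profile")
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat(sprintf("<inhibition_profile> %d glomeruli x %d source groups\n",
              nrow(x$percent), ncol(x$percent)))
  cat("  coefficient of variation across glomeruli:\n")
  for (g in colnames(x$percent)) {
    cat(sprintf("    %-20s %.3f\n", g, x$cv[[g]]))
  }
  invisible(x)
}

# Display weighting ----------------------------------------------------------------

#' Display edge weights under a scaling
#'
#' Returns a copy of the graph with a `display_weight` column: linear (the
#' raw synapse count) or square-root scaled, the two conventions used for
#' weighted-arrow wiring cartoons. The underlying counts are untouched.
#'
#' @param graph a [circuit_graph()].
#' @param scaling `"linear"` or `"sqrt"`.
#' @return the graph, with `edges$display_weight` added.
#' @export
edge_weight_views <- function(graph, scaling = c("linear", "sqrt")) {
  scaling <- match.arg(scaling)
  graph$edges$display_weight <- switch(scaling,
    linear = graph$edges$weight,
    sqrt = sqrt(graph$edges$weight))
  graph$scaling <- scaling
  graph
}
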