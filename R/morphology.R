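# Tree helpers --------------------------------------------------------------

children_index <- function(nodes) {
  split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
}

# ids of `node` plus all its descendants (iterative BFS)
subtree_nodes <- function(skel, node) {
  kids <- children_index(skel$nodes)
  out <- character(0); queue <- node
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    out <- c(out, n)
    queue <- c(queue, kids[[n]])
  }
  out
}

tagged_nodes <- function(skel, tag) skel$tags$node_id[skel$tags$tag == tag]

edge_lengths <- function(skel) {
  nodes <- skel$nodes
  i <- match(nodes$parent_id, nodes$node_id)
  has_parent <- !is.na(nodes$parent_id)
  len <- rep(0, nrow(nodes))
  len[has_parent] <- sqrt(
    (nodes$x[has_parent] - nodes$x[i[has_parent]])^2 +
    (nodes$y[has_parent] - nodes$y[i[has_parent]])^2 +
    (nodes$z[has_parent] - nodes$z[i[has_parent]])^2
  )
  names(len) <- nodes$node_id  # length of the edge to each node's parent
  len
}

# Compartment labelling ------------------------------------------------------

#' Label axon, dendrite and soma compartments of a skeleton
#'
#' Every node in the subtree(s) rooted at nodes tagged `"axon start"` is
#' labelled `axon`; nodes tagged `"soma"` are labelled `soma`; all remaining
#' nodes are `dendrite`. A skeleton with no axon-start tag (an axonless local
#' neuron, like the Broad LNs) gets zero axon nodes.
#'
#' @param skel a [skeleton()].
#' @param axon_tag tag marking the root of the axonal subtree.
#' @param soma_tag tag marking soma nodes.
#' @return named character vector (`node_id` -> `"axon"`, `"dendrite"` or
#'   `"soma"`), one entry per node.
#' @export
label_compartments <- function(skel, axon_tag = "axon start", soma_tag = "soma") {
  nodes <- skel$nodes
  lab <- rep("dendrite", nrow(nodes))
  names(lab) <- nodes$node_id
  starts <- tagged_nodes(skel, axon_tag)
  bad <- setdiff(c(starts, tagged_nodes(skel, soma_tag)), nodes$node_id)
  if (length(bad)) {
    stop(sprintf("skeleton %s: tag on non-existent node(s) %s",
                 skel$neuron_id, paste(bad, collapse = ", ")))
  }
  for (s in starts) lab[subtree_nodes(skel, s)] <- "axon"
  lab[tagged_nodes(skel, soma_tag)] <- "soma"
  lab
}

#' Compartment maps for every skeleton in a diagram
#'
#' @param diagram a [wiring_diagram()].
#' @inheritParams label_compartments
#' @return named list of [label_compartments()] vectors, one per skeleton.
#' @export
compartment_maps <- function(diagram, axon_tag = "axon start", soma_tag = "soma") {
  lapply(diagram$skeletons, label_compartments,
         axon_tag = axon_tag, soma_tag = soma_tag)
}

# Cable metrics ---------------------------------------------------------------

#' Cable length of a skeleton
#'
#' Sum of Euclidean parent-child edge lengths, in micrometres. With a
#' compartment restriction, an edge is attributed to the compartment of its
#' child node, so lengths are additive across compartments.
#'
#' @param skel a [skeleton()].
#' @param compartment optional `"axon"`, `"dendrite"` or `"soma"`.
#' @param compartments precomputed [label_compartments()] vector (computed on
#'   the fly when `NULL` and a restriction is requested).
#' @return cable length in micrometres.
#' @export
cable_length <- function(skel, compartment = NULL, compartments = NULL) {
  len <- edge_lengths(skel)
  if (!is.null(compartment)) {
    if (is.null(compartments)) compartments <- label_compartments(skel)
    len <- len[compartments[names(len)] == compartment]
  }
  sum(len)
}

# Geodesic distances ----------------------------------------------------------

# distance from every node to the root, along the cable
dist_to_root <- function(skel) {
  nodes <- skel$nodes
  len <- edge_lengths(skel)
  d <- rep(NA_real_, nrow(nodes)); names(d) <- nodes$node_id
  kids <- children_index(nodes)
  root <- nodes$node_id[is.na(nodes$parent_id)]
  stopifnot(length(root) == 1L)
  d[root] <- 0
  queue <- root
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    for (k in kids[[n]]) {
      d[k] <- d[n] + len[k]
      queue <- c(queue, k)
    }
  }
  d
}

node_depths <- function(skel) {
  nodes <- skel$nodes
  depth <- rep(NA_integer_, nrow(nodes)); names(depth) <- nodes$node_id
  kids <- children_index(nodes)
  root <- nodes$node_id[is.na(nodes$parent_id)]
  depth[root] <- 0L
  queue <- root
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    for (k in kids[[n]]) { depth[k] <- depth[n] + 1L; queue <- c(queue, k) }
  }
  depth
}

#' Geodesic distance between two skeleton nodes
#'
#' Path length along the cable (through the tree), not straight-line
#' distance.
#'
#' @param skel a [skeleton()].
#' @param a,b node ids.
#' @return distance in micrometres.
#' @export
geodesic_distance <- function(skel, a, b) {
  d <- dist_to_root(skel)
  depth <- node_depths(skel)
  parent <- skel$nodes$parent_id; names(parent) <- skel$nodes$node_id
  # walk the deeper node up until the two meet (lowest common ancestor)
  na <- a; nb <- b
  while (na != nb) {
    if (depth[[na]] >= depth[[nb]]) na <- parent[[na]] else nb <- parent[[nb]]
  }
  unname(d[a] + d[b] - 2 * d[na])
}

#' Distance along the cable from a node to a tagged node
#'
#' Used for the distance of postsynaptic sites to the axon initial segment.
#' Requires exactly one node carrying `tag` on the skeleton.
#'
#' @param skel a [skeleton()].
#' @param node node id.
#' @param tag tag string (default `"axon initial segment"`).
#' @return geodesic distance in micrometres; 0 iff `node` is the tagged node.
#' @export
distance_to_tag <- function(skel, node, tag = "axon initial segment") {
  tn <- tagged_nodes(skel, tag)
  if (length(tn) != 1L) {
    stop(sprintf("skeleton %s: expected exactly one '%s' tag, found %d",
                 skel$neuron_id, tag, length(tn)))
  }
  geodesic_distance(skel, node, tn)
}

#' Distances of postsynaptic sites to the axon initial segment
#'
#' For every postsynaptic site on `target`, the geodesic (along-the-cable)
#' distance from the site to the target's axon-initial-segment node, grouped
#' by presynaptic partner. The per-source medians make proximity claims
#' ("source A synapses more proximally than source B") directly assertable.
#'
#' @param diagram a [wiring_diagram()].
#' @param target target neuron id.
#' @param tag tag naming the reference node.
#' @param group_by `"neuron"` (per presynaptic neuron) or `"cell_type"`.
#' @return object of class `distance_profile`: a `data.frame` of sites with a
#'   `medians` attribute (named vector of per-source median distances).
#' @export
distance_profile <- function(diagram, target, tag = "axon initial segment",
                             group_by = c("neuron", "cell_type")) {
  group_by <- match.arg(group_by)
  skel <- diagram$skeletons[[target]]
  if (is.null(skel)) stop(sprintf("no skeleton for neuron %s", target))
  tn <- tagged_nodes(skel, tag)
  if (length(tn) != 1L) {
    stop(sprintf("skeleton %s: expected exactly one '%s' tag, found %d",
                 target, tag, length(tn)))
  }
  syn <- diagram$synapses[diagram$synapses$post_neuron == target, , drop = FALSE]
  d0 <- dist_to_root(skel); depth <- node_depths(skel)
  parent <- skel$nodes$parent_id; names(parent) <- skel$nodes$node_id
  dist1 <- function(x) {  # geodesic to tn reusing precomputed depths
    na <- x; nb <- tn
    while (na != nb) {
      if (depth[[na]] >= depth[[nb]]) na <- parent[[na]] else nb <- parent[[nb]]
    }
    unname(d0[x] + d0[tn] - 2 * d0[na])
  }
  dist <- if (nrow(syn)) vapply(syn$post_node, dist1, numeric(1)) else numeric()
  source <- syn$pre_neuron
  if (group_by == "cell_type") {
    source <- diagram$neurons$cell_type[match(source, diagram$neurons$id)]
  }
  prof <- data.frame(target = rep(target, nrow(syn)), source = source,
                     post_node = syn$post_node, distance = as.numeric(dist),
                     stringsAsFactors = FALSE)
  med <- if (nrow(prof)) {
    vapply(split(prof$distance, prof$source), stats::median, numeric(1))
  } else stats::setNames(numeric(), character())
  structure(prof, medians = med, class = c("distance_profile", "data.frame"))
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d postsynaptic sites on %s\n",
              nrow(x), if (nrow(x)) x$target[1] else "?"))
  med <- attr(x, "medians")
  if (length(med)) {
    med <- sort(med)
    cat("  median distance to axon initial segment (um), by source:\n")
    for (s in names(med)) cat(sprintf("    %-24s %8.2f\n", s, med[[s]]))
  }
  invisible(x)
}

# Axo-dendritic polarity ------------------------------------------------------

#' Axo-dendritic polarity index
#'
#' For `d` synapses from a source onto a target's dendrite and `a` onto its
#' axon, the index is `(d - a) / (d + a)`, in `[-1, 1]`: negative values mean
#' the source synapses more onto the axon, positive more onto the dendrite.
#' Undefined (NA) when `d + a = 0`.
#'
#' @param d,a non-negative integer counts.
#' @return the index, or `NA` when both counts are zero.
#' @export
polarity_index <- function(d, a) {
  stopifnot(d >= 0, a >= 0)
  if (d + a == 0) return(NA_real_)
  (d - a) / (d + a)
}

#' Per-connection polarity indices in a diagram
#'
#' Counts postsynaptic sites per (source, target) split by the target's
#' compartment and computes the [polarity_index()]. A connection is reported
#' only if at least one compartment reaches `min_synapses` sites (the
#' consistency gate across sides is applied by the caller on the two sides'
#' tables).
#'
#' @param diagram a [wiring_diagram()].
#' @param sources,targets neuron id vectors.
#' @param compartments list from [compartment_maps()] (computed when `NULL`).
#' @param min_synapses minimum per-compartment site count for a connection to
#'   enter the table (default 2).
#' @return `data.frame` with columns `source`, `target`, `dendrite`, `axon`,
#'   `polarity`.
#' @export
polarity_table <- function(diagram, sources, targets, compartments = NULL,
                           min_synapses = 2) {
  if (is.null(compartments)) compartments <- compartment_maps(diagram)
  syn <- diagram$synapses
  syn <- syn[syn$pre_neuron %in% sources & syn$post_neuron %in% targets, ,
             drop = FALSE]
  if (!nrow(syn)) {
    return(data.frame(source = character(), target = character(),
                      dendrite = integer(), axon = integer(),
                      polarity = numeric(), stringsAsFactors = FALSE))
  }
  comp <- mapply(function(tg, nd) compartments[[tg]][[nd]],
                 syn$post_neuron, syn$post_node)
  key <- paste(syn$pre_neuron, syn$post_neuron, sep = "\r")
  dd <- tapply(comp == "dendrite", key, sum)
  aa <- tapply(comp == "axon", key, sum)
  parts <- strsplit(names(dd), "\r", fixed = TRUE)
  out <- data.frame(
    source = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    dendrite = as.integer(dd), axon = as.integer(aa),
    stringsAsFactors = FALSE
  )
  out <- out[pmax(out$dendrite, out$axon) >= min_synapses, , drop = FALSE]
  out$polarity <- mapply(polarity_index, out$dendrite, out$axon)
  rownames(out) <- NULL
  out
}
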