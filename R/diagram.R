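#' Recognised cell types
#'
#' The neuron classes of the larval antennal lobe: olfactory receptor neurons
#' (ORN), uni- and multiglomerular projection neurons (uPN, mPN), the local
#' interneuron classes (Broad Trio/Duet, Picky, Choosy, Keystone, Ventral),
#' neurons projecting to the subesophageal zone (SEZ), descending and
#' neuromodulatory neurons, and a catch-all `Other` (also used for unassigned
#' arbor fragments).
#'
#' @export
CELL_TYPES <- c(
  "ORN", "uPN", "mPN", "BroadLN_Trio", "BroadLN_Duet", "PickyLN",
  "ChoosyLN", "Keystone", "VentralLN", "SEZ", "Descending",
  "Neuromodulatory", "Other"
)

SIDES <- c("left", "right", "unpaired")

#' Build a neuron roster
#'
#' @param id character vector of unique neuron ids.
#' @param name display names (defaults to `id`).
#' @param cell_type one of [CELL_TYPES] per neuron.
#' @param side `"left"`, `"right"` or `"unpaired"`.
#' @param glomerulus glomerulus label; required for ORNs and uPNs, `NA`
#'   otherwise.
#' @param is_fragment logical; `TRUE` marks pseudo-neurons standing for small
#'   unassigned arbor fragments, so unassigned-site accounting is first-class.
#' @return a `data.frame` with one row per neuron.
#' @export
neuron_roster <- function(id, name = id, cell_type, side,
                          glomerulus = NA_character_, is_fragment = FALSE) {
  if (length(id) == 0) {
    return(data.frame(id = character(), name = character(),
                      cell_type = character(), side = character(),
                      glomerulus = character(), is_fragment = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    id = as.character(id), name = as.character(name),
    cell_type = as.character(cell_type), side = as.character(side),
    glomerulus = as.character(glomerulus), is_fragment = as.logical(is_fragment),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

#' Build a skeleton
#'
#' A skeleton is a rooted tree of 3-D nodes. Exactly one node must have
#' `parent_id = NA` (the root). Coordinates are in micrometres; the SWC radius
#' field, if present on disk, is ignored.
#'
#' @param neuron_id id of the neuron the skeleton belongs to.
#' @param nodes `data.frame` with columns `node_id`, `parent_id` (`NA` for the
#'   root), `x`, `y`, `z`.
#' @param tags optional `data.frame` with columns `node_id`, `tag`
#'   (e.g. `"axon start"`, `"axon initial segment"`, `"soma"`).
#' @return an object of class `skeleton`.
#' @export
skeleton <- function(neuron_id, nodes, tags = NULL) {
  if (is.null(tags)) {
    tags <- data.frame(node_id = character(), tag = character(),
                       stringsAsFactors = FALSE)
  }
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  tags$node_id <- as.character(tags$node_id)
  structure(
    list(neuron_id = as.character(neuron_id), nodes = nodes, tags = tags),
    class = "skeleton"
  )
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> neuron %s: %d nodes, %d tags\n",
              x$neuron_id, nrow(x$nodes), nrow(x$tags)))
  invisible(x)
}

#' Build a synapse table
#'
#' One row per postsynaptic site: a polyadic connector with n postsynaptic
#' partners contributes n rows sharing a `connector_id`. Synapse counts
#' throughout the package are counts of postsynaptic sites, matching this
#' representation.
#'
#' @param connector_id,pre_neuron,pre_node,post_neuron,post_node vectors of
#'   equal length.
#' @return a `data.frame` with one row per postsynaptic site.
#' @export
synapse_table <- function(connector_id = character(), pre_neuron = character(),
                          pre_node = character(), post_neuron = character(),
                          post_node = character()) {
  data.frame(
    connector_id = as.character(connector_id),
    pre_neuron = as.character(pre_neuron), pre_node = as.character(pre_node),
    post_neuron = as.character(post_neuron), post_node = as.character(post_node),
    stringsAsFactors = FALSE
  )
}

#' Build a left/right homolog pairing
#'
#' @param pairs `data.frame` with columns `left`, `right` (neuron ids), and
#'   optionally `pair_id` naming the bilateral pair; a default `pair_id` is
#'   derived from the left id when absent.
#' @param unpaired character vector of neuron ids without a homolog (e.g. the
#'   ventral unpaired medial neurons).
#' @return an object of class `homolog_pairing`.
#' @export
homolog_pairing <- function(pairs = NULL, unpaired = character()) {
  if (is.null(pairs)) {
    pairs <- data.frame(pair_id = character(), left = character(),
                        right = character(), stringsAsFactors = FALSE)
  }
  pairs$left <- as.character(pairs$left)
  pairs$right <- as.character(pairs$right)
  if (is.null(pairs$pair_id)) pairs$pair_id <- sub("[._]?[Ll](eft)?$", "", pairs$left)
  pairs <- pairs[, c("pair_id", "left", "right")]
  structure(list(pairs = pairs, unpaired = as.character(unpaired)),
            class = "homolog_pairing")
}

#' @export
print.homolog_pairing <- function(x, ...) {
  cat(sprintf("<homolog_pairing> %d pairs, %d unpaired\n",
              nrow(x$pairs), length(x$unpaired)))
  invisible(x)
}

#' Assemble a wiring diagram
#'
#' Bundles the roster, skeletons, synapse table and homolog pairing for one
#' animal (both sides). Use [validate_diagram()] to check referential
#' integrity and the structural invariants.
#'
#' @param neurons roster from [neuron_roster()].
#' @param skeletons named list of [skeleton()] objects (names = neuron ids).
#' @param synapses table from [synapse_table()].
#' @param pairing a [homolog_pairing()] or `NULL`.
#' @return an object of class `wiring_diagram`.
#' @export
wiring_diagram <- function(neurons, skeletons = list(),
                           synapses = synapse_table(), pairing = NULL) {
  if (length(skeletons) && is.null(names(skeletons))) {
    names(skeletons) <- vapply(skeletons, function(s) s$neuron_id, character(1))
  }
  structure(
    list(neurons = neurons, skeletons = skeletons, synapses = synapses,
         pairing = pairing),
    class = "wiring_diagram"
  )
}

#' @export
print.wiring_diagram <- function(x, ...) {
  cat(sprintf("<wiring_diagram> %d neurons, %d skeletons, %d postsynaptic sites\n",
              nrow(x$neurons), length(x$skeletons), nrow(x$synapses)))
  if (!is.null(x$pairing)) {
    cat(sprintf("  pairing: %d pairs, %d unpaired\n",
                nrow(x$pairing$pairs), length(x$pairing$unpaired)))
  }
  invisible(x)
}

#' @export
summary.wiring_diagram <- function(object, ...) {
  print(object)
  cat("  neurons by type:\n")
  print(table(object$neurons$cell_type, object$neurons$side))
  invisible(object)
}

# ---- validation -------------------------------------------------------------

violation <- function(rule, record, message) {
  data.frame(rule = rule, record = record, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a wiring diagram
#'
#' Checks every structural invariant and reports violations rather than
#' throwing: duplicate ids, missing glomerulus labels on ORNs/uPNs, invalid
#' sides, skeleton tree structure (single root, no cycles, finite
#' coordinates), tags on missing nodes, synapse referential integrity, and
#' pairing consistency (each neuron at most once, matched cell types,
#' opposite sides).
#'
#' @param diagram a [wiring_diagram()].
#' @return a `data.frame` of class `validation_report` with columns `rule`,
#'   `record`, `message`; zero rows iff the diagram is well-formed.
#' @export
validate_diagram <- function(diagram) {
  v <- list()
  nr <- diagram$neurons

  dup <- nr$id[duplicated(nr$id)]
  for (d in unique(dup)) v[[length(v) + 1L]] <-
    violation("unique_id", d, "duplicate neuron id")

  bad_side <- nr$id[!nr$side %in% SIDES]
  for (d in bad_side) v[[length(v) + 1L]] <-
    violation("side", d, "side must be left, right or unpaired")

  bad_type <- nr$id[!nr$cell_type %in% CELL_TYPES]
  for (d in bad_type) v[[length(v) + 1L]] <-
    violation("cell_type", d, "unknown cell type")

  need_glom <- nr$cell_type %in% c("ORN", "uPN") & !isTRUE_vec(nr$is_fragment)
  miss_glom <- nr$id[need_glom & (is.na(nr$glomerulus) | nr$glomerulus == "")]
  for (d in miss_glom) v[[length(v) + 1L]] <-
    violation("glomerulus", d, "ORN/uPN must carry a glomerulus label")

  # skeletons: one root, acyclic parents, finite coordinates
  for (sk in diagram$skeletons) {
    nodes <- sk$nodes
    roots <- sum(is.na(nodes$parent_id))
    if (roots != 1L) v[[length(v) + 1L]] <-
      violation("skeleton_root", sk$neuron_id,
                sprintf("skeleton has %d roots (expected 1)", roots))
    known <- nodes$parent_id %in% nodes$node_id | is.na(nodes$parent_id)
    for (n in nodes$node_id[!known]) v[[length(v) + 1L]] <-
      violation("skeleton_parent", sk$neuron_id,
                sprintf("node %s references missing parent", n))
    if (any(duplicated(nodes$node_id))) v[[length(v) + 1L]] <-
      violation("skeleton_node_id", sk$neuron_id, "duplicate node ids")
    if (roots == 1L && all(known) && !any(duplicated(nodes$node_id)) &&
        has_cycle(nodes)) {
      v[[length(v) + 1L]] <-
        violation("skeleton_cycle", sk$neuron_id, "parent links form a cycle")
    }
    if (!all(is.finite(c(nodes$x, nodes$y, nodes$z)))) v[[length(v) + 1L]] <-
      violation("skeleton_coords", sk$neuron_id, "non-finite coordinates")
    bad_tag <- setdiff(sk$tags$node_id, nodes$node_id)
    for (n in bad_tag) v[[length(v) + 1L]] <-
      violation("tag_node", sk$neuron_id,
                sprintf("tag on non-existent node %s", n))
  }

  # synapses: referenced neurons and nodes exist
  syn <- diagram$synapses
  if (nrow(syn)) {
    for (col in c("pre_neuron", "post_neuron")) {
      missing <- !syn[[col]] %in% nr$id
      for (i in which(missing)) v[[length(v) + 1L]] <-
        violation("synapse_neuron", syn$connector_id[i],
                  sprintf("%s %s not in roster", col, syn[[col]][i]))
    }
    if (length(diagram$skeletons)) {
      chk <- function(neuron, node, i, what) {
        sk <- diagram$skeletons[[neuron]]
        if (!is.null(sk) && !node %in% sk$nodes$node_id) {
          violation("synapse_node", syn$connector_id[i],
                    sprintf("%s node %s absent from skeleton of %s",
                            what, node, neuron))
        } else NULL
      }
      for (i in seq_len(nrow(syn))) {
        v[[length(v) + 1L]] <- chk(syn$pre_neuron[i], syn$pre_node[i], i, "pre")
        v[[length(v) + 1L]] <- chk(syn$post_neuron[i], syn$post_node[i], i, "post")
      }
    }
  }

  # pairing
  pg <- diagram$pairing
  if (!is.null(pg)) {
    all_ids <- c(pg$pairs$left, pg$pairs$right, pg$unpaired)
    for (d in unique(all_ids[duplicated(all_ids)])) v[[length(v) + 1L]] <-
      violation("pairing_unique", d, "neuron appears more than once in pairing")
    for (d in setdiff(all_ids, nr$id)) v[[length(v) + 1L]] <-
      violation("pairing_roster", d, "paired neuron absent from roster")
    idx <- match(pg$pairs$left, nr$id); jdx <- match(pg$pairs$right, nr$id)
    ok <- !is.na(idx) & !is.na(jdx)
    mism <- which(ok & nr$cell_type[idx] != nr$cell_type[jdx])
    for (i in mism) v[[length(v) + 1L]] <-
      violation("pairing_type", pg$pairs$pair_id[i],
                "homologs have different cell types")
    badside <- which(ok & !(nr$side[idx] == "left" & nr$side[jdx] == "right"))
    for (i in badside) v[[length(v) + 1L]] <-
      violation("pairing_side", pg$pairs$pair_id[i],
                "homologs must be on opposite sides (left, right)")
  }

  v <- v[!vapply(v, is.null, logical(1))]
  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), record = character(), message = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# cycle check on parent pointers; assumes parents exist and ids unique
has_cycle <- function(nodes) {
  parent <- nodes$parent_id
  names(parent) <- nodes$node_id
  state <- integer(nrow(nodes)); names(state) <- nodes$node_id  # 0 new 1 done
  for (start in nodes$node_id) {
    n <- start; seen <- character()
    while (!is.na(parent[[n]]) && state[[n]] == 0L) {
      if (n %in% seen) return(TRUE)
      seen <- c(seen, n)
      n <- parent[[n]]
    }
    state[seen] <- 1L
  }
  FALSE
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<validation_report> no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

# ---- census -----------------------------------------------------------------

#' Roster census
#'
#' Counts neurons by cell type and side, counts homolog pairs and unpaired
#' neurons, and flags roster neurons absent from the pairing. For a fully
#' paired diagram, `total = 2 * n_pairs + n_unpaired`.
#'
#' @param diagram a [wiring_diagram()].
#' @param include_fragments count fragment pseudo-neurons (default `FALSE`).
#' @return an object of class `roster_census`.
#' @export
roster_census <- function(diagram, include_fragments = FALSE) {
  nr <- diagram$neurons
  if (!include_fragments) nr <- nr[!isTRUE_vec(nr$is_fragment), , drop = FALSE]
  by_type <- table(factor(nr$cell_type, levels = CELL_TYPES))
  by_side <- table(factor(nr$side, levels = SIDES))
  pg <- diagram$pairing
  n_pairs <- if (is.null(pg)) NA_integer_ else nrow(pg$pairs)
  n_unpaired <- if (is.null(pg)) NA_integer_ else length(pg$unpaired)
  not_in_pairing <- if (is.null(pg)) character() else
    setdiff(nr$id, c(pg$pairs$left, pg$pairs$right, pg$unpaired))
  structure(
    list(total = nrow(nr), by_type = by_type, by_side = by_side,
         n_pairs = n_pairs, n_unpaired = n_unpaired,
         not_in_pairing = not_in_pairing),
    class = "roster_census"
  )
}

#' @export
print.roster_census <- function(x, ...) {
  cat(sprintf("<roster_census> %d neurons", x$total))
  if (!is.na(x$n_pairs)) {
    cat(sprintf(" (%d homolog pairs, %d unpaired)", x$n_pairs, x$n_unpaired))
  }
  cat("\n")
  tt <- x$by_type[x$by_type > 0]
  if (length(tt)) {
    cat(paste(sprintf("  %s: %d", names(tt), as.integer(tt)), collapse = "\n"), "\n")
  }
  if (length(x$not_in_pairing)) {
    cat("  not in pairing:", paste(x$not_in_pairing, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- unassigned fragments ---------------------------------------------------

#' Display rounding of a percentage
#'
#' Percentages are computed on raw counts and rounded to one decimal for
#' display; the raw value is kept alongside.
#'
#' @param numerator,denominator raw counts (or lengths).
#' @param digits decimals for display (default 1).
#' @return list with `raw` (unrounded percent, `NaN` if denominator is 0) and
#'   `display` (rounded).
#' @export
percent_display <- function(numerator, denominator, digits = 1) {
  raw <- if (denominator == 0) NaN else 100 * numerator / denominator
  list(raw = raw, display = round(raw, digits))
}

#' Unassigned-fragment accounting
#'
#' Measures how much of a diagram remains as small unassigned arbor
#' fragments: the fraction of postsynaptic sites downstream of the target
#' cell types that land on fragment pseudo-neurons, and the fraction of total
#' reconstructed cable belonging to fragment skeletons.
#'
#' @param diagram a [wiring_diagram()] whose fragment pseudo-neurons carry
#'   `is_fragment = TRUE` in the roster.
#' @param target_types cell types whose downstream (postsynaptic) sites are
#'   audited; default `"ORN"`.
#' @return list with raw counts and [percent_display()] percentages for sites
#'   and cable.
#' @export
unassigned_fraction <- function(diagram, target_types = "ORN") {
  nr <- diagram$neurons
  frag_ids <- nr$id[isTRUE_vec(nr$is_fragment)]
  src_ids <- nr$id[nr$cell_type %in% target_types & !isTRUE_vec(nr$is_fragment)]
  syn <- diagram$synapses[diagram$synapses$pre_neuron %in% src_ids, , drop = FALSE]
  site_total <- nrow(syn)
  site_count <- sum(syn$post_neuron %in% frag_ids)

  cab <- vapply(diagram$skeletons, cable_length, numeric(1))
  cable_total <- sum(cab)
  cable_frag <- sum(cab[names(cab) %in% frag_ids])

  list(
    site_count = site_count, site_total = site_total,
    site_pct = percent_display(site_count, site_total),
    cable_fragment = cable_frag, cable_total = cable_total,
    cable_pct = percent_display(cable_frag, cable_total)
  )
}
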