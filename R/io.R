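# SWC skeletons ----------------------------------------------------------------

#' Read a skeleton from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; root parent -1).
#' The radius column is ignored; coordinates are taken as micrometres. Tags
#' are not part of SWC and are supplied separately (see [read_tags()]).
#'
#' @param path SWC file.
#' @param neuron_id neuron the skeleton belongs to (default: file stem).
#' @param tags optional tag `data.frame` (`node_id`, `tag`).
#' @return a [skeleton()].
#' @export
read_swc <- function(path, neuron_id = sub("\\.swc$", "", basename(path)),
                     tags = NULL) {
  df <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  skeleton(neuron_id,
           nodes = data.frame(
             node_id = as.character(df$id),
             parent_id = ifelse(df$parent == -1, NA_character_,
                                as.character(df$parent)),
             x = df$x, y = df$y, z = df$z, stringsAsFactors = FALSE),
           tags = tags)
}

#' Write a skeleton to an SWC file
#'
#' Nodes are written in a parent-before-child order; the root's parent is -1
#' and the (ignored) radius is written as 1. Integer node ids are preserved
#' so synapse and tag tables keep referring to the same nodes after a round
#' trip; non-integer ids are renumbered 1-based and the mapping returned.
#'
#' @param skel a [skeleton()].
#' @param path output file.
#' @return invisibly, the mapping from original node ids to SWC ids.
#' @export
write_swc <- function(skel, path) {
  nodes <- skel$nodes
  # order parents before children
  ord <- character(0); kids <- children_index(nodes)
  queue <- nodes$node_id[is.na(nodes$parent_id)]
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, n); queue <- c(queue, kids[[n]])
  }
  keep_ids <- !anyNA(suppressWarnings(as.integer(nodes$node_id)))
  idmap <- if (keep_ids) {
    stats::setNames(as.integer(ord), ord)
  } else {
    stats::setNames(seq_along(ord), ord)
  }
  nodes <- nodes[match(ord, nodes$node_id), , drop = FALSE]
  out <- data.frame(
    id = idmap[nodes$node_id], type = 0L,
    x = nodes$x, y = nodes$y, z = nodes$z, radius = 1,
    parent = ifelse(is.na(nodes$parent_id), -1L, idmap[nodes$parent_id])
  )
  utils::write.table(out, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(idmap)
}

# CSV tables --------------------------------------------------------------------

#' Read node tags
#'
#' CSV with columns `skeleton_id`, `node_id`, `tag`.
#' @param path CSV file.
#' @return `data.frame`.
#' @export
read_tags <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(skeleton_id = "character",
                                 node_id = "character", tag = "character"))
}

#' Read a synapse table
#'
#' CSV with one row per postsynaptic site: `connector_id`, `pre_neuron`,
#' `pre_node`, `post_neuron`, `post_node`.
#' @param path CSV file.
#' @return a [synapse_table()].
#' @export
read_synapses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  synapse_table(df$connector_id, df$pre_neuron, df$pre_node,
                df$post_neuron, df$post_node)
}

#' Read a neuron roster
#'
#' CSV with columns `id`, `name`, `cell_type`, `side`, `glomerulus`,
#' `is_fragment`.
#' @param path CSV file.
#' @return a [neuron_roster()] `data.frame`.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  neuron_roster(df$id, if (is.null(df$name)) df$id else df$name,
                df$cell_type, df$side,
                if (is.null(df$glomerulus)) NA else df$glomerulus,
                if (is.null(df$is_fragment)) FALSE else df$is_fragment)
}

#' Read a homolog pairing
#'
#' CSV with columns `pair_id`, `left`, `right`; rows with an empty `right`
#' list unpaired neurons in `left`.
#' @param path CSV file.
#' @return a [homolog_pairing()].
#' @export
read_pairing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  unp <- df$left[is.na(df$right) | df$right == ""]
  homolog_pairing(df[!(is.na(df$right) | df$right == ""), , drop = FALSE],
                  unpaired = unp)
}

#' Write a wiring diagram to a directory
#'
#' Writes `roster.csv`, `pairing.csv`, `synapses.csv`, `tags.csv` and one
#' SWC file per skeleton under `skeletons/`. [read_diagram()] reads the same
#' layout back.
#'
#' @param diagram a [wiring_diagram()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_diagram <- function(diagram, dir) {
  dir.create(file.path(dir, "skeletons"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(diagram$neurons, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  pg <- diagram$pairing
  pr <- if (is.null(pg)) {
    data.frame(pair_id = character(), left = character(), right = character())
  } else {
    rbind(pg$pairs,
          data.frame(pair_id = pg$unpaired, left = pg$unpaired,
                     right = rep("", length(pg$unpaired))))
  }
  utils::write.csv(pr, file.path(dir, "pairing.csv"), row.names = FALSE)
  utils::write.csv(diagram$synapses, file.path(dir, "synapses.csv"),
                   row.names = FALSE)
  tags <- do.call(rbind, lapply(diagram$skeletons, function(s)
    if (nrow(s$tags)) cbind(skeleton_id = s$neuron_id, s$tags) else NULL))
  if (is.null(tags)) {
    tags <- data.frame(skeleton_id = character(), node_id = character(),
                       tag = character())
  }
  utils::write.csv(tags, file.path(dir, "tags.csv"), row.names = FALSE)
  for (s in diagram$skeletons) {
    # SWC renumbers nodes; keep original node ids stable by writing our own
    # ids into the SWC id column only when they are already integers
    write_swc(s, file.path(dir, "skeletons", paste0(s$neuron_id, ".swc")))
  }
  invisible(dir)
}

#' Read a wiring diagram from a directory written by [write_diagram()]
#'
#' @param dir directory.
#' @return a [wiring_diagram()].
#' @export
read_diagram <- function(dir) {
  roster <- read_roster(file.path(dir, "roster.csv"))
  pairing <- read_pairing(file.path(dir, "pairing.csv"))
  synapses <- read_synapses(file.path(dir, "synapses.csv"))
  tags <- read_tags(file.path(dir, "tags.csv"))
  files <- list.files(file.path(dir, "skeletons"), pattern = "\\.swc$",
                      full.names = TRUE)
  skels <- lapply(files, function(f) {
    id <- sub("\\.swc$", "", basename(f))
    tg <- tags[tags$skeleton_id == id, c("node_id", "tag"), drop = FALSE]
    read_swc(f, neuron_id = id, tags = tg)
  })
  names(skels) <- vapply(skels, function(s) s$neuron_id, character(1))
  wiring_diagram(roster, skels, synapses, pairing)
}

#' Read an odorant x ORN response matrix
#'
#' CSV with odorants in rows (first column = odorant id) and ORNs in columns.
#' A per-source scaling hook is exposed for merging screens recorded on
#' different scales; no transformation is applied by default.
#'
#' @param path CSV file.
#' @param scale_fun optional function applied to the numeric matrix.
#' @return numeric matrix.
#' @export
read_response_matrix <- function(path, scale_fun = identity) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  scale_fun(m)
}

#' Write a matrix as CSV with an id column
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_col name of the first (row id) column.
#' @export
write_matrix_csv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE)
}
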