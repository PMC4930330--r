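# Synapse-count matrices ------------------------------------------------------

#' Synapse-count matrix
#'
#' Cell (r, c) is the number of postsynaptic sites on column neuron c (within
#' an optional compartment restriction of c's arbor) whose presynaptic neuron
#' is r. `rows` may be a named list of groups, in which case member rows are
#' summed under the group name.
#'
#' @param diagram a [wiring_diagram()].
#' @param rows presynaptic neuron ids, or a named list of id groups.
#' @param cols postsynaptic neuron ids.
#' @param compartment optional `"dendrite"`, `"axon"` or `"soma"`: restrict
#'   to sites on that compartment of the column neuron.
#' @param compartments list from [compartment_maps()]; computed when `NULL`
#'   and a restriction is requested.
#' @param pre_compartment optional restriction on the presynaptic node's
#'   compartment (e.g. `"dendrite"` for dendro-dendritic synapses).
#' @return integer matrix with class `synapse_count_matrix`.
#' @export
count_matrix <- function(diagram, rows, cols, compartment = NULL,
                         compartments = NULL, pre_compartment = NULL) {
  groups <- if (is.list(rows)) rows else as.list(stats::setNames(rows, rows))
  ids <- unique(unlist(groups))
  unknown <- setdiff(c(ids, cols), diagram$neurons$id)
  if (length(unknown)) {
    stop("unknown neuron id(s): ", paste(unknown, collapse = ", "))
  }
  syn <- restricted_synapses(diagram, compartment, compartments, pre_compartment)
  syn <- syn[syn$pre_neuron %in% ids & syn$post_neuron %in% cols, , drop = FALSE]
  m <- matrix(0L, nrow = length(groups), ncol = length(cols),
              dimnames = list(names(groups), cols))
  if (nrow(syn)) {
    member_of <- rep(names(groups), lengths(groups))
    names(member_of) <- unlist(groups)
    tab <- table(factor(member_of[syn$pre_neuron], levels = names(groups)),
                 factor(syn$post_neuron, levels = cols))
    m <- m + unclass(tab)
  }
  storage.mode(m) <- "integer"
  structure(m, compartment = compartment,
            class = c("synapse_count_matrix", class(m)))
}

restricted_synapses <- function(diagram, compartment, compartments,
                                pre_compartment = NULL) {
  syn <- diagram$synapses
  if (is.null(compartment) && is.null(pre_compartment)) return(syn)
  if (is.null(compartments)) compartments <- compartment_maps(diagram)
  look <- function(neuron, node) {
    mapply(function(ne, no) {
      cm <- compartments[[ne]]
      if (is.null(cm)) NA_character_ else cm[[no]]
    }, neuron, node, USE.NAMES = FALSE)
  }
  if (!is.null(compartment)) {
    syn <- syn[!is.na(look(syn$post_neuron, syn$post_node)) &
                 look(syn$post_neuron, syn$post_node) == compartment, ,
               drop = FALSE]
  }
  if (!is.null(pre_compartment) && nrow(syn)) {
    pc <- look(syn$pre_neuron, syn$pre_node)
    syn <- syn[!is.na(pc) & pc == pre_compartment, , drop = FALSE]
  }
  syn
}

#' Total postsynaptic sites per neuron
#'
#' The per-column denominators for input fractions: the number of
#' postsynaptic sites on each neuron, optionally restricted to a compartment
#' (e.g. dendrite-only denominators).
#'
#' @inheritParams count_matrix
#' @param neurons neuron ids.
#' @return named integer vector.
#' @export
postsynaptic_totals <- function(diagram, neurons, compartment = NULL,
                                compartments = NULL) {
  syn <- restricted_synapses(diagram, compartment, compartments)
  tab <- table(factor(syn$post_neuron, levels = neurons))
  stats::setNames(as.integer(tab), neurons)
}

# Input fractions --------------------------------------------------------------

#' Input fractions from a count matrix
#'
#' Converts counts into the percent of a column neuron's postsynaptic sites
#' contributed by each row. The denominator is explicit (whole-neuron vs
#' dendrite-only totals differ); raw counts are retained alongside, and the
#' display rounding is applied later by [render_table()], never here.
#'
#' @param counts a [count_matrix()].
#' @param denominators named per-column totals, e.g. from
#'   [postsynaptic_totals()]. Columns with a zero denominator are dropped with
#'   a warning.
#' @param denominator_spec free-text label recording which denominator was
#'   used (e.g. `"whole-neuron"`, `"dendrite-only"`).
#' @return object of class `fraction_matrix`: percent matrix with attributes
#'   `counts`, `denominators`, `denominator_spec`.
#' @export
input_fractions <- function(counts, denominators,
                            denominator_spec = "whole-neuron") {
  cols <- colnames(counts)
  den <- denominators[cols]
  if (anyNA(den)) stop("missing denominator for column(s): ",
                       paste(cols[is.na(den)], collapse = ", "))
  zero <- den == 0
  if (any(zero)) {
    warning("dropping column(s) with zero denominator: ",
            paste(cols[zero], collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
    den <- den[!zero]
  }
  fr <- sweep(unclass(counts) * 100, 2, den, "/")
  structure(fr, counts = unclass(counts), denominators = den,
            denominator_spec = denominator_spec,
            class = c("fraction_matrix", "matrix", "array"))
}

#' @export
print.fraction_matrix <- function(x, digits = 1, ...) {
  cat(sprintf("<fraction_matrix> %d x %d, %% of postsynaptic sites (%s denominator)\n",
              nrow(x), ncol(x), attr(x, "denominator_spec")))
  print(round(unclass(x), digits))
  invisible(x)
}

# Display rounding -------------------------------------------------------------

#' Render a fraction matrix under a display rounding convention
#'
#' Two conventions are supported for small percentages: `floor_below_half`
#' maps values in (0, 0.5) to 0, `ceil_to_one` maps values in (0, 1) to 1.
#' Values of 0.5 and above (resp. 1 and above) round to the nearest integer.
#' Column totals are always computed from the raw values, never from the
#' rendered entries.
#'
#' @param fractions a [input_fractions()] matrix (or plain percent matrix).
#' @param style `"floor_below_half"` or `"ceil_to_one"`.
#' @param totals append a `total` row computed from raw values (default
#'   `TRUE`).
#' @return integer display matrix (plus the raw-total row if requested).
#' @export
render_table <- function(fractions, style = c("floor_below_half", "ceil_to_one"),
                         totals = TRUE) {
  style <- match.arg(style)
  raw <- unclass(fractions)
  disp <- round(raw)
  small <- raw > 0 & raw < 1
  if (style == "floor_below_half") {
    disp[small] <- ifelse(raw[small] < 0.5, 0, 1)
  } else {
    disp[small] <- 1
  }
  storage.mode(disp) <- "integer"
  if (totals) disp <- rbind(disp, total = as.integer(round(colSums(raw))))
  disp
}

# Bilateral-consistency filter --------------------------------------------------

#' Count matrices per side, indexed by homolog pair
#'
#' Builds the left and right synapse-count matrices for the same sets of
#' bilateral pairs, with rows/columns named by `pair_id` so the two sides are
#' directly comparable.
#'
#' @param diagram a [wiring_diagram()] with a pairing.
#' @param row_pairs,col_pairs `pair_id`s (default: all pairs).
#' @inheritParams count_matrix
#' @return list with elements `left` and `right`.
#' @export
bilateral_count_matrices <- function(diagram, row_pairs = NULL, col_pairs = NULL,
                                     compartment = NULL, compartments = NULL) {
  pg <- diagram$pairing
  if (is.null(pg)) stop("diagram has no homolog pairing")
  pairs <- pg$pairs
  if (is.null(row_pairs)) row_pairs <- pairs$pair_id
  if (is.null(col_pairs)) col_pairs <- pairs$pair_id
  side_mat <- function(side_col) {
    ids <- pairs[[side_col]][match(c(row_pairs, col_pairs), pairs$pair_id)]
    rows <- stats::setNames(ids[seq_along(row_pairs)], row_pairs)
    cols <- ids[length(row_pairs) + seq_along(col_pairs)]
    m <- count_matrix(diagram, as.list(as.list(rows)), cols,
                      compartment = compartment, compartments = compartments)
    colnames(m) <- col_pairs
    m
  }
  list(left = side_mat("left"), right = side_mat("right"))
}

#' Bilateral-consistency filter
#'
#' Keeps a connection only when it reaches the minimum synapse count between
#' the homologous neurons on *both* the left and the right side — the
#' stereotypy criterion used for identified-neuron connectivity tables. The
#' threshold is a per-side minimum, not a summed one. The result is symmetric
#' under swapping the two input matrices.
#'
#' @param left_counts,right_counts matrices with identical dimnames, indexed
#'   by homolog pair (see [bilateral_count_matrices()]).
#' @param min_synapses per-side minimum count (default 2; display variants of
#'   some tables use 4).
#' @return `data.frame` of class `bilateral_edges` with columns `source`,
#'   `target`, `left_count`, `right_count`, `kept`.
#' @export
bilateral_filter <- function(left_counts, right_counts, min_synapses = 2) {
  stopifnot(min_synapses >= 1)
  if (!identical(dimnames(left_counts), dimnames(right_counts))) {
    stop("left and right matrices must share dimnames (pair ids)")
  }
  lc <- unclass(left_counts); rc <- unclass(right_counts)
  idx <- which(lc > 0 | rc > 0, arr.ind = TRUE)
  out <- data.frame(
    source = rownames(lc)[idx[, 1]],
    target = colnames(lc)[idx[, 2]],
    left_count = as.integer(lc[idx]),
    right_count = as.integer(rc[idx]),
    stringsAsFactors = FALSE
  )
  out$kept <- out$left_count >= min_synapses & out$right_count >= min_synapses
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bilateral_edges", "data.frame")
  out
}

#' Kept edge set from a bilateral filter result
#'
#' @param edges result of [bilateral_filter()].
#' @return `data.frame` of kept edges only.
#' @export
kept_edges <- function(edges) {
  out <- edges[edges$kept, c("source", "target", "left_count", "right_count"),
               drop = FALSE]
  rownames(out) <- NULL
  out
}

# Bilateral input merging -------------------------------------------------------

#' Merge left and right inputs onto a bilateral neuron
#'
#' For neurons with a bilateral arbor (e.g. bilateral mPNs, VUM neurons) the
#' inputs received from the left and right homologs of each source are summed
#' under the source's pair identity.
#'
#' @param diagram a [wiring_diagram()] with a pairing.
#' @param target neuron id of the bilateral target.
#' @inheritParams count_matrix
#' @return named integer vector of input counts, indexed by source `pair_id`
#'   (unpaired sources keep their own id).
#' @export
merge_bilateral_inputs <- function(diagram, target, compartment = NULL,
                                   compartments = NULL) {
  pg <- diagram$pairing
  if (is.null(pg)) stop("diagram has no homolog pairing")
  syn <- restricted_synapses(diagram, compartment, compartments)
  syn <- syn[syn$post_neuron == target, , drop = FALSE]
  to_pair <- c(stats::setNames(pg$pairs$pair_id, pg$pairs$left),
               stats::setNames(pg$pairs$pair_id, pg$pairs$right))
  src <- syn$pre_neuron
  mapped <- ifelse(src %in% names(to_pair), to_pair[src], src)
  tab <- table(mapped)
  stats::setNames(as.integer(tab), names(tab))
}

# Glomerular grouping -----------------------------------------------------------

#' Glomerular input grouping
#'
#' Defines each glomerulus as a source group consisting of its ORN together
#' with the dendro-dendritic output of that ORN's uPN (uPN synapses whose
#' presynaptic node lies on the uPN dendrite). Axonal uPN outputs are
#' excluded. Glomeruli lacking a uPN contribute the ORN alone and are
#' flagged.
#'
#' @param diagram a [wiring_diagram()].
#' @param cols target neuron ids.
#' @param compartments list from [compartment_maps()]; computed when `NULL`.
#' @param side restrict ORNs/uPNs to one side (`"left"`/`"right"`), or `NULL`
#'   for all.
#' @return integer matrix (glomeruli x targets) with attribute
#'   `missing_upn` naming glomeruli that lack a uPN.
#' @export
glomerular_grouping <- function(diagram, cols, compartments = NULL,
                                side = NULL) {
  nr <- diagram$neurons
  if (!is.null(side)) nr <- nr[nr$side == side | nr$side == "unpaired", , drop = FALSE]
  orns <- nr[nr$cell_type == "ORN" & !isTRUE_vec(nr$is_fragment), , drop = FALSE]
  upns <- nr[nr$cell_type == "uPN", , drop = FALSE]
  gloms <- sort(unique(orns$glomerulus))
  if (is.null(compartments)) compartments <- compartment_maps(diagram)

  orn_counts <- count_matrix(
    diagram,
    rows = stats::setNames(lapply(gloms, function(g) orns$id[orns$glomerulus == g]),
                           gloms),
    cols = cols
  )
  upn_groups <- stats::setNames(
    lapply(gloms, function(g) upns$id[upns$glomerulus == g]), gloms)
  upn_counts <- count_matrix(
    diagram, rows = upn_groups, cols = cols,
    compartments = compartments, pre_compartment = "dendrite"
  )
  m <- unclass(orn_counts) + unclass(upn_counts)
  storage.mode(m) <- "integer"
  missing_upn <- gloms[lengths(upn_groups) == 0]
  if (length(missing_upn)) {
    warning("glomerul", if (length(missing_upn) > 1) "i" else "us", " without uPN: ",
            paste(missing_upn, collapse = ", "))
  }
  structure(m, missing_upn = missing_upn)
}
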