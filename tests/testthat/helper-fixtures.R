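# Shared fixtures, all built in code.

# chain skeleton along x with given edge lengths; node ids "1".."n+1"
chain_skeleton <- function(id, lengths, tags = NULL) {
  n <- length(lengths) + 1L
  skeleton(id,
           nodes = data.frame(
             node_id = as.character(seq_len(n)),
             parent_id = c(NA, as.character(seq_len(n - 1L))),
             x = cumsum(c(0, lengths)), y = 0, z = 0,
             stringsAsFactors = FALSE),
           tags = tags)
}

# random rooted tree skeleton with random coordinates (oracle fodder)
random_tree_skeleton <- function(id, n, tags = NULL) {
  parent <- c(NA_integer_, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                                  integer(1)))
  skeleton(id,
           nodes = data.frame(
             node_id = as.character(seq_len(n)),
             parent_id = as.character(parent),
             x = stats::runif(n, 0, 50), y = stats::runif(n, 0, 50),
             z = stats::runif(n, 0, 50), stringsAsFactors = FALSE),
           tags = tags)
}

# minimal two-neuron diagram: ORN A -> uPN B, `n` postsynaptic sites
toy_two_neuron <- function(n_sites = 2) {
  roster <- neuron_roster(
    id = c("A", "B"), cell_type = c("ORN", "uPN"), side = "left",
    glomerulus = "g1")
  sa <- chain_skeleton("A", c(1, 1))
  sb <- chain_skeleton("B", c(1, 1))
  syn <- synapse_table(
    connector_id = rep("c1", n_sites), pre_neuron = "A", pre_node = "2",
    post_neuron = "B", post_node = rep("2", n_sites))
  wiring_diagram(roster, list(A = sa, B = sb), syn)
}

# mirrored diagram fixture for filter / motif tests, built explicitly:
# pair-level edge list -> per-side synapse rows (1 site per synapse count)
mirrored_diagram <- function(pairs, edges_left, edges_right) {
  # pairs: data.frame(pair_id, cell_type, glomerulus)
  roster <- neuron_roster(
    id = c(paste0(pairs$pair_id, ".L"), paste0(pairs$pair_id, ".R")),
    cell_type = rep(pairs$cell_type, 2),
    side = rep(c("left", "right"), each = nrow(pairs)),
    glomerulus = rep(pairs$glomerulus, 2))
  pairing <- homolog_pairing(data.frame(
    pair_id = pairs$pair_id,
    left = paste0(pairs$pair_id, ".L"), right = paste0(pairs$pair_id, ".R"),
    stringsAsFactors = FALSE))
  skels <- lapply(roster$id, chain_skeleton, lengths = c(1, 1))
  names(skels) <- roster$id
  mk <- function(edges, suffix) {
    if (is.null(edges) || !nrow(edges)) return(synapse_table())
    rows <- do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
      k <- edges$count[i]
      synapse_table(
        connector_id = paste0(suffix, i, "_", seq_len(k)),
        pre_neuron = paste0(edges$source[i], suffix),
        pre_node = "2",
        post_neuron = paste0(edges$target[i], suffix), post_node = "2")
    }))
    rows
  }
  syn <- rbind(mk(edges_left, ".L"), mk(edges_right, ".R"))
  wiring_diagram(roster, skels, syn, pairing)
}

# compact generator config for ground-truth recovery runs (sized so that the
# expected number of below-threshold truncated-Poisson draws over a 20-seed
# suite is well under one)
recovery_config <- function(seed, lambda = 10) {
  ed <- rbind(
    data.frame(source_type = "ORN", target_type = "uPN", p = 1,
               lambda = lambda, post = "dendrite", pre = NA, match_glom = TRUE),
    data.frame(source_type = "ORN", target_type = "mPN", p = 1,
               lambda = lambda, post = "dendrite", pre = NA, match_glom = FALSE))
  wiring_config(type_counts = c(ORN = 2, uPN = 2, mPN = 1),
                unpaired = c(mPN = 0), edges = ed,
                fragment_site_rate = 0, seed = seed)
}

# small config for Monte-Carlo spurious-edge survival runs
spurious_config <- function(seed, epsilon = 0.3) {
  ed <- data.frame(source_type = "ORN", target_type = "uPN", p = 1,
                   lambda = 10, post = "dendrite", pre = NA, match_glom = TRUE)
  wiring_config(type_counts = c(ORN = 6, uPN = 6), unpaired = c(mPN = 0),
                edges = ed, epsilon = epsilon, spurious_lambda = 2,
                fragment_site_rate = 0, seed = seed)
}

# brute-force count oracle: direct loop over the synapse table
brute_count <- function(diagram, pre, post) {
  syn <- diagram$synapses
  sum(syn$pre_neuron == pre & syn$post_neuron == post)
}

# brute-force bilateral filter oracle on two count matrices
brute_filter <- function(left, right, min_synapses) {
  kept <- list()
  for (r in rownames(left)) for (c in colnames(left)) {
    if (left[r, c] >= min_synapses && right[r, c] >= min_synapses) {
      kept[[length(kept) + 1L]] <- c(r, c)
    }
  }
  if (length(kept)) sort(vapply(kept, paste, character(1), collapse = "->"))
  else character()
}

# brute-force triad census for input motifs
brute_input_motifs <- function(edges, types, target, source_class = "ORN",
                               relay_class = "PickyLN") {
  key <- paste(edges$source, edges$target)
  has <- function(a, b) paste(a, b) %in% key
  out <- stats::setNames(character(), character())
  for (s in names(types)[types == source_class]) {
    direct <- has(s, target)
    lateral <- FALSE
    for (r in names(types)[types == relay_class]) {
      if (has(s, r) && has(r, target)) lateral <- TRUE
    }
    if (direct && lateral) out[s] <- "feedforward_loop"
    else if (direct) out[s] <- "direct"
    else if (lateral) out[s] <- "lateral"
  }
  out
}

# exhaustive Otsu oracle: maximize between-class variance over every cut at
# the sorted unique values themselves and their midpoints
brute_otsu <- function(values) {
  u <- sort(unique(values))
  cand <- sort(c(u[-length(u)], (u[-1] + u[-length(u)]) / 2))
  best <- -Inf; best_tau <- NA
  for (tau in cand) {
    lo <- values[values <= tau]; hi <- values[values > tau]
    if (!length(lo) || !length(hi)) next
    b <- (length(lo) / length(values)) * (length(hi) / length(values)) *
      (mean(lo) - mean(hi))^2
    if (b > best) { best <- b; best_tau <- tau }
  }
  best_tau
}
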