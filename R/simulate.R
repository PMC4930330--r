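# Seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# zero-truncated Poisson: counts on realized edges are always >= 1
rtpois <- function(n, lambda) {
  p0 <- stats::ppois(0, lambda)
  u <- stats::runif(n, p0, 1)
  stats::qpois(u, lambda)
}

#' Default glomerulus labels
#'
#' 21 receptor-style glomerulus names used by the synthetic roster, one per
#' ORN/uPN pair.
#' @export
GLOMERULI <- c("1a", "13a", "22c", "24a", "30a", "33a", "33b", "35a", "42a",
               "42b", "45a", "45b", "47a", "49a", "59a", "63a", "67b", "74a",
               "82a", "85c", "94a")

#' Default type-level ground-truth edge table
#'
#' One row per (source type, target type) with connection probability `p`,
#' mean synapse count `lambda`, the compartment the postsynaptic sites land
#' on (`post`), an optional presynaptic compartment (`pre`; `"dendrite"`
#' marks dendro-dendritic outputs, `NA` means the source's default, axon if
#' it has one), and `match_glom` restricting edges to same-glomerulus pairs
#' (the ORN -> uPN convergence). Probabilities and means are chosen to mimic
#' the qualitative structure of the larval antennal lobe: panglomerular Broad
#' LN pre- and postsynaptic inhibition, oligoglomerular Picky/Choosy input,
#' a reciprocal Broad-Trio/Keystone core and a sparse Picky hierarchy.
#'
#' @return a `data.frame`.
#' @export
default_edge_table <- function() {
  e <- function(src, tgt, p, lambda, post = "dendrite", pre = NA, match_glom = FALSE)
    data.frame(source_type = src, target_type = tgt, p = p, lambda = lambda,
               post = post, pre = pre, match_glom = match_glom,
               stringsAsFactors = FALSE)
  rbind(
    e("ORN", "uPN",           1.00, 55, match_glom = TRUE),
    e("ORN", "BroadLN_Trio",  1.00,  7),
    e("ORN", "BroadLN_Duet",  1.00, 10),
    e("ORN", "PickyLN",       0.30,  6),
    e("ORN", "ChoosyLN",      0.15,  5),
    e("ORN", "Keystone",      0.50,  5),
    e("ORN", "mPN",           0.35,  7),
    e("ORN", "SEZ",           0.10,  4),
    e("ORN", "VentralLN",     0.15,  4),
    e("BroadLN_Trio", "ORN",  1.00,  5, post = "axon"),
    e("BroadLN_Duet", "ORN",  1.00,  5, post = "axon"),
    e("BroadLN_Trio", "uPN",  1.00,  3),
    e("BroadLN_Duet", "uPN",  1.00, 10),
    e("BroadLN_Trio", "BroadLN_Trio", 1.00, 8),
    e("BroadLN_Trio", "BroadLN_Duet", 1.00, 4),
    e("BroadLN_Duet", "BroadLN_Trio", 1.00, 3),
    e("uPN", "BroadLN_Trio",  1.00,  6, pre = "dendrite"),
    e("uPN", "mPN",           0.15,  5, pre = "dendrite"),
    e("Keystone", "BroadLN_Trio", 1.00, 12),
    e("BroadLN_Trio", "Keystone", 1.00, 10),
    e("Keystone", "ORN",      0.70,  4, post = "axon"),
    e("PickyLN", "Keystone",  0.20,  8),
    e("PickyLN", "mPN",       0.30,  6),
    e("PickyLN", "PickyLN",   0.25,  4),
    e("PickyLN", "ORN",       0.10,  3, post = "axon"),
    e("ChoosyLN", "uPN",      1.00,  6),
    e("VentralLN", "BroadLN_Trio", 1.00, 3)
  )
}

#' Configuration for the synthetic wiring-diagram generator
#'
#' Defaults reproduce the composition of the larval antennal-lobe roster: 78
#' bilateral pairs per animal (21 ORN, 21 uPN, 13 mPN, 3 Broad Trio, 2 Broad
#' Duet, 5 Picky, 2 Choosy, 1 Keystone, 1 Ventral LN, 6 SEZ, 1 descending, 2
#' neuromodulatory) plus 4 ventral unpaired medial neurons (2 mPNs, 2
#' neuromodulatory), 160 neurons in total.
#'
#' @param type_counts named vector: homolog pairs per cell type.
#' @param unpaired named vector: unpaired (VUM) neurons per cell type.
#' @param edges type-level ground-truth edge table ([default_edge_table()]).
#' @param epsilon spurious-edge rate: probability that any ordered same-side
#'   neuron pair not carrying a real edge receives a spurious one, drawn
#'   independently per side (so the bilateral filter has real work to do).
#' @param spurious_lambda mean synapse count of spurious edges.
#' @param mirror_noise probability that a real edge is realized on one
#'   (random) side only.
#' @param fragment_site_rate probability that an ORN postsynaptic site is
#'   diverted to an unassigned-fragment pseudo-neuron (default 0.009).
#' @param skeleton list: `n_dendrite`, `n_axon` node counts, `mean_edge`
#'   micrometres (edge lengths are exponential with this mean),
#'   `branching_prob`.
#' @param axonless cell types without an axon (compartment maps of these have
#'   zero axon nodes).
#' @param glomeruli glomerulus labels for ORN/uPN pairs.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return object of class `wiring_config`.
#' @export
wiring_config <- function(
    type_counts = c(ORN = 21, uPN = 21, mPN = 13, BroadLN_Trio = 3,
                    BroadLN_Duet = 2, PickyLN = 5, ChoosyLN = 2, Keystone = 1,
                    VentralLN = 1, SEZ = 6, Descending = 1, Neuromodulatory = 2),
    unpaired = c(mPN = 2, Neuromodulatory = 2),
    edges = default_edge_table(),
    epsilon = 0, spurious_lambda = 2, mirror_noise = 0,
    fragment_site_rate = 0.009,
    skeleton = list(n_dendrite = 10, n_axon = 6, mean_edge = 2,
                    branching_prob = 0.3),
    axonless = c("BroadLN_Trio", "BroadLN_Duet", "Keystone"),
    glomeruli = GLOMERULI,
    seed = 1) {
  stopifnot(all(edges$p >= 0 & edges$p <= 1), all(edges$lambda > 0),
            all(type_counts >= 0), epsilon >= 0, epsilon <= 1,
            mirror_noise >= 0, mirror_noise <= 1,
            fragment_site_rate >= 0, fragment_site_rate <= 1)
  if (("ORN" %in% names(type_counts)) &&
      type_counts[["ORN"]] > length(glomeruli)) {
    stop("more ORN pairs than glomerulus labels")
  }
  structure(
    list(type_counts = type_counts, unpaired = unpaired, edges = edges,
         epsilon = epsilon, spurious_lambda = spurious_lambda,
         mirror_noise = mirror_noise, fragment_site_rate = fragment_site_rate,
         skeleton = skeleton, axonless = axonless, glomeruli = glomeruli,
         seed = seed),
    class = "wiring_config"
  )
}

# random rooted tree: root (soma) + dendritic subtree + optional axonal
# subtree whose first node carries the "axon start" / "axon initial segment"
# tags
build_skeleton <- function(neuron_id, cfg, axonless) {
  nd <- cfg$n_dendrite; na <- if (axonless) 0L else cfg$n_axon
  n <- 1L + nd + na
  parent <- rep(NA_integer_, n)
  grow <- function(first, count, attach_to) {
    # chain with occasional branching back to an earlier node of the subtree
    ids <- seq(first, length.out = count)
    for (k in seq_along(ids)) {
      if (k == 1L) parent[ids[k]] <<- attach_to
      else if (stats::runif(1) < cfg$branching_prob)
        parent[ids[k]] <<- sample(ids[seq_len(k - 1L)], 1L)
      else parent[ids[k]] <<- ids[k - 1L]
    }
  }
  if (nd > 0) grow(2L, nd, 1L)
  if (na > 0) grow(2L + nd, na, 1L)
  len <- stats::rexp(n, rate = 1 / cfg$mean_edge)
  dir <- matrix(stats::rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  xyz <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)[-1L]) xyz[i, ] <- xyz[parent[i], ] + len[i] * dir[i, ]
  tags <- data.frame(node_id = "1", tag = "soma", stringsAsFactors = FALSE)
  if (na > 0) {
    ais <- as.character(2L + nd)
    tags <- rbind(tags,
                  data.frame(node_id = ais, tag = "axon start"),
                  data.frame(node_id = ais, tag = "axon initial segment"))
  }
  skeleton(neuron_id,
           nodes = data.frame(node_id = as.character(seq_len(n)),
                              parent_id = as.character(parent),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              stringsAsFactors = FALSE),
           tags = tags)
}

build_roster <- function(config) {
  rows <- list(); pairs <- list(); unp <- character()
  for (ty in names(config$type_counts)) {
    k <- config$type_counts[[ty]]
    if (k == 0) next
    pid <- if (ty %in% c("ORN", "uPN")) {
      paste0(ty, ".", config$glomeruli[seq_len(k)])
    } else paste0(ty, ".", seq_len(k))
    glom <- if (ty %in% c("ORN", "uPN")) config$glomeruli[seq_len(k)] else NA
    rows[[length(rows) + 1L]] <- neuron_roster(
      id = c(paste0(pid, ".L"), paste0(pid, ".R")),
      cell_type = ty, side = rep(c("left", "right"), each = k),
      glomerulus = rep(glom, 2)
    )
    pairs[[length(pairs) + 1L]] <- data.frame(
      pair_id = pid, left = paste0(pid, ".L"), right = paste0(pid, ".R"),
      stringsAsFactors = FALSE
    )
  }
  for (ty in names(config$unpaired)) {
    k <- config$unpaired[[ty]]
    if (k == 0) next
    id <- paste0(ty, ".VUM.", seq_len(k))
    rows[[length(rows) + 1L]] <- neuron_roster(id = id, cell_type = ty,
                                               side = "unpaired")
    unp <- c(unp, id)
  }
  list(roster = do.call(rbind, rows),
       pairing = homolog_pairing(do.call(rbind, pairs), unpaired = unp))
}

#' Generate a synthetic wiring diagram with known ground truth
#'
#' Draws a mirrored left/right diagram from a [wiring_config()]: for every
#' type-level edge, each eligible (source pair, target pair) combination
#' carries a real connection with probability `p`; real connections are
#' realized on both sides (unless dropped on one by `mirror_noise`) with
#' zero-truncated Poisson(`lambda`) synapse counts. Spurious connections are
#' drawn independently per side at rate `epsilon`. Skeletons are random
#' rooted trees with tagged axon-start / axon-initial-segment nodes, and
#' synapse sites are placed on the configured compartments. A configurable
#' fraction of ORN postsynaptic sites is diverted to unassigned-fragment
#' pseudo-neurons.
#'
#' @param config a [wiring_config()].
#' @return list with elements `diagram` (a [wiring_diagram()]) and
#'   `ground_truth`: `edges` (pair-level real connections) and `realized`
#'   (per-side neuron-level edges with counts and a `spurious` flag).
#' @export
generate_wiring <- function(config) {
  stopifnot(inherits(config, "wiring_config"))
  with_seed(config$seed, {
    ros <- build_roster(config)
    roster <- ros$roster; pairing <- ros$pairing

    skels <- lapply(seq_len(nrow(roster)), function(i) {
      build_skeleton(roster$id[i], config$skeleton,
                     roster$cell_type[i] %in% config$axonless)
    })
    names(skels) <- roster$id
    comps <- lapply(skels, label_compartments)

    pair_type <- roster$cell_type[match(pairing$pairs$left, roster$id)]
    names(pair_type) <- pairing$pairs$pair_id
    pair_glom <- roster$glomerulus[match(pairing$pairs$left, roster$id)]
    names(pair_glom) <- pairing$pairs$pair_id
    unp_type <- roster$cell_type[match(pairing$unpaired, roster$id)]
    names(unp_type) <- pairing$unpaired

    side_id <- function(pair, side) {
      if (pair %in% pairing$pairs$pair_id) {
        i <- match(pair, pairing$pairs$pair_id)
        if (side == "left") pairing$pairs$left[i] else pairing$pairs$right[i]
      } else pair  # unpaired neurons are their own instance on both sides
    }

    gt_edges <- list(); realized <- list()
    for (i in seq_len(nrow(config$edges))) {
      ed <- config$edges[i, ]
      src <- names(pair_type)[pair_type == ed$source_type]
      tgt <- c(names(pair_type)[pair_type == ed$target_type],
               names(unp_type)[unp_type == ed$target_type])
      if (!length(src) || !length(tgt)) next
      combos <- expand.grid(source = src, target = tgt,
                            stringsAsFactors = FALSE)
      combos <- combos[combos$source != combos$target, , drop = FALSE]
      if (isTRUE(ed$match_glom)) {
        combos <- combos[!is.na(pair_glom[combos$source]) &
                           pair_glom[combos$source] ==
                             pair_glom[combos$target], , drop = FALSE]
      }
      if (!nrow(combos)) next
      real <- stats::runif(nrow(combos)) < ed$p
      combos <- combos[real, , drop = FALSE]
      if (!nrow(combos)) next
      gt_edges[[length(gt_edges) + 1L]] <- data.frame(
        source = combos$source, target = combos$target,
        source_type = ed$source_type, target_type = ed$target_type,
        lambda = ed$lambda, stringsAsFactors = FALSE
      )
      for (j in seq_len(nrow(combos))) {
        sides <- c("left", "right")
        if (config$mirror_noise > 0 &&
            stats::runif(1) < config$mirror_noise) {
          sides <- sample(sides, 1L)
        }
        for (sd_ in sides) {
          realized[[length(realized) + 1L]] <- data.frame(
            source = combos$source[j], target = combos$target[j],
            side = sd_,
            source_neuron = side_id(combos$source[j], sd_),
            target_neuron = side_id(combos$target[j], sd_),
            count = rtpois(1, ed$lambda),
            post = ed$post, pre = if (is.na(ed$pre)) NA_character_ else ed$pre,
            spurious = FALSE, stringsAsFactors = FALSE
          )
        }
      }
    }
    gt_edges <- if (length(gt_edges)) do.call(rbind, gt_edges) else
      data.frame(source = character(), target = character(),
                 source_type = character(), target_type = character(),
                 lambda = numeric(), stringsAsFactors = FALSE)

    # spurious edges, independent per side
    if (config$epsilon > 0) {
      real_keys <- unique(unlist(lapply(realized, function(d)
        paste(d$source_neuron, d$target_neuron))))
      for (sd_ in c("left", "right")) {
        ids <- roster$id[roster$side == sd_]
        cand <- expand.grid(source_neuron = ids, target_neuron = ids,
                            stringsAsFactors = FALSE)
        cand <- cand[cand$source_neuron != cand$target_neuron, , drop = FALSE]
        key <- paste(cand$source_neuron, cand$target_neuron)
        cand <- cand[!key %in% real_keys, , drop = FALSE]
        hit <- stats::runif(nrow(cand)) < config$epsilon
        cand <- cand[hit, , drop = FALSE]
        if (nrow(cand)) {
          to_pair <- c(stats::setNames(pairing$pairs$pair_id, pairing$pairs$left),
                       stats::setNames(pairing$pairs$pair_id, pairing$pairs$right))
          realized[[length(realized) + 1L]] <- data.frame(
            source = unname(to_pair[cand$source_neuron]),
            target = unname(to_pair[cand$target_neuron]),
            side = sd_, source_neuron = cand$source_neuron,
            target_neuron = cand$target_neuron,
            count = rtpois(nrow(cand), config$spurious_lambda),
            post = "dendrite", pre = NA_character_,
            spurious = TRUE, stringsAsFactors = FALSE
          )
        }
      }
    }
    realized <- if (length(realized)) do.call(rbind, realized) else
      data.frame(source = character(), target = character(), side = character(),
                 source_neuron = character(), target_neuron = character(),
                 count = integer(), post = character(), pre = character(),
                 spurious = logical(), stringsAsFactors = FALSE)
    rownames(realized) <- NULL

    # place synapse sites on skeleton nodes
    syn <- place_synapses(realized, skels, comps, roster, config)
    diagram <- wiring_diagram(syn$roster, syn$skeletons, syn$synapses, pairing)
    list(diagram = diagram,
         ground_truth = list(edges = gt_edges, realized = realized))
  })
}

# sample pre/post nodes per realized edge; divert a fraction of ORN
# postsynaptic sites to fragment pseudo-neurons
place_synapses <- function(realized, skels, comps, roster, config) {
  nodes_in <- function(neuron, wanted) {
    cm <- comps[[neuron]]
    out <- names(cm)[cm %in% wanted]
    if (!length(out)) names(cm)  # fall back to any node
    else out
  }
  pre_default <- function(neuron) {
    ty <- roster$cell_type[match(neuron, roster$id)]
    if (ty %in% config$axonless) "dendrite" else "axon"
  }
  rows <- vector("list", nrow(realized))
  cid <- 0L
  for (k in seq_len(nrow(realized))) {
    r <- realized[k, ]
    n <- r$count
    pre_comp <- if (is.na(r$pre)) pre_default(r$source_neuron) else r$pre
    pre_pool <- nodes_in(r$source_neuron, pre_comp)
    post_pool <- nodes_in(r$target_neuron, r$post)
    rows[[k]] <- data.frame(
      connector_id = as.character(cid + seq_len(n)),
      pre_neuron = r$source_neuron,
      pre_node = sample(pre_pool, n, replace = TRUE),
      post_neuron = r$target_neuron,
      post_node = sample(post_pool, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    cid <- cid + n
  }
  syn <- if (length(rows)) do.call(rbind, rows) else synapse_table()
  rownames(syn) <- NULL

  # unassigned fragments: divert ORN postsynaptic sites
  if (config$fragment_site_rate > 0 && nrow(syn)) {
    orn_ids <- roster$id[roster$cell_type == "ORN"]
    is_orn_site <- syn$pre_neuron %in% orn_ids
    divert <- is_orn_site & stats::runif(nrow(syn)) < config$fragment_site_rate
    if (any(divert)) {
      for (sd_ in c("L", "R")) {
        fid <- paste0("fragment.", sd_)
        roster <- rbind(roster, neuron_roster(
          id = fid, cell_type = "Other",
          side = ifelse(sd_ == "L", "left", "right"), is_fragment = TRUE))
        skels[[fid]] <- skeleton(fid, nodes = data.frame(
          node_id = c("1", "2"), parent_id = c(NA, "1"),
          x = c(0, config$skeleton$mean_edge), y = 0, z = 0,
          stringsAsFactors = FALSE))
      }
      frag_of <- ifelse(grepl("\\.L$", syn$pre_neuron[divert]),
                        "fragment.L", "fragment.R")
      syn$post_neuron[divert] <- frag_of
      syn$post_node[divert] <- sample(c("1", "2"), sum(divert), replace = TRUE)
    }
  }
  list(roster = roster, skeletons = skels, synapses = syn)
}

# ---- ORN response matrices ---------------------------------------------------

#' Configuration for synthetic ORN response matrices
#'
#' Plants a known cluster structure: odorants fall into `n_clusters` chemical
#' classes, each eliciting elevated responses in its class-specific set of
#' encoding ORNs and background responses elsewhere. A matching
#' odorant-descriptor matrix with the same class structure is generated for
#' descriptor-space clustering.
#'
#' @param n_orns,n_odorants matrix dimensions.
#' @param n_clusters number of planted odorant classes.
#' @param encoding list of `n_clusters` integer vectors (ORN indices encoding
#'   each class); default splits the first ORNs into disjoint sets of 4.
#' @param within_mean,within_sd response distribution (spikes/s) of an
#'   odorant at its class's encoding ORNs.
#' @param background_mean,background_sd response elsewhere.
#' @param n_descriptors dimensionality of the odorant descriptor space.
#' @param descriptor_sd within-class spread of descriptors (class centres are
#'   standard-normal draws scaled by 3).
#' @param class_names labels for the planted classes.
#' @param seed integer seed.
#' @return object of class `response_config`.
#' @export
response_config <- function(n_orns = 21, n_odorants = 35, n_clusters = 5,
                            encoding = NULL,
                            within_mean = 150, within_sd = 15,
                            background_mean = 10, background_sd = 5,
                            n_descriptors = 32, descriptor_sd = 0.5,
                            class_names = NULL, seed = 1) {
  if (is.null(encoding)) {
    per <- 4L
    if (n_clusters * per > n_orns) per <- max(1L, n_orns %/% n_clusters)
    encoding <- lapply(seq_len(n_clusters),
                       function(c) ((c - 1L) * per + 1L):((c - 1L) * per + per))
  }
  stopifnot(n_clusters >= 1, length(encoding) == n_clusters,
            all(unlist(encoding) >= 1), all(unlist(encoding) <= n_orns))
  if (is.null(class_names)) {
    base <- c("alcohols", "aromatics", "esters", "pyrazines", "mixed")
    class_names <- if (n_clusters <= 5) base[seq_len(n_clusters)] else
      paste0("class", seq_len(n_clusters))
  }
  structure(
    list(n_orns = n_orns, n_odorants = n_odorants, n_clusters = n_clusters,
         encoding = encoding, within_mean = within_mean, within_sd = within_sd,
         background_mean = background_mean, background_sd = background_sd,
         n_descriptors = n_descriptors, descriptor_sd = descriptor_sd,
         class_names = class_names, seed = seed),
    class = "response_config"
  )
}

#' Generate a synthetic ORN x odorant response matrix
#'
#' @param config a [response_config()].
#' @return list of class `orn_responses`: `responses` (odorants x ORNs),
#'   `descriptors` (odorants x descriptors), `odorant_class` (planted class
#'   label per odorant), `encoding` (planted encoding-ORN name sets per
#'   class).
#' @export
generate_responses <- function(config) {
  stopifnot(inherits(config, "response_config"))
  with_seed(config$seed, {
    orns <- sprintf("ORN%02d", seq_len(config$n_orns))
    odors <- sprintf("od%02d", seq_len(config$n_odorants))
    cls <- rep(seq_len(config$n_clusters), length.out = config$n_odorants)
    cls <- sort(cls)
    resp <- matrix(
      stats::rnorm(config$n_odorants * config$n_orns,
                   config$background_mean, config$background_sd),
      nrow = config$n_odorants, dimnames = list(odors, orns))
    for (c in seq_len(config$n_clusters)) {
      rows <- which(cls == c); cols <- config$encoding[[c]]
      resp[rows, cols] <- stats::rnorm(length(rows) * length(cols),
                                       config$within_mean, config$within_sd)
    }
    centres <- matrix(3 * stats::rnorm(config$n_clusters * config$n_descriptors),
                      nrow = config$n_clusters)
    desc <- centres[cls, , drop = FALSE] +
      matrix(stats::rnorm(config$n_odorants * config$n_descriptors,
                          0, config$descriptor_sd),
             nrow = config$n_odorants)
    dimnames(desc) <- list(odors, sprintf("D%02d", seq_len(config$n_descriptors)))
    structure(
      list(responses = resp, descriptors = desc,
           odorant_class = stats::setNames(config$class_names[cls], odors),
           encoding = stats::setNames(
             lapply(config$encoding, function(i) orns[i]),
             config$class_names),
           config = config),
      class = "orn_responses")
  })
}

#' @export
print.orn_responses <- function(x, ...) {
  cat(sprintf("<orn_responses> %d odorants x %d ORNs, %d planted classes\n",
              nrow(x$responses), ncol(x$responses), x$config$n_clusters))
  invisible(x)
}
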