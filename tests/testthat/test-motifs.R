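motif_graph <- function(edges, types) {
  circuit_graph(data.frame(source = edges$source, target = edges$target,
                           weight = if (is.null(edges$weight)) 1
                                    else edges$weight),
                node_types = types)
}

test_that("input motifs classify direct, lateral and feedforward loops", {
  types <- c(A = "ORN", P = "PickyLN", M = "mPN")
  # A->M, A->P, P->M: a feedforward loop
  g <- motif_graph(data.frame(source = c("A", "A", "P"),
                              target = c("M", "P", "M")), types)
  res <- input_motifs(g, "M")
  expect_equal(res$motif, "feedforward_loop")
  expect_equal(res$relays, "P")
  # A->P, P->M only: lateral
  g2 <- motif_graph(data.frame(source = c("A", "P"), target = c("P", "M")),
                    types)
  expect_equal(input_motifs(g2, "M")$motif, "lateral")
  # A->M only: direct
  g3 <- motif_graph(data.frame(source = "A", target = "M"), types)
  expect_equal(input_motifs(g3, "M")$motif, "direct")
  # empty graph: no motifs; unknown target errors
  g0 <- circuit_graph(data.frame(source = character(), target = character(),
                                 weight = numeric()), types)
  expect_equal(nrow(input_motifs(g0, "M")), 0)
  expect_error(input_motifs(g0, "Z"), "not in graph")
})

test_that("motif census equals brute-force triad enumeration on random graphs", {
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    ids <- paste0("n", seq_len(n))
    types <- stats::setNames(
      sample(c("ORN", "PickyLN", "mPN"), n, replace = TRUE), ids)
    types[sample(n, 1)] <- "mPN"  # ensure a target exists
    m <- matrix(stats::runif(n * n) < 0.35, n, n); diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                        weight = rep(1, nrow(idx)))
    g <- circuit_graph(edges, types)
    for (tgt in names(types)[types == "mPN"]) {
      got <- input_motifs(g, tgt)
      want <- brute_input_motifs(edges, types, tgt)
      expect_equal(stats::setNames(got$motif, got$source), want)
    }
  }
})

test_that("motif classes partition the influencing sources", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 7
    ids <- paste0("n", seq_len(n))
    types <- stats::setNames(
      c("mPN", sample(c("ORN", "PickyLN"), n - 1, replace = TRUE)), ids)
    m <- matrix(stats::runif(n * n) < 0.4, n, n); diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    g <- circuit_graph(data.frame(source = ids[idx[, 1]],
                                  target = ids[idx[, 2]],
                                  weight = rep(1, nrow(idx))), types)
    res <- input_motifs(g, "n1")
    expect_equal(anyDuplicated(res$source), 0)  # one class per source
  }
})

test_that("hierarchy layering condenses cycles and ranks by longest path", {
  types <- stats::setNames(rep("PickyLN", 4), paste0("P", 0:3))
  # P0 -> P1, P0 -> P2: P0 on top
  g <- motif_graph(data.frame(source = c("P0", "P0"), target = c("P1", "P2")),
                   types[1:3])
  h <- hierarchy_layers(g)
  expect_equal(unname(h$ranks[c("P0", "P1", "P2")]), c(0L, 1L, 1L))
  expect_equal(h$dominant, "P0")
  # a 2-cycle merges into one reciprocal component
  g2 <- motif_graph(data.frame(source = c("P1", "P2"), target = c("P2", "P1")),
                    types[2:3])
  h2 <- hierarchy_layers(g2)
  expect_length(h2$reciprocal_components, 1)
  expect_setequal(h2$reciprocal_components[[1]], c("P1", "P2"))
  expect_equal(unname(h2$ranks[c("P1", "P2")]), c(0L, 0L))
  # parallel nodes (no path either way) are flagged
  g3 <- motif_graph(data.frame(source = c("P0", "P3"), target = c("P1", "P1")),
                    types)
  h3 <- hierarchy_layers(g3)
  expect_true(any((h3$parallel$a == "P0" & h3$parallel$b == "P3") |
                    (h3$parallel$a == "P3" & h3$parallel$b == "P0")))
})

test_that("hierarchy ranks equal a brute-force longest-path oracle on DAGs", {
  brute_rank <- function(edges, nodes) {
    preds <- function(v) edges$source[edges$target == v]
    rank1 <- function(v) {
      p <- preds(v)
      if (!length(p)) return(0L)
      1L + max(vapply(p, rank1, integer(1)))
    }
    vapply(nodes, rank1, integer(1))
  }
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    ids <- paste0("n", seq_len(n))
    # random DAG: edges only from lower to higher index
    m <- matrix(stats::runif(n * n) < 0.4 & upper.tri(matrix(0, n, n)), n, n)
    idx <- which(m, arr.ind = TRUE)
    edges <- data.frame(source = ids[idx[, 1]], target = ids[idx[, 2]],
                        weight = rep(1, nrow(idx)), stringsAsFactors = FALSE)
    g <- circuit_graph(edges, stats::setNames(rep("PickyLN", n), ids))
    h <- hierarchy_layers(g)
    expect_equal(h$ranks[ids], brute_rank(edges, stats::setNames(ids, ids)))
  }
})

test_that("hierarchy output is invariant to node relabeling", {
  types <- stats::setNames(rep("PickyLN", 4), paste0("P", 1:4))
  edges <- data.frame(source = c("P1", "P1", "P2"),
                      target = c("P2", "P3", "P4"), weight = 1)
  h <- hierarchy_layers(motif_graph(edges, types))
  # relabel via permutation
  perm <- c(P1 = "Q3", P2 = "Q1", P3 = "Q4", P4 = "Q2")
  edges2 <- data.frame(source = unname(perm[edges$source]),
                       target = unname(perm[edges$target]), weight = 1)
  h2 <- hierarchy_layers(motif_graph(edges2, stats::setNames(rep("PickyLN", 4),
                                                             unname(perm))))
  expect_equal(unname(h2$ranks[unname(perm[names(h$ranks)])]),
               unname(h$ranks))
  expect_equal(unname(perm[h$dominant]), h2$dominant)
})

test_that("reciprocal cores need both directions at threshold", {
  types <- c(T1 = "BroadLN_Trio", K = "Keystone")
  g <- motif_graph(data.frame(source = c("T1", "K"), target = c("K", "T1"),
                              weight = c(10, 8)), types)
  rc <- reciprocal_cores(g, "BroadLN_Trio", "Keystone", min_weight = 5)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$weight_ab, 10)
  # one direction only -> not reported
  g2 <- motif_graph(data.frame(source = "T1", target = "K", weight = 10), types)
  expect_equal(nrow(reciprocal_cores(g2, "BroadLN_Trio", "Keystone", 5)), 0)
  # equals brute-force pair scan on random graphs
  set.seed(53)
  for (rep in 1:10) {
    ids <- paste0("n", 1:5)
    ty <- stats::setNames(sample(c("BroadLN_Trio", "Keystone"), 5,
                                 replace = TRUE), ids)
    m <- matrix(stats::rpois(25, 2), 5, 5, dimnames = list(ids, ids))
    diag(m) <- 0
    idx <- which(m > 0, arr.ind = TRUE)
    g3 <- circuit_graph(data.frame(source = ids[idx[, 1]],
                                   target = ids[idx[, 2]],
                                   weight = m[idx]), ty)
    rc3 <- reciprocal_cores(g3, "BroadLN_Trio", "Keystone", min_weight = 2)
    brute <- 0L
    for (a in ids[ty == "BroadLN_Trio"]) for (b in ids[ty == "Keystone"]) {
      if (a != b && m[a, b] >= 2 && m[b, a] >= 2) brute <- brute + 1L
    }
    expect_equal(nrow(rc3), brute)
  }
})

test_that("group self-arrows average within-group inputs per member", {
  pairs <- data.frame(pair_id = c("T1", "T2", "T3"),
                      cell_type = "BroadLN_Trio", glomerulus = NA)
  edges <- data.frame(source = c("T1", "T2", "T3"),
                      target = c("T2", "T3", "T1"), count = c(4, 6, 2))
  d <- mirrored_diagram(pairs, edges, NULL)
  members <- c("T1.L", "T2.L", "T3.L")
  expect_equal(group_self_weight(d, members), (4 + 6 + 2) / 3)
})

test_that("inhibition profiles expose uniform vs selective source heterogeneity", {
  # 4 glomeruli; source U hits every ORN axon equally, source S skips two
  roster <- rbind(
    neuron_roster(paste0("orn", 1:4), cell_type = "ORN", side = "right",
                  glomerulus = paste0("g", 1:4)),
    neuron_roster(c("U", "S"), cell_type = c("BroadLN_Trio", "Keystone"),
                  side = "right"))
  sks <- lapply(roster$id, function(id)
    chain_skeleton(id, c(1, 1), tags = data.frame(node_id = "2",
                                                  tag = "axon start")))
  names(sks) <- roster$id
  syn <- rbind(
    do.call(rbind, lapply(1:4, function(i) synapse_table(
      paste0("u", i, "_", 1:3), "U", "2", paste0("orn", i), "3"))),
    do.call(rbind, lapply(1:2, function(i) synapse_table(
      paste0("s", i, "_", 1:6), "S", "2", paste0("orn", i), "3"))))
  d <- wiring_diagram(roster, sks, syn)
  prof <- inhibition_profile(d, list(uniform = "U", selective = "S"),
                             target = "ORN_axon", side = "right")
  expect_lt(prof$cv[["uniform"]], prof$cv[["selective"]])
  # single source contributing everything -> 100% everywhere
  d1 <- d
  d1$synapses <- d$synapses[d$synapses$pre_neuron == "U", ]
  prof1 <- inhibition_profile(d1, list(uniform = "U"), target = "ORN_axon",
                              side = "right")
  expect_true(all(prof1$percent[, "uniform"] == 100))
  expect_equal(unname(prof1$cv[["uniform"]]), 0)
  # glomerulus with no axonal input excluded with warning
  d2 <- d
  d2$synapses <- d$synapses[d$synapses$post_neuron != "orn4", ]
  expect_warning(prof2 <- inhibition_profile(
    d2, list(uniform = "U"), target = "ORN_axon", side = "right"), "excluded")
  expect_true("g4" %in% prof2$excluded)
})

test_that("edge weight views scale display weights without touching counts", {
  types <- c(A = "ORN", B = "mPN")
  g <- motif_graph(data.frame(source = "A", target = "B", weight = 16), types)
  expect_equal(edge_weight_views(g, "sqrt")$edges$display_weight, 4)
  expect_equal(edge_weight_views(g, "linear")$edges$display_weight, 16)
  expect_equal(edge_weight_views(g, "sqrt")$edges$weight, 16)
})
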