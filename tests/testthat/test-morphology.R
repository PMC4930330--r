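test_that("compartment labels follow the axon-start subtree rule", {
  # no axon tag: axonless neuron, everything dendrite (bar the soma)
  sk <- chain_skeleton("n", c(1, 1, 1),
                       tags = data.frame(node_id = "1", tag = "soma"))
  lab <- label_compartments(sk)
  expect_equal(sum(lab == "axon"), 0)
  expect_equal(unname(lab[["1"]]), "soma")
  # tag at the root: the whole arbor is axon
  sk2 <- chain_skeleton("n", c(1, 1),
                        tags = data.frame(node_id = "1", tag = "axon start"))
  expect_true(all(label_compartments(sk2) == "axon"))
  # tag on a missing node errors
  sk3 <- chain_skeleton("n", 1,
                        tags = data.frame(node_id = "9", tag = "axon start"))
  expect_error(label_compartments(sk3), "non-existent")
})

test_that("compartment labels equal brute-force descendant enumeration", {
  set.seed(5)
  brute_descendants <- function(sk, node) {
    # repeatedly expand the descendant set until fixed point
    out <- node
    repeat {
      more <- sk$nodes$node_id[sk$nodes$parent_id %in% out]
      new <- setdiff(more, out)
      if (!length(new)) return(out)
      out <- c(out, new)
    }
  }
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    tag_at <- as.character(sample.int(n, 1))
    sk <- random_tree_skeleton("n", n,
                               tags = data.frame(node_id = tag_at,
                                                 tag = "axon start"))
    lab <- label_compartments(sk)
    axon <- names(lab)[lab == "axon"]
    expect_setequal(axon, brute_descendants(sk, tag_at))
  }
})

test_that("cable length is additive over edges and compartments", {
  sk <- chain_skeleton("n", c(3, 4))
  expect_equal(cable_length(sk), 7)
  single <- skeleton("s", data.frame(node_id = "1", parent_id = NA,
                                     x = 0, y = 0, z = 0))
  expect_equal(cable_length(single), 0)
  # additivity: axon + dendrite + soma = total
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    sk <- random_tree_skeleton("n", n, tags = data.frame(
      node_id = c("1", as.character(sample(2:n, 1))),
      tag = c("soma", "axon start")))
    cm <- label_compartments(sk)
    expect_equal(cable_length(sk),
                 cable_length(sk, "axon", cm) +
                   cable_length(sk, "dendrite", cm) +
                   cable_length(sk, "soma", cm))
  }
})

test_that("cable length equals a brute-force edge-sum oracle", {
  set.seed(23)
  for (rep in 1:10) {
    sk <- random_tree_skeleton("n", sample(5:30, 1))
    nodes <- sk$nodes
    tot <- 0
    for (i in seq_len(nrow(nodes))) {
      if (is.na(nodes$parent_id[i])) next
      j <- which(nodes$node_id == nodes$parent_id[i])
      tot <- tot + sqrt(sum((unlist(nodes[i, c("x", "y", "z")]) -
                               unlist(nodes[j, c("x", "y", "z")]))^2))
    }
    expect_equal(cable_length(sk), tot)
  }
})

test_that("geodesic distances to the tagged node match the tree metric", {
  sk <- chain_skeleton("n", c(3, 4),
                       tags = data.frame(node_id = "1",
                                         tag = "axon initial segment"))
  expect_equal(distance_to_tag(sk, "1"), 0)
  expect_equal(distance_to_tag(sk, "3"), 7)
  # missing or duplicated tag errors, naming the skeleton
  sk0 <- chain_skeleton("sk0", 1)
  expect_error(distance_to_tag(sk0, "1"), "sk0")
  sk2 <- chain_skeleton("sk2", 1, tags = data.frame(
    node_id = c("1", "2"), tag = "axon initial segment"))
  expect_error(distance_to_tag(sk2, "1"), "sk2")
})

test_that("geodesic distance equals the igraph shortest-path oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:25, 1)
    sk <- random_tree_skeleton("n", n)
    nodes <- sk$nodes
    has_p <- !is.na(nodes$parent_id)
    w <- sqrt((nodes$x[has_p] - nodes$x[match(nodes$parent_id[has_p], nodes$node_id)])^2 +
                (nodes$y[has_p] - nodes$y[match(nodes$parent_id[has_p], nodes$node_id)])^2 +
                (nodes$z[has_p] - nodes$z[match(nodes$parent_id[has_p], nodes$node_id)])^2)
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes$parent_id[has_p], to = nodes$node_id[has_p]),
      directed = FALSE,
      vertices = data.frame(name = nodes$node_id))
    a <- as.character(sample.int(n, 1)); b <- as.character(sample.int(n, 1))
    oracle <- igraph::distances(g, a, b, weights = w)[1, 1]
    expect_equal(geodesic_distance(sk, a, b), oracle)
  }
})

test_that("tree-metric property: child/parent distances differ by the edge", {
  set.seed(37)
  sk <- random_tree_skeleton("n", 20, tags = data.frame(
    node_id = "7", tag = "axon initial segment"))
  nodes <- sk$nodes
  for (i in which(!is.na(nodes$parent_id))) {
    nid <- nodes$node_id[i]; pid <- nodes$parent_id[i]
    j <- which(nodes$node_id == pid)
    edge <- sqrt(sum((unlist(nodes[i, c("x", "y", "z")]) -
                        unlist(nodes[j, c("x", "y", "z")]))^2))
    expect_equal(abs(distance_to_tag(sk, nid) - distance_to_tag(sk, pid)),
                 edge, tolerance = 1e-9)
  }
})

test_that("distance profiles expose per-source medians for proximity claims", {
  d <- toy_two_neuron()
  d$skeletons$B <- chain_skeleton("B", c(10, 10), tags = data.frame(
    node_id = "1", tag = "axon initial segment"))
  d$synapses <- synapse_table(c("c1", "c2"), "A", "2", "B", c("2", "3"))
  prof <- distance_profile(d, "B")
  expect_equal(sort(prof$distance), c(10, 20))
  expect_equal(unname(attr(prof, "medians")[["A"]]), 15)
  # no inputs -> empty profile
  d0 <- d; d0$synapses <- synapse_table()
  expect_equal(nrow(distance_profile(d0, "B")), 0)
})

test_that("a proximally-placed source has the smaller median distance", {
  # target chain of 10 edges, AIS at the root; source P synapses on nodes
  # 2-3 (proximal), source Q on nodes 9-11 (distal)
  roster <- neuron_roster(c("P", "Q", "T"),
                          cell_type = c("ChoosyLN", "BroadLN_Trio", "uPN"),
                          side = "left", glomerulus = c(NA, NA, "g1"))
  tsk <- chain_skeleton("T", rep(2, 10), tags = data.frame(
    node_id = "1", tag = "axon initial segment"))
  sks <- list(P = chain_skeleton("P", 1), Q = chain_skeleton("Q", 1), T = tsk)
  syn <- rbind(
    synapse_table(c("p1", "p2"), "P", "2", "T", c("2", "3")),
    synapse_table(c("q1", "q2", "q3"), "Q", "2", "T", c("9", "10", "11")))
  d <- wiring_diagram(roster, sks, syn)
  med <- attr(distance_profile(d, "T"), "medians")
  expect_lt(med[["P"]], med[["Q"]])
})

test_that("polarity index has the documented boundary and symmetry behaviour", {
  expect_equal(polarity_index(2, 0), 1)    # all dendritic
  expect_equal(polarity_index(0, 3), -1)   # all axonal
  expect_equal(polarity_index(4, 4), 0)    # balanced
  expect_true(is.na(polarity_index(0, 0)))
  # antisymmetry and scale invariance
  set.seed(41)
  for (rep in 1:20) {
    dd <- sample(0:9, 1); aa <- sample(0:9, 1)
    if (dd + aa == 0) next
    expect_equal(polarity_index(dd, aa), -polarity_index(aa, dd))
    k <- sample(1:5, 1)
    expect_equal(polarity_index(k * dd, k * aa), polarity_index(dd, aa))
    expect_equal(sign(polarity_index(dd, aa)), sign(dd - aa))
  }
})

test_that("polarity tables split counts by target compartment and negate on relabel", {
  roster <- neuron_roster(c("orn", "picky"), cell_type = c("ORN", "PickyLN"),
                          side = "left", glomerulus = c("g1", NA))
  psk <- chain_skeleton("picky", c(1, 1, 1), tags = data.frame(
    node_id = "3", tag = "axon start"))
  d <- wiring_diagram(roster,
                      list(orn = chain_skeleton("orn", 1), picky = psk),
                      rbind(synapse_table(paste0("d", 1:3), "orn", "2",
                                          "picky", "2"),
                            synapse_table(paste0("a", 1:2), "orn", "2",
                                          "picky", "4")))
  tab <- polarity_table(d, "orn", "picky", min_synapses = 2)
  expect_equal(tab$dendrite, 3L)
  expect_equal(tab$axon, 2L)
  expect_equal(tab$polarity, 1 / 5)
  # swapping axon/dendrite labels negates the index
  comps <- compartment_maps(d)
  flipped <- comps
  flipped$picky[flipped$picky == "axon"] <- "tmp"
  flipped$picky[flipped$picky == "dendrite"] <- "axon"
  flipped$picky[flipped$picky == "tmp"] <- "dendrite"
  tab2 <- polarity_table(d, "orn", "picky", compartments = flipped,
                         min_synapses = 2)
  expect_equal(tab2$polarity, -tab$polarity)
  # below the per-compartment threshold the connection is not reported
  expect_equal(nrow(polarity_table(d, "orn", "picky", min_synapses = 4)), 0)
})
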