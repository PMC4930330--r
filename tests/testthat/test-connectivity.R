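test_that("count_matrix counts postsynaptic sites, polyadic and grouped", {
  # one connector with two sites on B -> count 2
  d <- toy_two_neuron(n_sites = 2)
  m <- count_matrix(d, "A", "B")
  expect_equal(m["A", "B"], 2L)
  # no synapses -> zero matrix
  d0 <- d; d0$synapses <- synapse_table()
  expect_true(all(count_matrix(d0, "A", "B") == 0))
  # unknown id errors
  expect_error(count_matrix(d, "nope", "B"), "unknown neuron")
  # grouped rows sum members
  d$neurons <- rbind(d$neurons, neuron_roster("A2", cell_type = "ORN",
                                              side = "left", glomerulus = "g2"))
  d$skeletons$A2 <- chain_skeleton("A2", c(1, 1))
  d$synapses <- rbind(d$synapses, synapse_table("c9", "A2", "2", "B", "3"))
  g <- count_matrix(d, list(g = c("A", "A2")), "B")
  expect_equal(g["g", "B"], 3L)
})

test_that("count_matrix equals a brute-force recount on synthetic diagrams", {
  sim <- generate_wiring(wiring_config(
    type_counts = c(ORN = 4, uPN = 4, PickyLN = 2, mPN = 3),
    unpaired = c(mPN = 1), fragment_site_rate = 0.02, seed = 8))
  d <- sim$diagram
  ids <- d$neurons$id[!d$neurons$is_fragment]
  m <- count_matrix(d, ids, ids)
  for (k in seq_len(50)) {
    i <- sample(ids, 1); j <- sample(ids, 1)
    expect_equal(unname(m[i, j]), brute_count(d, i, j))
  }
})

test_that("compartment-restricted counts only see sites on that compartment", {
  # B: chain 1-2-3, axon starts at node 3
  d <- toy_two_neuron()
  d$skeletons$B$tags <- data.frame(node_id = "3", tag = "axon start")
  d$synapses <- synapse_table(
    c("c1", "c2", "c3"), "A", "2", "B", c("2", "3", "3"))
  comps <- compartment_maps(d)
  expect_equal(count_matrix(d, "A", "B", "dendrite", comps)["A", "B"], 1L)
  expect_equal(count_matrix(d, "A", "B", "axon", comps)["A", "B"], 2L)
  expect_equal(count_matrix(d, "A", "B")["A", "B"], 3L)
})

test_that("input fractions divide by the explicit denominator and keep raw counts", {
  d <- toy_two_neuron(n_sites = 45)
  m <- count_matrix(d, "A", "B")
  fr <- input_fractions(m, c(B = 100))
  expect_equal(unclass(fr)["A", "B"], 45)
  expect_equal(attr(fr, "counts")["A", "B"], 45L)
  # full source partition sums to 100
  den <- postsynaptic_totals(d, "B")
  fr2 <- input_fractions(m, den)
  expect_equal(colSums(unclass(fr2))[["B"]], 100)
  # zero denominator drops the column with a warning
  m2 <- cbind(m, Z = 0L); colnames(m2) <- c("B", "Z")
  expect_warning(fr3 <- input_fractions(m2, c(B = 45, Z = 0)), "zero denominator")
  expect_equal(colnames(fr3), "B")
})

test_that("display rounding conventions act on small percentages only", {
  fr <- matrix(c(0.4, 0.6, 45.4, 99.6), nrow = 4,
               dimnames = list(c("a", "b", "c", "d"), "X"))
  floor_style <- render_table(fr, "floor_below_half", totals = FALSE)
  ceil_style <- render_table(fr, "ceil_to_one", totals = FALSE)
  expect_equal(unname(floor_style[, "X"]), c(0L, 1L, 45L, 100L))
  expect_equal(unname(ceil_style[, "X"]), c(1L, 1L, 45L, 100L))
  # totals always from raw values, invariant to style
  t1 <- render_table(fr, "floor_below_half")["total", "X"]
  t2 <- render_table(fr, "ceil_to_one")["total", "X"]
  expect_equal(t1, t2)
  expect_equal(t1, as.integer(round(sum(fr))))
})

test_that("bilateral filter applies the per-side minimum rule", {
  pairs <- data.frame(pair_id = c("A", "B"), cell_type = c("ORN", "uPN"),
                      glomerulus = "g1")
  mk <- function(l, r) {
    d <- mirrored_diagram(pairs,
                          data.frame(source = "A", target = "B", count = l),
                          data.frame(source = "A", target = "B", count = r))
    both <- bilateral_count_matrices(d)
    bilateral_filter(both$left, both$right, min_synapses = 2)
  }
  expect_true(mk(2, 2)$kept)    # at threshold on both sides: kept
  expect_false(mk(5, 1)$kept)   # strong on one side only: dropped
  expect_false(mk(1, 1)$kept)   # below threshold bilaterally: dropped
  # symmetric under swapping sides
  d <- mirrored_diagram(pairs,
                        data.frame(source = "A", target = "B", count = 3),
                        data.frame(source = "A", target = "B", count = 2))
  both <- bilateral_count_matrices(d)
  a <- bilateral_filter(both$left, both$right, 2)
  b <- bilateral_filter(both$right, both$left, 2)
  expect_equal(a$kept, b$kept)
})

test_that("bilateral filter equals the brute-force oracle on random matrices", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    ids <- paste0("p", seq_len(n))
    l <- matrix(rpois(n * n, 2), n, n, dimnames = list(ids, ids))
    r <- matrix(rpois(n * n, 2), n, n, dimnames = list(ids, ids))
    min_s <- sample(1:4, 1)
    kept <- kept_edges(bilateral_filter(l, r, min_s))
    got <- sort(sprintf("%s->%s", kept$source, kept$target))
    expect_identical(got, brute_filter(l, r, min_s))
  }
})

test_that("raising the threshold never adds edges (monotonicity)", {
  set.seed(101)
  ids <- paste0("p", 1:5)
  l <- matrix(rpois(25, 3), 5, 5, dimnames = list(ids, ids))
  r <- matrix(rpois(25, 3), 5, 5, dimnames = list(ids, ids))
  prev <- NULL
  for (min_s in 1:6) {
    kept <- kept_edges(bilateral_filter(l, r, min_s))
    cur <- paste(kept$source, kept$target)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("filter recovers planted ground truth exactly under clean conditions", {
  for (s in 0:19) {
    sim <- generate_wiring(recovery_config(seed = s))
    both <- bilateral_count_matrices(sim$diagram)
    kept <- kept_edges(bilateral_filter(both$left, both$right, 2))
    gt <- sim$ground_truth$edges
    expect_setequal(paste(kept$source, kept$target),
                    paste(gt$source, gt$target))
  }
})

test_that("bilateral input merging sums homologous sources by pair identity", {
  pairs <- data.frame(pair_id = c("X", "M"), cell_type = c("ORN", "mPN"),
                      glomerulus = c("g1", NA))
  d <- mirrored_diagram(pairs, NULL, NULL)
  # target M.L receives 3 sites from X.L and 2 from X.R (bilateral arbor)
  d$synapses <- rbind(
    synapse_table(paste0("l", 1:3), "X.L", "2", "M.L", "2"),
    synapse_table(paste0("r", 1:2), "X.R", "2", "M.L", "2"))
  merged <- merge_bilateral_inputs(d, "M.L")
  expect_equal(unname(merged["X"]), 5L)
  # unilateral target: merging equals the plain column count
  d2 <- mirrored_diagram(pairs,
                         data.frame(source = "X", target = "M", count = 4),
                         NULL)
  expect_equal(unname(merge_bilateral_inputs(d2, "M.L")["X"]), 4L)
  expect_equal(unname(count_matrix(d2, "X.L", "M.L")[1, 1]), 4L)
})

test_that("glomerular grouping adds uPN dendro-dendritic output to the ORN", {
  roster <- neuron_roster(
    id = c("orn", "upn", "m"), cell_type = c("ORN", "uPN", "mPN"),
    side = "left", glomerulus = c("g1", "g1", NA))
  sk <- lapply(c("orn", "upn", "m"), function(id)
    chain_skeleton(id, c(1, 1, 1),
                   tags = data.frame(node_id = "3", tag = "axon start")))
  names(sk) <- c("orn", "upn", "m")
  syn <- rbind(
    synapse_table(paste0("a", 1:5), "orn", "3", "m", "2"),  # ORN: 5 sites
    synapse_table(paste0("b", 1:7), "upn", "2", "m", "2"),  # uPN dendritic: 7
    synapse_table(paste0("c", 1:3), "upn", "4", "m", "2"))  # uPN axonal: excluded
  d <- wiring_diagram(roster, sk, syn)
  g <- glomerular_grouping(d, cols = "m")
  expect_equal(unname(g["g1", "m"]), 12L)
  # missing uPN flagged
  d2 <- d
  d2$neurons$glomerulus[2] <- "other"
  d2$neurons <- rbind(d2$neurons, neuron_roster(
    "orn2", cell_type = "ORN", side = "left", glomerulus = "g2"))
  d2$skeletons$orn2 <- sk$orn
  expect_warning(g2 <- glomerular_grouping(d2, cols = "m"), "without uPN")
  expect_true(all(c("g1", "g2") %in% attr(g2, "missing_upn")))
})

test_that("input fractions track ground-truth expected shares on average", {
  # two sources with lambda 12 and 4 onto one target: expected shares 75/25
  ed <- rbind(
    data.frame(source_type = "ORN", target_type = "mPN", p = 1, lambda = 12,
               post = "dendrite", pre = NA, match_glom = FALSE),
    data.frame(source_type = "PickyLN", target_type = "mPN", p = 1, lambda = 4,
               post = "dendrite", pre = NA, match_glom = FALSE))
  fr_orn <- numeric(0)
  for (s in 0:59) {
    sim <- generate_wiring(wiring_config(
      type_counts = c(ORN = 1, PickyLN = 1, mPN = 1), unpaired = c(mPN = 0),
      edges = ed, fragment_site_rate = 0, seed = s))
    m <- count_matrix(sim$diagram, c("ORN.1a.L", "PickyLN.1.L"), "mPN.1.L")
    fr_orn <- c(fr_orn, 100 * m[1, 1] / sum(m))
  }
  # expected share from zero-truncated Poisson means (~12/16 since lambdas
  # are large enough that truncation barely shifts them)
  expect_equal(mean(fr_orn), 75, tolerance = 0.05)
})
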