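# Pipeline configuration -------------------------------------------------------

#' Pipeline configuration
#'
#' One human-readable configuration drives every stage, so each emitted table
#' records its provenance (seed, thresholds, denominators, rounding) exactly.
#' Thresholds are always explicit: the per-side minimum synapse count, the
#' rounding style and the fraction denominator have no hidden defaults at the
#' table level.
#'
#' @param path optional YAML file to read; fields below override it.
#' @param out_dir output directory.
#' @param seed integer seed recorded in all outputs.
#' @param diagram_dir optional directory with an existing diagram (from
#'   [write_diagram()]); when absent, stages use the diagram simulated into
#'   `out_dir` by the `simulate` stage, generating it if needed.
#' @param min_synapses per-side bilateral-filter threshold (default 2).
#' @param rounding `"floor_below_half"` or `"ceil_to_one"`.
#' @param denominator `"whole-neuron"` or `"dendrite-only"`.
#' @param tuning list of [orn_tuning()] arguments.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, out_dir = "glomwire-out", seed = 1,
                            diagram_dir = NULL, min_synapses = 2,
                            rounding = "floor_below_half",
                            denominator = "whole-neuron", tuning = list()) {
  cfg <- list(out_dir = out_dir, seed = seed, diagram_dir = diagram_dir,
              min_synapses = min_synapses, rounding = rounding,
              denominator = denominator, tuning = tuning)
  if (!is.null(path)) {
    from_file <- yaml::read_yaml(path)
    given <- names(as.list(match.call())[-1])  # args set explicitly
    for (k in intersect(names(from_file), names(cfg))) {
      if (!k %in% given) cfg[[k]] <- from_file[[k]]
    }
  }
  stopifnot(cfg$min_synapses >= 1,
            cfg$rounding %in% c("floor_below_half", "ceil_to_one"),
            cfg$denominator %in% c("whole-neuron", "dendrite-only"))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  core <- unclass(config)
  core$out_dir <- NULL
  yaml::write_yaml(core, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(stage, config, files) {
  yaml::write_yaml(
    list(stage = stage, seed = config$seed, config_hash = config_hash(config),
         files = basename(files)),
    file.path(config$out_dir, stage, "manifest.yaml"))
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# obtain the working diagram: explicit dir > simulated dir > fresh simulation
pipeline_diagram <- function(config) {
  if (!is.null(config$diagram_dir)) return(read_diagram(config$diagram_dir))
  sim_dir <- file.path(config$out_dir, "simulate", "diagram")
  if (dir.exists(sim_dir)) return(read_diagram(sim_dir))
  generate_wiring(wiring_config(seed = config$seed))$diagram
}

# Stages -----------------------------------------------------------------------

stage_validate <- function(config) {
  d <- stage_dir(config, "validate")
  diagram <- pipeline_diagram(config)
  rep <- validate_diagram(diagram)
  f <- file.path(d, "validation.csv")
  utils::write.csv(as.data.frame(rep), f, row.names = FALSE)
  write_manifest("validate", config, f)
  if (nrow(rep)) {
    stop(sprintf("diagram failed validation with %d violation(s); see %s",
                 nrow(rep), f))
  }
  message("validate: diagram well-formed")
  f
}

stage_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  sim <- generate_wiring(wiring_config(seed = config$seed))
  write_diagram(sim$diagram, file.path(d, "diagram"))
  utils::write.csv(sim$ground_truth$edges, file.path(d, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$ground_truth$realized, file.path(d, "realized.csv"),
                   row.names = FALSE)
  resp <- generate_responses(response_config(seed = config$seed))
  write_matrix_csv(resp$responses, file.path(d, "responses.csv"),
                   id_col = "odorant")
  write_matrix_csv(resp$descriptors, file.path(d, "descriptors.csv"),
                   id_col = "odorant")
  utils::write.csv(
    data.frame(odorant = names(resp$odorant_class),
               class = unname(resp$odorant_class)),
    file.path(d, "odorant_classes.csv"), row.names = FALSE)
  files <- list.files(d, recursive = TRUE, full.names = TRUE)
  write_manifest("simulate", config, files)
  message(sprintf("simulate: %d neurons, %d postsynaptic sites",
                  nrow(sim$diagram$neurons), nrow(sim$diagram$synapses)))
  files
}

stage_tables <- function(config) {
  d <- stage_dir(config, "tables")
  diagram <- pipeline_diagram(config)
  both <- bilateral_count_matrices(diagram)
  edges <- bilateral_filter(both$left, both$right,
                            min_synapses = config$min_synapses)
  utils::write.csv(as.data.frame(edges), file.path(d, "edges.csv"),
                   row.names = FALSE)
  compartment <- if (config$denominator == "dendrite-only") "dendrite" else NULL
  right_ids <- diagram$pairing$pairs$right
  counts <- count_matrix(diagram, rows = right_ids, cols = right_ids,
                         compartment = compartment)
  den <- postsynaptic_totals(diagram, right_ids, compartment = compartment)
  keep <- den > 0
  fr <- input_fractions(counts[, keep, drop = FALSE], den,
                        denominator_spec = config$denominator)
  write_matrix_csv(unclass(fr), file.path(d, "fractions_raw.csv"),
                   id_col = "source")
  write_matrix_csv(render_table(fr, style = config$rounding),
                   file.path(d, "fractions_display.csv"), id_col = "source")
  files <- file.path(d, c("edges.csv", "fractions_raw.csv",
                          "fractions_display.csv"))
  write_manifest("tables", config, files)
  message(sprintf("tables: %d of %d connections kept at >=%d synapses per side",
                  sum(edges$kept), nrow(edges), config$min_synapses))
  files
}

stage_morphology <- function(config) {
  d <- stage_dir(config, "morphology")
  diagram <- pipeline_diagram(config)
  comps <- compartment_maps(diagram)
  comp_df <- do.call(rbind, lapply(names(comps), function(id)
    data.frame(skeleton_id = id, node_id = names(comps[[id]]),
               label = unname(comps[[id]]), stringsAsFactors = FALSE)))
  utils::write.csv(comp_df, file.path(d, "compartments.csv"),
                   row.names = FALSE)
  cab <- do.call(rbind, lapply(names(diagram$skeletons), function(id) {
    sk <- diagram$skeletons[[id]]
    data.frame(neuron = id,
               total = cable_length(sk),
               axon = cable_length(sk, "axon", comps[[id]]),
               dendrite = cable_length(sk, "dendrite", comps[[id]]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cab, file.path(d, "cable_lengths.csv"), row.names = FALSE)
  nr <- diagram$neurons
  orns <- nr$id[nr$cell_type == "ORN" & !isTRUE_vec(nr$is_fragment)]
  picky <- nr$id[nr$cell_type == "PickyLN"]
  pol <- polarity_table(diagram, orns, picky, compartments = comps,
                        min_synapses = config$min_synapses)
  utils::write.csv(pol, file.path(d, "polarity_orn_picky.csv"),
                   row.names = FALSE)
  files <- file.path(d, c("compartments.csv", "cable_lengths.csv",
                          "polarity_orn_picky.csv"))
  write_manifest("morphology", config, files)
  message(sprintf("morphology: %.2f mm total cable", sum(cab$total) / 1000))
  files
}

stage_motifs <- function(config) {
  d <- stage_dir(config, "motifs")
  diagram <- pipeline_diagram(config)
  both <- bilateral_count_matrices(diagram)
  kept <- kept_edges(bilateral_filter(both$left, both$right,
                                      min_synapses = config$min_synapses))
  pg <- diagram$pairing$pairs
  ptypes <- stats::setNames(
    diagram$neurons$cell_type[match(pg$left, diagram$neurons$id)], pg$pair_id)
  graph <- circuit_graph_from_kept(kept, ptypes)
  mpns <- names(ptypes)[ptypes == "mPN"]
  census <- do.call(rbind, lapply(mpns, function(m) input_motifs(graph, m)))
  if (is.null(census)) census <- input_motifs(graph, mpns[1])[0, ]
  utils::write.csv(census, file.path(d, "input_motifs.csv"),
                   row.names = FALSE)
  hier <- hierarchy_layers(graph, names(ptypes)[ptypes == "PickyLN"])
  utils::write.csv(
    data.frame(node = names(hier$ranks), rank = unname(hier$ranks),
               out_reach = unname(hier$out_reach[names(hier$ranks)]),
               dominant = names(hier$ranks) %in% hier$dominant),
    file.path(d, "picky_hierarchy.csv"), row.names = FALSE)
  recip <- reciprocal_cores(graph, "BroadLN_Trio", "Keystone",
                            min_weight = config$min_synapses)
  utils::write.csv(recip, file.path(d, "reciprocal_cores.csv"),
                   row.names = FALSE)
  files <- file.path(d, c("input_motifs.csv", "picky_hierarchy.csv",
                          "reciprocal_cores.csv"))
  write_manifest("motifs", config, files)
  message(sprintf("motifs: %d input motifs (%d feedforward loops)",
                  nrow(census), sum(census$motif == "feedforward_loop")))
  files
}

stage_tuning <- function(config) {
  d <- stage_dir(config, "tuning")
  resp_file <- file.path(config$out_dir, "simulate", "responses.csv")
  cls_file <- file.path(config$out_dir, "simulate", "odorant_classes.csv")
  if (file.exists(resp_file)) {
    responses <- read_response_matrix(resp_file)
    cls <- utils::read.csv(cls_file, stringsAsFactors = FALSE)
    odorant_class <- stats::setNames(cls$class, cls$odorant)
  } else {
    resp <- generate_responses(response_config(seed = config$seed))
    responses <- resp$responses
    odorant_class <- resp$odorant_class
  }
  args <- c(list(responses = responses, odorant_class = odorant_class),
            config$tuning)
  model <- do.call(orn_tuning, args)
  utils::write.csv(
    data.frame(odorant = names(model$labels), cluster = unname(model$labels),
               exemplar = rownames(responses)[model$labels]),
    file.path(d, "odorant_clusters.csv"), row.names = FALSE)
  enc <- data.frame(
    cluster = rep(names(model$encoding),
                  vapply(model$encoding, length, integer(1))),
    orn = unlist(model$encoding), row.names = NULL)
  utils::write.csv(enc, file.path(d, "encoding_orns.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(quantity = c("k", "n_clusters", "otsu_threshold"),
               value = c(model$pca$k, length(model$exemplars),
                         model$threshold)),
    file.path(d, "tuning_summary.csv"), row.names = FALSE)
  files <- file.path(d, c("odorant_clusters.csv", "encoding_orns.csv",
                          "tuning_summary.csv"))
  write_manifest("tuning", config, files)
  message(sprintf("tuning: %d clusters, %d components, Otsu threshold %.4f",
                  length(model$exemplars), model$pca$k, model$threshold))
  files
}

#' Run a pipeline stage
#'
#' Stages mirror the analysis: `validate` (structural checks; errors on a
#' malformed diagram), `simulate` (synthetic diagram + response matrix),
#' `tables` (bilateral filtering and input-fraction tables), `morphology`
#' (compartments, cable, polarity), `motifs` (input-motif census, hierarchy,
#' reciprocal cores), `tuning` (odor-tuning cluster model), or `all`. Every
#' stage is deterministic given the config and seed and writes a manifest
#' with the config hash next to its artifacts.
#'
#' @param stage one of the names above.
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return invisibly, the files written.
#' @export
run_stage <- function(stage = c("all", "validate", "simulate", "tables",
                                "morphology", "motifs", "tuning"),
                      config = pipeline_config()) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- pipeline_config(path = config)
  runners <- list(validate = stage_validate, simulate = stage_simulate,
                  tables = stage_tables, morphology = stage_morphology,
                  motifs = stage_motifs, tuning = stage_tuning)
  stages <- if (stage == "all") {
    c("simulate", "validate", "tables", "morphology", "motifs", "tuning")
  } else stage
  files <- unlist(lapply(stages, function(s) runners[[s]](config)))
  invisible(files)
}
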