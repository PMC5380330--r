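# End-to-end orchestration from a single config: normalize -> DEM per
# contrast -> cross-contrast comparison -> genomic clustering of
# co-down/co-up DEM coordinates -> over-representation of cluster
# target genes -> miRNA-target network.  Every run writes a manifest
# (inputs, thresholds, seed, content hashes) and a JSON-lines event
# log; identical config + inputs give byte-identical outputs.

.DEFAULT_THRESHOLDS <- list(alpha = 0.05, fc_up = 2.0, fc_down = 0.5,
                            cluster_gap = 5000, cluster_min_size = 2,
                            enrich_alpha = 0.05, enrich_fdr = 0.05)

#' Load and validate a pipeline config
#'
#' Accepts a YAML file path or an R list.  Fields: `outdir`; `seed`;
#' either `simulate` (arguments for [de_spec()] plus optional
#' `annotation`/`target_db` blocks) or `inputs` (paths `expression`,
#' `flags`, `groups`, `coordinates`, `coordinates_dialect`, `gmt`,
#' `mti`); `contrasts` (list of `(test, reference)` pairs); `thresholds`
#' (defaults: alpha 0.05, fc_up 2, fc_down 0.5, cluster_gap 5000,
#' enrichment alpha/fdr 0.05); optional `stages` subset.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `PipelineConfig`.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) usage_error("config must be a YAML file or a list")
  if (is.null(cfg$outdir)) usage_error("config needs an outdir")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$thresholds <- modifyList(.DEFAULT_THRESHOLDS,
                               as.list(cfg$thresholds))
  if (any(unlist(cfg$thresholds) <= 0))
    usage_error("thresholds must be positive")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    usage_error("config needs a simulate block or an inputs block")
  if (!is.null(cfg$contrasts))
    cfg$contrasts <- lapply(cfg$contrasts, function(x) {
      x <- unlist(x)
      if (length(x) != 2)
        usage_error("each contrast must be a (test, reference) pair")
      as.character(x)
    })
  all_stages <- c("normalize", "dem", "compare", "cluster", "enrich",
                  "network")
  cfg$stages <- if (is.null(cfg$stages)) all_stages
                else match.arg(unlist(cfg$stages), all_stages,
                               several.ok = TRUE)
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

log_event <- function(con, stage, event, ...) {
  rec <- c(list(stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing every output table
#' under `outdir` together with `manifest.json` (config, thresholds,
#' seed, md5 of every output) and `events.jsonl`.  Any stage failure
#' aborts with the stage name and removes partial outputs.  Validation
#' (groups exist, contrasts reference declared groups) happens before
#' any computation.
#'
#' @param config a YAML path or list for [load_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(outdir, written)), add = TRUE)
  log_path <- file.path(outdir, "events.jsonl")
  con <- file(log_path, "w")
  on.exit(close(con), add = TRUE)
  written <- c(written, "events.jsonl")

  emit <- function(name, tab) {
    write_results(setNames(list(tab), name), outdir)
    written <<- c(written, paste0(name, ".tsv"))
  }
  stage <- "load"
  res <- tryCatch({
    # ---- inputs -----------------------------------------------------
    dataset <- NULL; coords <- NULL; collection <- NULL; mti <- NULL
    truth <- NULL
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim_args <- cfg$simulate
      sim_args$seed <- stage_seed(cfg$seed, "simulate")
      ann_args <- sim_args$annotation; sim_args$annotation <- NULL
      db_args <- sim_args$target_db; sim_args$target_db <- NULL
      gen <- generate_expression_dataset(do.call(de_spec, sim_args))
      dataset <- gen$dataset; truth <- gen$truth
      emit("planted_truth", truth)
      if (!is.null(ann_args)) {
        ann_args$seed <- stage_seed(cfg$seed, "annotation")
        coords <- generate_annotation(do.call(cluster_spec, ann_args))
      }
      if (!is.null(db_args)) {
        db_args$seed <- stage_seed(cfg$seed, "target_db")
        db_args$mirnas <- dataset$probe_ids
        db <- do.call(generate_target_db, db_args)
        collection <- db$collection; mti <- db$mti
      }
      log_event(con, "simulate", "done", n_probes = nrow(dataset$intensities))
    } else {
      stage <- "load"
      inp <- cfg$inputs
      if (!is.null(inp$expression))
        dataset <- read_expression_table(inp$expression, inp$flags,
                                         inp$groups)
      if (!is.null(inp$coordinates))
        coords <- read_coordinates(
          inp$coordinates,
          if (is.null(inp$coordinates_dialect)) "table1"
          else inp$coordinates_dialect)
      if (!is.null(inp$gmt)) collection <- read_gmt(inp$gmt)
      if (!is.null(inp$mti)) mti <- read_mti(inp$mti)
      log_event(con, "load", "done")
    }
    # ---- validation before computation ------------------------------
    stage <- "validate"
    contrasts <- cfg$contrasts
    if (!is.null(dataset)) {
      if (is.null(contrasts) && length(unique(dataset$groups)) >= 2) {
        gl <- unique(unname(dataset$groups))
        contrasts <- lapply(gl[-1], function(g) c(g, gl[1]))
      }
      for (ct in contrasts) {
        bad <- setdiff(ct, dataset$groups)
        if (length(bad))
          usage_error(paste("contrast references undeclared group(s):",
                            paste(bad, collapse = ", ")))
      }
    }
    th <- cfg$thresholds
    results <- list()

    # ---- normalize --------------------------------------------------
    if (!is.null(dataset) && "normalize" %in% cfg$stages) {
      stage <- "normalize"
      dataset <- expression_dataset(
        quantile_normalize(dataset$intensities), dataset$flags,
        dataset$groups)
      log_event(con, "normalize", "done")
    }
    # ---- dem per contrast -------------------------------------------
    dems <- list()
    if (!is.null(dataset) && "dem" %in% cfg$stages) {
      stage <- "dem"
      for (ct in contrasts) {
        key <- paste(ct, collapse = "_vs_")
        dems[[key]] <- run_contrast(dataset, ct, alpha = th$alpha,
                                    fc_up = th$fc_up,
                                    fc_down = th$fc_down)
        emit(paste0("dem_", key), as.data.frame(dems[[key]]))
        log_event(con, "dem", "done", contrast = key,
                  n_up = sum(dems[[key]]$call == "up"),
                  n_down = sum(dems[[key]]$call == "down"))
      }
      results$dems <- dems
    }
    # ---- compare ----------------------------------------------------
    co_down <- character(0); co_up <- character(0)
    if (length(dems) >= 2 && "compare" %in% cfg$stages) {
      stage <- "compare"
      cmp <- compare_contrasts(dems[[1]], dems[[2]])
      co_down <- cmp$shared_down; co_up <- cmp$shared_up
      emit("contrast_comparison", cmp$percentages)
      results$comparison <- cmp
      log_event(con, "compare", "done",
                shared_up = length(co_up), shared_down = length(co_down))
    } else if (length(dems) == 1) {
      co_down <- dem_probes(dems[[1]], "down")
      co_up <- dem_probes(dems[[1]], "up")
    }
    # ---- cluster ----------------------------------------------------
    if (!is.null(coords) && "cluster" %in% cfg$stages) {
      stage <- "cluster"
      sel <- coords
      # restrict to co-down DEM loci when the annotation covers them;
      # otherwise cluster the full annotation (standalone geometry)
      if (length(co_down) && any(coords$name %in% co_down))
        sel <- coords[coords$name %in% co_down, , drop = FALSE]
      cl <- cluster_features(sel, max_gap = th$cluster_gap,
                             min_size = th$cluster_min_size)
      emit("clusters", attr(cl, "summary"))
      emit("cluster_members",
           cl[, c("cluster_id", "name", "chromosome", "low", "high")])
      results$clusters <- cl
      log_event(con, "cluster", "done",
                n_clusters = nrow(attr(cl, "summary")))
    }
    # ---- enrich -----------------------------------------------------
    if (!is.null(collection) && !is.null(mti) && "enrich" %in% cfg$stages) {
      stage <- "enrich"
      sel_mirnas <- if (length(co_down)) co_down else unique(mti$mirna)
      targets <- unique(mti$gene[mti$mirna %in% sel_mirnas])
      enr <- enrich_terms(targets, collection,
                          background = unique(mti$gene),
                          alpha = th$enrich_alpha, fdr = th$enrich_fdr)
      emit("enrichment", as.data.frame(enr))
      results$enrichment <- enr
      log_event(con, "enrich", "done",
                n_significant = sum(enr$significant))
    }
    # ---- network ----------------------------------------------------
    if (!is.null(mti) && "network" %in% cfg$stages) {
      stage <- "network"
      sel_mirnas <- if (length(c(co_down, co_up))) c(co_down, co_up)
                    else unique(mti$mirna)
      gene_universe <- if (!is.null(collection))
        unique(unlist(collection$sets, use.names = FALSE))
      else unique(mti$gene)
      edges <- filter_mti(mti, sel_mirnas, gene_universe)
      status <- setNames(rep("other", length(sel_mirnas)), sel_mirnas)
      status[names(status) %in% co_down] <- "co_down"
      status[names(status) %in% co_up] <- "co_up"
      net <- build_network(edges, mirna_annotations = status)
      rank <- mirna_degree_ranking(net)
      classes <- classify_genes_by_regulators(net, co_down, co_up)
      emit("network_edges", net$edges)
      emit("mirna_degree", rank)
      emit("gene_classes",
           data.frame(gene = names(classes), class = unname(classes)))
      export_network(net, file.path(outdir, "network.sif"), "sif")
      export_network(net, file.path(outdir, "network.graphml"), "graphml")
      written <- c(written, "network.sif", "network.graphml")
      results$network <- net
      log_event(con, "network", "done", n_edges = nrow(net$edges))
    }
    results
  }, error = function(e) {
    # partial outputs are removed by the on.exit handler (ok == FALSE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  # ---- manifest -----------------------------------------------------
  flush(con)
  files <- setdiff(sort(written), "events.jsonl")
  hashes <- as.list(tools::md5sum(file.path(outdir, files)))
  names(hashes) <- files
  manifest <- list(package = "cikmir",
                   version = as.character(utils::packageVersion("cikmir")),
                   seed = cfg$seed,
                   thresholds = cfg$thresholds,
                   stages = cfg$stages,
                   inputs = if (is.null(cfg$inputs)) "simulated"
                            else cfg$inputs,
                   output_md5 = hashes)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(c(res, list(manifest = manifest)))
}
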