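# End-to-end orchestration: load -> filter/aggregate -> classify ->
# similarity transfer / PPI expansion -> networks & enrichment ->
# expression arm -> run manifest.

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full drug-food interaction pipeline
#'
#' Stage order: load tables, filter and aggregate measurements, classify
#' food-compound activity, chemical-similarity target transfer with PPI
#' expansion and ortholog mapping (when structures and reference compounds
#' are available), food/target networks and biological-system enrichment,
#' then the expression arm (differential expression, tag lists,
#' connectivity) when expression inputs are present. Partial inputs run the
#' chemistry arm alone. All randomness flows from the config seed. A run
#' manifest (config snapshot, input digests, per-stage row counts, output
#' digests, seed, package version) is written as `manifest.json`; re-running
#' on identical inputs with the same seed reproduces identical outputs.
#'
#' @param inputDir directory of canonical input TSVs (see [loadTables()]).
#' @param outDir output directory, created if needed.
#' @param config a [DfiConfig-class].
#' @param nPerm permutations for connectivity scoring (default config
#'   `n_permutations`).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(inputDir, outDir, config = dfiConfig(),
                        nPerm = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stage <- "load"
  res <- list()
  tryCatch({
    reg <- loadTables(inputDir, config)
    res$registry <- reg

    stage <- "filter/aggregate"
    flagged <- filterMeasurements(reg, config)
    interactions <- aggregateInteractions(flagged, config)
    .writeTsv(interactions, file.path(outDir, "interactions.tsv"))

    stage <- "classify"
    foodCompounds <- unique(reg@foods$compound_id)
    foodInter <- interactions[interactions$compound_id %in% foodCompounds, ,
                              drop = FALSE]
    calls <- classifyActivity(foodInter, reg, config)
    .writeTsv(calls, file.path(outDir, "calls.tsv"))
    res$interactions <- interactions
    res$calls <- calls

    stage <- "chemspace"
    refIds <- reg@compounds$compound_id[
      reg@compounds$origin == "reference_bioactive"]
    inferred <- NULL
    if (length(refIds) && any(nzchar(reg@compounds$smiles))) {
      qTab <- reg@compounds[reg@compounds$origin == "food", , drop = FALSE]
      rTab <- reg@compounds[reg@compounds$origin == "reference_bioactive", ,
                            drop = FALSE]
      qd <- computeDescriptors(qTab, config)
      rd <- computeDescriptors(rTab, config)
      matches <- matchCompounds(qd, rd, config)
      refInter <- interactions[interactions$compound_id %in% refIds, ,
                               drop = FALSE]
      inferred <- transferTargets(matches, refInter)
      inferred <- expandViaPPI(inferred, reg, config)
      if (nrow(inferred)) {
        sp <- reg@proteins$species[match(inferred$protein_id,
                                         reg@proteins$protein_id)]
        mapped <- mapOrthologs(inferred$protein_id, sp, reg@orthologs)
        inferred <- merge(inferred, mapped,
                          by.x = "protein_id", by.y = "input_id")
        names(inferred)[names(inferred) == "human_id"] <- "human_protein_id"
        inferred$species <- NULL
      }
      .writeTsv(inferred, file.path(outDir, "inferred_links.tsv"))
      res$inferred <- inferred
    }

    stage <- "networks"
    profile <- foodProteinProfile(calls, reg)
    .writeTsv(profile, file.path(outDir, "food_profile.tsv"))
    foodNet <- buildFoodNetwork(calls, reg)
    writeNetwork(foodNet, file.path(outDir, "food_network"))
    res$foodNetwork <- foodNet
    classes <- sort(unique(unlist(splitSet(
      reg@proteins$disease_classes[reg@proteins$category == "drug_target"]))))
    targetNets <- list()
    for (cl in classes) {
      tn <- buildTargetNetwork(calls, reg, cl, config)
      writeNetwork(tn, file.path(outDir, paste0("target_network_", cl)))
      targetNets[[cl]] <- tn
    }
    res$targetNetworks <- targetNets

    stage <- "enrichment"
    prt <- reg@proteins
    dt <- prt[prt$category == "drug_target", , drop = FALSE]
    if (nrow(dt)) {
      affected <- unique(calls$protein_id[calls$is_active])
      systems <- sort(unique(dt$biological_system))
      inputs <- data.frame(
        category = systems,
        tpc = vapply(systems, function(s)
          sum(dt$biological_system == s), integer(1)),
        observed = vapply(systems, function(s)
          sum(dt$biological_system == s & dt$protein_id %in% affected),
          integer(1)),
        stringsAsFactors = FALSE)
      enr <- categoryEnrichment(inputs, tdt = nrow(dt),
                                tpa = sum(dt$protein_id %in% affected))
      .writeTsv(enr, file.path(outDir, "enrichment.tsv"))
      res$enrichment <- enr
    }

    stage <- "expression"
    conn <- NULL
    if (nrow(reg@expression)) {
      deAll <- list(); connAll <- list()
      for (f in unique(reg@groups$food_id)) {
        gs <- reg@groups[reg@groups$food_id == f, , drop = FALSE]
        mat <- reg@expression[, gs$sample_id, drop = FALSE]
        de <- differentialExpression(mat, gs, config)
        .writeTsv(de, file.path(outDir, paste0("de_", f, ".tsv")))
        deAll[[f]] <- de
        if (nrow(reg@referenceRanks)) {
          tags <- tryCatch(
            buildTagLists(de, cap = dfiParam(config, "tag_list_cap")),
            error = function(e) NULL)
          if (!is.null(tags)) {
            cs <- connectivityScore(tags, reg@referenceRanks,
                                    reg@instances, config, nPerm = nPerm)
            connAll[[f]] <- cbind(food_id = f, cs)
          }
        }
      }
      res$de <- deAll
      if (length(connAll)) {
        connRes <- do.call(rbind, connAll)
        rownames(connRes) <- NULL
        drugCls <- unique(reg@drugs[, c("drug_id", "disease_classes")])
        names(drugCls) <- c("reference_id", "disease_classes")
        conn <- classifyConnections(connRes, drugCls)
        .writeTsv(connRes, file.path(outDir, "connectivity.tsv"))
        .writeTsv(conn$edges, file.path(outDir, "connectivity_edges.tsv"))
        res$connectivity <- connRes
        res$connectivityEdges <- conn$edges
      }
    }

    stage <- "manifest"
    inputFiles <- list.files(inputDir, pattern = "\\.tsv$",
                             full.names = TRUE)
    outFiles <- setdiff(list.files(outDir, full.names = TRUE),
                        file.path(outDir, "manifest.json"))
    manifest <- list(
      tool = "dfinet",
      version = as.character(utils::packageVersion("dfinet")),
      seed = dfiSeed(config),
      config = config@params,
      input_digests = as.list(tools::md5sum(sort(inputFiles))),
      output_digests = as.list(tools::md5sum(sort(outFiles))),
      counts = list(
        compounds = nrow(reg@compounds),
        measurements = nrow(reg@measurements),
        confident_interactions = nrow(interactions),
        active_calls = sum(calls$is_active),
        inferred_links = rowsDf(inferred),
        food_network_nodes = nrow(networkNodes(foodNet)),
        food_network_edges = nrow(networkEdges(foodNet)),
        de_genes = if (!is.null(res$de))
          sum(vapply(res$de, function(d) sum(d$direction != "ns"),
                     numeric(1))) else 0,
        connectivity_edges = if (!is.null(conn)) nrow(conn$edges) else 0))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  dfiLog("pipeline complete: ", outDir)
  invisible(res)
}
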