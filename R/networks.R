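# Food-food, target-target and tripartite networks, plus biological-system
# enrichment.

.foodProteinSets <- function(calls, registry) {
  act <- calls[calls$is_active, , drop = FALSE]
  m <- merge(registry@foods, act, by = "compound_id")
  split(m$protein_id, m$food_id)
}

#' Build the food-food shared-protein network
#'
#' Nodes are foods annotated with their number of bioactive phytochemicals
#' and interacting proteins; an edge connects two foods with the number of
#' interacting proteins they share (set-intersection cardinality; no edge
#' when disjoint, no self-edges). Node and edge ordering is deterministic.
#'
#' @param calls activity calls from [classifyActivity()].
#' @param registry a [DfiRegistry-class].
#' @return A [FoodNetwork-class].
#' @export
buildFoodNetwork <- function(calls, registry) {
  profile <- foodProteinProfile(calls, registry)
  nodes <- profile[order(profile$food_id, method = "radix"),
                   c("food_id", "n_bioactive_compounds",
                     "n_interacting_proteins")]
  rownames(nodes) <- NULL
  sets <- lapply(.foodProteinSets(calls, registry), unique)
  ids <- sort(names(sets))
  edges <- emptyDf(from = "character", to = "character", weight = "integer",
                   shared_proteins = "character")
  if (length(ids) >= 2L) {
    res <- list()
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      sh <- intersect(sets[[ids[i]]], sets[[ids[j]]])
      if (length(sh) == 0L) next
      res[[length(res) + 1L]] <- data.frame(
        from = ids[i], to = ids[j], weight = length(sh),
        shared_proteins = paste(sort(sh), collapse = "|"),
        stringsAsFactors = FALSE)
    }
    if (length(res)) edges <- do.call(rbind, res)
  }
  rownames(edges) <- NULL
  new("FoodNetwork", nodes = nodes, edges = edges)
}

# (drug, food) pairs with biological activity against a target: the drug
# targets the protein and the food holds >= 1 active phytochemical on it.
# Counted once per (drug, food) pair regardless of how many phytochemicals
# mediate it.
.targetPairSets <- function(targets, calls, registry) {
  act <- calls[calls$is_active, , drop = FALSE]
  foodsOf <- merge(registry@foods, act, by = "compound_id")
  drg <- registry@drugs[registry@drugs$role == "target", , drop = FALSE]
  sets <- list()
  for (t in targets) {
    ds <- unique(drg$drug_id[drg$protein_id == t])
    fs <- unique(foodsOf$food_id[foodsOf$protein_id == t])
    sets[[t]] <- if (length(ds) && length(fs))
      as.vector(outer(ds, fs, paste, sep = "\r")) else character(0)
  }
  sets
}

#' Build a per-disease target-target network
#'
#' Restricted to drug targets annotated with the given disease class (human
#' disease ontology level 3). Two targets are connected when they share at
#' least `shared_pair_min` (default 3) drug-food pairs with biological
#' activity against both proteins. The number of targets of the class
#' affected by food is stored in the `nTargetsAffected` slot.
#'
#' @param calls activity calls from [classifyActivity()].
#' @param registry a [DfiRegistry-class].
#' @param diseaseClass disease class label.
#' @param config a [DfiConfig-class].
#' @return A [TargetNetwork-class].
#' @export
buildTargetNetwork <- function(calls, registry, diseaseClass,
                               config = dfiConfig()) {
  prt <- registry@proteins
  inClass <- vapply(splitSet(prt$disease_classes),
                    function(s) diseaseClass %in% s, logical(1))
  targets <- sort(prt$protein_id[prt$category == "drug_target" & inClass])
  if (length(targets) == 0L)
    warnf("no drug target annotated with disease class '%s'", diseaseClass)
  sets <- .targetPairSets(targets, calls, registry)
  nPairs <- vapply(sets, length, integer(1))
  act <- calls[calls$is_active, , drop = FALSE]
  affected <- intersect(targets, act$protein_id)
  nodes <- data.frame(protein_id = targets,
                      protein_name = prt$protein_name[match(targets,
                                                            prt$protein_id)],
                      n_drug_food_pairs = as.integer(nPairs),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- emptyDf(from = "character", to = "character", weight = "integer")
  minShared <- dfiParam(config, "shared_pair_min")
  if (length(targets) >= 2L) {
    res <- list()
    for (i in seq_len(length(targets) - 1L))
      for (j in (i + 1L):length(targets)) {
        w <- length(intersect(sets[[targets[i]]], sets[[targets[j]]]))
        if (w >= minShared)
          res[[length(res) + 1L]] <- data.frame(
            from = targets[i], to = targets[j], weight = w,
            stringsAsFactors = FALSE)
      }
    if (length(res)) edges <- do.call(rbind, res)
  }
  rownames(edges) <- NULL
  new("TargetNetwork", nodes = nodes, edges = edges,
      diseaseClass = diseaseClass, nTargetsAffected = length(affected))
}

#' Keep each node's k heaviest edges
#'
#' Display-layer reduction: for every node its `k` heaviest incident edges
#' are marked, and an edge survives if it is top-k for either endpoint. Ties
#' are broken by weight descending, then the lexical `from|to` edge key.
#' Idempotent; never used to compute statistics.
#'
#' @param x a [FoodNetwork-class] or [TargetNetwork-class].
#' @param k number of edges kept per node (default config
#'   `top_edges_shown` = 5).
#' @param ... unused.
#' @return The same class of network with the reduced edge set.
#' @export
setMethod("topKEdges", "FoodNetwork", function(x, k = 5, ...) {
  x@edges <- .topK(x@edges, k); x
})

#' @rdname topKEdges
#' @export
setMethod("topKEdges", "TargetNetwork", function(x, k = 5, ...) {
  x@edges <- .topK(x@edges, k); x
})

.topK <- function(edges, k) {
  if (nrow(edges) <= 1L) return(edges)
  key <- paste(edges$from, edges$to, sep = "|")
  keep <- rep(FALSE, nrow(edges))
  for (node in unique(c(edges$from, edges$to))) {
    inc <- which(edges$from == node | edges$to == node)
    ord <- inc[order(-edges$weight[inc], key[inc], method = "radix")]
    keep[utils::head(ord, k)] <- TRUE
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a protein with its strongest-binding phytochemical
#'
#' Among the active food compounds on the protein (in the stated role
#' context), selects the one with the minimal representative affinity, i.e.
#' the highest binding activity. Reports the foods containing that compound
#' and the drugs linked to the protein in the matching role. In the
#' pharmacodynamics context (`role = "pd"`) only `drug_target` records are
#' considered; in the pharmacokinetics context (`role = "pk"`) enzyme,
#' transporter and carrier records. `protein` may be a protein id or a
#' protein name (a name may resolve to several records, e.g. one per
#' category; the role context disambiguates).
#'
#' @param calls activity calls from [classifyActivity()] (carrying
#'   `representative_affinity`).
#' @param registry a [DfiRegistry-class].
#' @param protein protein id or protein name.
#' @param role `"pd"` or `"pk"`.
#' @param interactions optional confident interactions (from
#'   [aggregateInteractions()]) used to recover the endpoint of the best
#'   binder.
#' @param topN optional display truncation of the food and drug lists
#'   (e.g. 3); never affects the selected binder.
#' @return One-row data.frame: `protein_id`, `protein_name`,
#'   `best_compound`, `best_affinity_nm`, `endpoint`, `foods`, `drugs`
#'   ("|"-separated), or NULL (with a warning) when no active phytochemical
#'   exists in the context.
#' @examples
#' reg <- inPaperFixture()
#' calls <- classifyActivity(
#'   aggregateInteractions(filterMeasurements(reg)), reg)
#' annotateStrongestBinder(calls, reg, "aromatase", role = "pd")
#' @export
annotateStrongestBinder <- function(calls, registry, protein,
                                    role = c("pd", "pk"),
                                    interactions = NULL, topN = NULL) {
  role <- match.arg(role)
  prt <- registry@proteins
  cats <- if (role == "pd") "drug_target" else
    c("enzyme", "transporter", "carrier")
  rec <- prt[(prt$protein_id == protein | prt$protein_name == protein) &
               prt$category %in% cats, , drop = FALSE]
  if (nrow(rec) == 0L) {
    warnf("no %s-context protein record matches '%s'", role, protein)
    return(NULL)
  }
  foodCompounds <- unique(registry@foods$compound_id)
  cand <- calls[calls$is_active & calls$protein_id %in% rec$protein_id &
                  calls$compound_id %in% foodCompounds &
                  !is.na(calls$representative_affinity), , drop = FALSE]
  if (nrow(cand) == 0L) {
    warnf("no active phytochemical with affinity on '%s' (%s context)",
          protein, role)
    return(NULL)
  }
  best <- cand[order(cand$representative_affinity, cand$compound_id,
                     method = "radix")[1L], ]
  endpoint <- NA_character_
  if (!is.null(interactions)) {
    mix <- interactions$endpoint_mix[
      interactions$compound_id == best$compound_id &
        interactions$protein_id == best$protein_id]
    if (length(mix)) endpoint <- strsplit(mix[1L], "|", fixed = TRUE)[[1L]][1L]
  }
  fds <- sort(unique(registry@foods$food_id[
    registry@foods$compound_id == best$compound_id]))
  role2 <- if (role == "pd") "target" else
    c("enzyme", "transporter", "carrier")
  drg <- registry@drugs
  ds <- sort(unique(drg$drug_id[drg$protein_id %in% rec$protein_id &
                                  drg$role %in% role2]))
  if (!is.null(topN)) {
    fds <- utils::head(fds, topN)
    ds <- utils::head(ds, topN)
  }
  data.frame(protein_id = best$protein_id,
             protein_name = rec$protein_name[match(best$protein_id,
                                                   rec$protein_id)],
             best_compound = best$compound_id,
             best_affinity_nm = best$representative_affinity,
             endpoint = endpoint,
             foods = paste(fds, collapse = "|"),
             drugs = paste(ds, collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Biological-system enrichment of food-affected drug targets
#'
#' For each biological category the expected number of food-affected targets
#' is `exp = (tpc / tdt) * tpa`, where `tpc` is the number of drug targets
#' in the category, `tdt` the total number of drug targets, and `tpa` the
#' number of drug targets participating in food interactions. Significance
#' is assessed two ways and both are reported: a one-sample Student t-test
#' over the per-category observed/expected ratios (the published test,
#' statistically unusual for categorical data but implemented as stated)
#' and an exact binomial test per category (observed successes in `tpa`
#' draws at probability `tpc/tdt`).
#'
#' @param inputs data.frame with columns `category`, `tpc` (targets in
#'   category) and `observed` (food-affected targets in category).
#' @param tdt total number of drug targets across categories.
#' @param tpa total number of drug targets participating in food
#'   interactions.
#' @param alpha significance level for the per-category flag (default
#'   0.05).
#' @return data.frame per category: `expected`, `observed`, `ratio`,
#'   `binom_p`, `significant`; the t-test over ratios is attached as
#'   attribute `t_test` (list with `statistic`, `p_value`).
#' @examples
#' categoryEnrichment(
#'   data.frame(category = "signal_transduction", tpc = 100, observed = 25),
#'   tdt = 1806, tpa = 186)
#' @export
categoryEnrichment <- function(inputs, tdt, tpa, alpha = 0.05) {
  if (tdt <= 0) stopf("tdt must be positive")
  stopifnot(all(inputs$tpc >= 0), all(inputs$tpc <= tdt), tpa >= 0,
            tpa <= tdt)
  out <- data.frame(category = inputs$category, tpc = inputs$tpc,
                    observed = inputs$observed,
                    expected = inputs$tpc / tdt * tpa,
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out$binom_p <- vapply(seq_len(nrow(out)), function(i) {
    if (out$tpc[i] == 0) return(NA_real_)
    stats::binom.test(out$observed[i], tpa,
                      p = out$tpc[i] / tdt)$p.value
  }, numeric(1))
  out$significant <- !is.na(out$binom_p) & out$binom_p < alpha
  tt <- list(statistic = NA_real_, p_value = NA_real_)
  r <- out$ratio[!is.na(out$ratio)]
  if (length(r) >= 2L && stats::sd(r) > 0) {
    t0 <- stats::t.test(r, mu = 1)
    tt <- list(statistic = unname(t0$statistic), p_value = t0$p.value)
  }
  attr(out, "t_test") <- tt
  out
}

#' Export a network as edge-list TSV, node TSV and GraphML
#'
#' GraphML carries all node and edge attributes; an optional display
#' truncation to the top-k edges per node can be applied to the exported
#' copy only.
#'
#' @param network a [FoodNetwork-class] or [TargetNetwork-class].
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @param topK optional `k` passed to [topKEdges()] for the display copy.
#' @return Invisibly, the vector of files written.
#' @export
writeNetwork <- function(network, prefix, topK = NULL) {
  disp <- if (is.null(topK)) network else topKEdges(network, topK)
  files <- paste0(prefix, c("_nodes.tsv", "_edges.tsv", ".graphml"))
  utils::write.table(networkNodes(disp), files[1L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(networkEdges(disp), files[2L], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  g <- asIgraph(disp)
  igraph::write_graph(g, files[3L], format = "graphml")
  invisible(files)
}
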