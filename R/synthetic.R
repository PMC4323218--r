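# Synthetic data with planted ground truth. The generator emulates the
# shapes of the source databases (food-compound tables, bioassay
# measurements, drug-protein links, PPI edges, ortholog maps, expression
# matrices, reference rank profiles) at desk scale, with every planted
# signal recorded so any stage's output can be scored without re-running
# the generator.

.scaffolds <- c("c1ccc(%s)cc1", "C1CCC(%s)CC1", "c1ccnc(%s)c1",
                "C1CC(%s)C1")
.refScaffold <- "c1ccc2cc(%s)ccc2c1"  # reserved for reference bioactives so
                                      # pool structures never collide
.terminals <- c("O", "N", "C(=O)O", "OC", "C(=O)N", "F")

# Deterministic structure pool: scaffold x chain length x terminal group.
# Chain-homolog "twins" (length L vs L+1 on the same scaffold/terminal)
# share every circular environment of radius 2 along the chain, so their
# folded fingerprints satisfy TC >= 0.85 by construction.
.structurePool <- function(n, minChain = 2L, maxChain = 20L) {
  grid <- expand.grid(chain = seq(minChain, maxChain, by = 3L),
                      term = .terminals, scaf = .scaffolds,
                      stringsAsFactors = FALSE)
  if (nrow(grid) < n)
    grid <- expand.grid(chain = minChain:maxChain, term = .terminals,
                        scaf = .scaffolds, stringsAsFactors = FALSE)
  if (nrow(grid) < n) stopf("structure pool exhausted (need %d)", n)
  smi <- sprintf(grid$scaf, paste0(strrep("C", grid$chain), grid$term))
  unique(smi)[seq_len(n)]
}

.twinOf <- function(smiles) {
  # one extra chain carbon right after the scaffold attachment point
  sub("\\((C+)", "(C\\1", smiles)
}

.logUnif <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

.defaultChemParams <- function() list(
  frac_in_range   = 0.5,   # planted share of food compounds inside drug range
  n_replicates    = 3L,    # measurements per compound-protein pair
  flip_rate       = 0,     # per-replicate probability of a negative assay
  affinity_sigma  = 0.03,  # log10 noise on replicate affinities
  n_twins         = 4L,    # similarity-twin query/reference pairs
  drug_affinity_lo = 5,    # nM; drug activity window (kept below the
  drug_affinity_hi = 80,   # pchembl cutoff so out-of-range plants still
                           # yield positive measurements)
  out_range_lo_x  = 3,     # out-of-range plants start at 3x the weakest drug
  out_range_hi    = 700,   # nM; ceiling keeping pchembl > 6 with margin for
                           # replicate jitter at the rounding boundary
  frac_rodent     = 0.15,  # proteins assigned to rat/mouse
  ortholog_cover  = 0.9,   # rodent proteins with a human ortholog row
  n_ppi_edges     = 40L
)

.diseaseVocab <- c("cancer", "neurological", "cardiovascular", "metabolic",
                   "infectious", "immunological")
.systemVocab <- c("signal_transduction", "immune_system", "metabolism",
                  "developmental_biology", "neuronal_system")

#' Generate a synthetic chemistry-side dataset with planted ground truth
#'
#' Emulates every chemistry-side input table: foods, compounds (with
#' parseable SMILES), proteins (categories, disease classes, biological
#' systems, species), drug-protein links, replicated bioassay measurements,
#' PPI edges and ortholog rows. Drug affinities are drawn log-uniformly
#' over a stated window; food-compound affinities are planted inside or
#' outside the per-protein drug range; replicate measurements are flipped
#' negative at a stated rate so the positive-frequency rule is exercised;
#' twin compound pairs (chain homologs, Tanimoto >= 0.85 by construction)
#' exercise similarity transfer.
#'
#' @param seed integer seed; fixed seed gives byte-identical tables.
#' @param nFoods,nCompounds,nProteins,nDrugs dataset dimensions.
#' @param params named list overriding the generator defaults (see source:
#'   `frac_in_range`, `n_replicates`, `flip_rate`, `affinity_sigma`,
#'   `n_twins`, `drug_affinity_lo`/`_hi`, `out_range_lo_x`, `out_range_hi`,
#'   `frac_rodent`, `ortholog_cover`, `n_ppi_edges`).
#' @return list: `registry` (a validated [DfiRegistry-class]) and `truth`
#'   (planted actives, food ranking, target-network pair counts, twins,
#'   seed, params).
#' @export
genChemistry <- function(seed, nFoods = 15L, nCompounds = 60L,
                         nProteins = 25L, nDrugs = 20L, params = list()) {
  p <- utils::modifyList(.defaultChemParams(), params)
  if (p$n_twins > 0 && nCompounds <= 0)
    stopf("twins requested with no compounds")
  set.seed(seed)

  ## proteins ---------------------------------------------------------------
  pid <- sprintf("P%03d", seq_len(nProteins))
  cat <- sample(c(rep("drug_target", ceiling(nProteins * 0.7)),
                  sample(c("enzyme", "transporter", "carrier"),
                         nProteins - ceiling(nProteins * 0.7),
                         replace = TRUE)))
  species <- sample(c("human", "rat", "mouse"), nProteins, replace = TRUE,
                    prob = c(1 - p$frac_rodent, p$frac_rodent / 2,
                             p$frac_rodent / 2))
  disease <- vapply(seq_len(nProteins), function(i)
    if (cat[i] == "drug_target")
      paste(sort(sample(.diseaseVocab, sample(1:2, 1))), collapse = "|")
    else "", character(1))
  proteins <- data.frame(
    protein_id = pid, protein_name = tolower(pid), category = cat,
    disease_classes = disease,
    biological_system = sample(.systemVocab, nProteins, replace = TRUE),
    species = species, stringsAsFactors = FALSE)

  ## compounds --------------------------------------------------------------
  nRef <- p$n_twins
  smiles <- .structurePool(nCompounds + nDrugs)
  cidFood <- sprintf("FC%03d", seq_len(nCompounds))
  cidDrug <- sprintf("DC%03d", seq_len(nDrugs))
  cidRef <- if (nRef) sprintf("RC%03d", seq_len(nRef)) else character(0)
  # long chains keep the homolog twin's folded-fingerprint TC at >= 0.85;
  # the terminal varies fastest so a twin (one extra chain carbon) never
  # coincides with another reference structure
  refSmiles <- if (nRef) sprintf(
    .refScaffold, paste0(strrep("C", 8L + (seq_len(nRef) - 1L) %/% 6L),
                         .terminals[1L + (seq_len(nRef) - 1L) %% 6L]))
  else character(0)
  # twins: the first n_twins food compounds are chain homologs of the
  # reference compounds
  foodSmiles <- smiles[seq_len(nCompounds)]
  if (nRef) foodSmiles[seq_len(nRef)] <- vapply(refSmiles, .twinOf,
                                                character(1))
  compounds <- data.frame(
    compound_id = c(cidFood, cidDrug, cidRef),
    smiles = c(foodSmiles, smiles[nCompounds + seq_len(nDrugs)], refSmiles),
    mw = NA_real_,
    names = c(cidFood, cidDrug, cidRef),
    origin = c(rep("food", nCompounds), rep("drug", nDrugs),
               rep("reference_bioactive", nRef)),
    stringsAsFactors = FALSE)

  ## drugs and drug measurements -------------------------------------------
  role2cat <- c(drug_target = "target", enzyme = "enzyme",
                transporter = "transporter", carrier = "carrier")
  did <- sprintf("D%03d", seq_len(nDrugs))
  drugRows <- list(); msRows <- list(); baseRows <- list()
  targetsOfDrug <- vector("list", nDrugs)
  for (i in seq_len(nDrugs)) {
    nl <- sample(1:3, 1)
    prots <- sample(pid, nl)
    targetsOfDrug[[i]] <- prots
    dclasses <- unique(unlist(splitSet(
      proteins$disease_classes[match(prots, pid)])))
    drugRows[[i]] <- data.frame(
      drug_id = did[i], compound_id = cidDrug[i], protein_id = prots,
      role = role2cat[proteins$category[match(prots, pid)]],
      disease_classes = paste(sort(dclasses), collapse = "|"),
      stringsAsFactors = FALSE)
    aff <- .logUnif(nl, p$drug_affinity_lo, p$drug_affinity_hi)
    for (j in seq_len(nl)) {
      v <- aff[j] * 10^stats::rnorm(p$n_replicates, 0, p$affinity_sigma)
      msRows[[length(msRows) + 1L]] <- data.frame(
        compound_id = cidDrug[i], protein_id = prots[j],
        endpoint = sample(c("Ki", "IC50"), 1), value = v, units = "nM",
        pchembl = round(9 - log10(v), 2), stringsAsFactors = FALSE)
      baseRows[[length(baseRows) + 1L]] <- data.frame(
        drug_id = did[i], protein_id = prots[j], base = aff[j],
        stringsAsFactors = FALSE)
    }
  }
  drugs <- do.call(rbind, drugRows)
  drugBase <- do.call(rbind, baseRows)

  ## food compound plants ---------------------------------------------------
  # only proteins with drug affinity data host planted calls, so every call
  # uses the drug-range branch and the plant is unambiguous
  hostable <- unique(drugs$protein_id)
  planted <- list()
  for (i in seq_len(nCompounds)) {
    prots <- sample(hostable, min(length(hostable), sample(1:2, 1)))
    inRange <- stats::runif(length(prots)) < p$frac_in_range
    for (j in seq_along(prots)) {
      # the per-drug base affinities bound what the classifier will see as
      # the drug range (jitter is symmetric around them)
      vals <- drugBase$base[drugBase$protein_id == prots[j]]
      lo <- min(vals); hi <- max(vals)
      # margin keeps replicate jitter from pushing an in-range plant across
      # the range boundary (6 sd of the geometric-mean difference)
      margin <- 10^(6 * p$affinity_sigma / sqrt(p$n_replicates))
      aff <- if (inRange[j]) .logUnif(1, lo, hi) / margin else
        .logUnif(1, hi * p$out_range_lo_x, max(hi * p$out_range_lo_x + 1,
                                               p$out_range_hi))
      flips <- stats::runif(p$n_replicates) < p$flip_rate
      v <- aff * 10^stats::rnorm(p$n_replicates, 0, p$affinity_sigma)
      pch <- round(9 - log10(v), 2)
      v[flips] <- 1e4; pch[flips] <- 5
      msRows[[length(msRows) + 1L]] <- data.frame(
        compound_id = cidFood[i], protein_id = prots[j],
        endpoint = "IC50", value = v, units = "nM", pchembl = pch,
        stringsAsFactors = FALSE)
      planted[[length(planted) + 1L]] <- data.frame(
        compound_id = cidFood[i], protein_id = prots[j],
        in_range = inRange[j], affinity = aff, n_flipped = sum(flips),
        stringsAsFactors = FALSE)
    }
  }
  plantedDf <- do.call(rbind, planted)

  ## reference bioactive interactions (for similarity transfer) -------------
  twinTruth <- NULL
  if (nRef) {
    twinProts <- lapply(seq_len(nRef), function(i)
      sample(pid, sample(1:3, 1)))
    for (i in seq_len(nRef)) {
      aff <- .logUnif(length(twinProts[[i]]), 10, 500)
      for (j in seq_along(twinProts[[i]]))
        msRows[[length(msRows) + 1L]] <- data.frame(
          compound_id = cidRef[i], protein_id = twinProts[[i]][j],
          endpoint = "Ki",
          value = aff[j] * 10^stats::rnorm(p$n_replicates, 0,
                                           p$affinity_sigma),
          units = "nM",
          pchembl = round(9 - log10(aff[j]), 2), stringsAsFactors = FALSE)
    }
    twinTruth <- data.frame(
      query_compound_id = cidFood[seq_len(nRef)],
      reference_compound_id = cidRef,
      planted_targets = vapply(twinProts, function(x)
        paste(sort(x), collapse = "|"), character(1)),
      stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, msRows)

  ## food memberships with a planted top food -------------------------------
  fid <- sprintf("F%02d", seq_len(nFoods))
  member <- data.frame(
    food_id = sample(fid, nCompounds, replace = TRUE),
    compound_id = cidFood, stringsAsFactors = FALSE)
  uncovered <- setdiff(fid, member$food_id)
  if (length(uncovered))
    member <- rbind(member, data.frame(
      food_id = uncovered,
      compound_id = sample(cidFood, length(uncovered), replace = TRUE),
      stringsAsFactors = FALSE))
  extra <- sample(cidFood, ceiling(nCompounds / 2))
  member <- unique(rbind(member, data.frame(food_id = fid[1L],
                                            compound_id = extra,
                                            stringsAsFactors = FALSE)))
  member <- orderBy(member, c("food_id", "compound_id"))

  ## ppi and orthologs -------------------------------------------------------
  nE <- min(p$n_ppi_edges, nProteins * (nProteins - 1) / 2)
  pairIdx <- which(upper.tri(matrix(TRUE, nProteins, nProteins)),
                   arr.ind = TRUE)
  pick <- pairIdx[sample(nrow(pairIdx), nE), , drop = FALSE]
  ppi <- data.frame(protein_a = pid[pick[, 1L]], protein_b = pid[pick[, 2L]],
                    score = sample(150:950, nE, replace = TRUE),
                    stringsAsFactors = FALSE)
  rodent <- proteins$protein_id[proteins$species != "human"]
  covered <- rodent[stats::runif(length(rodent)) < p$ortholog_cover]
  orthoTab <- if (length(covered))
    data.frame(source_id = covered,
               source_species = proteins$species[match(covered, pid)],
               human_id = paste0(covered, "_HS"), stringsAsFactors = FALSE)
  else .emptyTable("orthologs")

  registry <- dfiRegistry(compounds = compounds, foods = member,
                          proteins = proteins, drugs = drugs,
                          measurements = measurements, ppi = ppi,
                          orthologs = orthoTab)

  ## generator-side expectations --------------------------------------------
  inR <- plantedDf[plantedDf$in_range, , drop = FALSE]
  protOf <- split(inR$protein_id, inR$compound_id)
  ranking <- do.call(rbind, lapply(fid, function(f) {
    cs <- member$compound_id[member$food_id == f]
    ps <- unique(unlist(protOf[intersect(cs, names(protOf))]))
    data.frame(food_id = f,
               n_proteins = length(ps),
               n_compounds = length(intersect(cs, names(protOf))),
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$n_proteins, ranking$food_id,
                           method = "radix"), ]
  rownames(ranking) <- NULL

  # expected (drug, food) pair counts per drug target, noiseless conditions
  tgt <- unique(drugs$protein_id[drugs$role == "target"])
  pairSets <- lapply(setNames(nm = sort(tgt)), function(t) {
    ds <- unique(drugs$drug_id[drugs$protein_id == t & drugs$role == "target"])
    cs <- inR$compound_id[inR$protein_id == t]
    fs <- unique(member$food_id[member$compound_id %in% cs])
    if (length(ds) && length(fs)) as.vector(outer(ds, fs, paste, sep = "\r"))
    else character(0)
  })
  truth <- list(seed = seed, params = p,
                planted_active = plantedDf,
                food_ranking = ranking,
                target_pair_sets = lapply(pairSets, length),
                target_pair_members = pairSets,
                twins = twinTruth)
  list(registry = registry, truth = truth)
}

.defaultExprParams <- function() list(
  de_frac = 0.05, effect = 2, sigma = 1, baseline = 8,
  instances_per_drug = 3L, tag_offset = 6, tag_noise = 1
)

#' Generate a synthetic expression dataset with planted connectivity
#'
#' For each food, a genes x samples matrix of Gaussian noise with a planted
#' set of differentially expressed genes (half shifted up, half down in the
#' treatment group). Reference rank profiles are built per drug: a drug
#' planted as `correlated` with a food ranks that food's up-genes near the
#' top and down-genes near the bottom of its instances (with noise); an
#' `anticorrelated` drug the reverse; a `null` drug ranks at random.
#'
#' @param seed integer seed.
#' @param nGenes number of genes.
#' @param nPerGroup samples per group per food (>= 2; the design needs at
#'   least 2 treatment and 2 control arrays).
#' @param foods character vector of food ids.
#' @param drugAssign named list per food: list(correlated=, anticorrelated=,
#'   null=) drug id vectors; drugs may repeat across foods only with a
#'   consistent class.
#' @param params generator overrides (`de_frac`, `effect` (in units of
#'   sigma), `sigma`, `baseline`, `instances_per_drug`, `tag_offset`,
#'   `tag_noise`).
#' @return list: `registry` ([DfiRegistry-class] carrying expression,
#'   groups, reference ranks, instances) and `truth` (planted DE genes per
#'   food and the planted class per food-drug pair).
#' @export
genExpression <- function(seed, nGenes = 1000L, nPerGroup = 4L,
                          foods = c("FOOD_A", "FOOD_B"),
                          drugAssign = NULL, params = list()) {
  p <- utils::modifyList(.defaultExprParams(), params)
  if (nPerGroup < 2L)
    stopf("need >= 2 samples per group (>= 4 arrays per food)")
  set.seed(seed)
  if (is.null(drugAssign))
    drugAssign <- setNames(lapply(seq_along(foods), function(i)
      list(correlated = sprintf("DRUG_COR_%s", foods[i]),
           anticorrelated = sprintf("DRUG_ANT_%s", foods[i]),
           null = sprintf("DRUG_NUL_%s", foods[i]))), foods)
  genes <- sprintf("g%05d", seq_len(nGenes))
  nDE <- max(2L, round(p$de_frac * nGenes))
  if (nDE %% 2L) nDE <- nDE + 1L

  exprCols <- list(); groupRows <- list(); deTruth <- list()
  for (f in foods) {
    de <- sample(genes, nDE)
    up <- de[seq_len(nDE / 2)]
    down <- de[nDE / 2 + seq_len(nDE / 2)]
    m <- matrix(stats::rnorm(nGenes * 2L * nPerGroup, p$baseline, p$sigma),
                nGenes, 2L * nPerGroup, dimnames = list(genes, NULL))
    trt <- seq_len(nPerGroup)
    m[up, trt] <- m[up, trt] + p$effect * p$sigma
    m[down, trt] <- m[down, trt] - p$effect * p$sigma
    cols <- sprintf("%s_%s_%d", f, rep(c("trt", "ctl"), each = nPerGroup),
                    rep(seq_len(nPerGroup), 2L))
    colnames(m) <- cols
    exprCols[[f]] <- m
    groupRows[[f]] <- data.frame(
      sample_id = cols, food_id = f,
      group = rep(c("treatment", "control"), each = nPerGroup),
      stringsAsFactors = FALSE)
    deTruth[[f]] <- list(up = sort(up), down = sort(down))
  }
  expression <- do.call(cbind, exprCols)
  groups <- do.call(rbind, groupRows)
  rownames(groups) <- NULL

  ## reference rank profiles -------------------------------------------------
  classRows <- list(); rankCols <- list(); instRows <- list()
  for (f in foods) for (cls in names(drugAssign[[f]])) {
    for (d in drugAssign[[f]][[cls]]) {
      classRows[[length(classRows) + 1L]] <- data.frame(
        food_id = f, reference_id = d, class = cls,
        stringsAsFactors = FALSE)
      for (k in seq_len(p$instances_per_drug)) {
        sc <- stats::rnorm(nGenes, 0, 1)
        names(sc) <- genes
        if (cls == "correlated") {
          sc[deTruth[[f]]$up] <- sc[deTruth[[f]]$up] +
            p$tag_offset + stats::rnorm(nDE / 2, 0, p$tag_noise)
          sc[deTruth[[f]]$down] <- sc[deTruth[[f]]$down] -
            p$tag_offset + stats::rnorm(nDE / 2, 0, p$tag_noise)
        } else if (cls == "anticorrelated") {
          sc[deTruth[[f]]$up] <- sc[deTruth[[f]]$up] -
            p$tag_offset + stats::rnorm(nDE / 2, 0, p$tag_noise)
          sc[deTruth[[f]]$down] <- sc[deTruth[[f]]$down] +
            p$tag_offset + stats::rnorm(nDE / 2, 0, p$tag_noise)
        }
        iid <- sprintf("%s_i%d", d, k)
        rankCols[[iid]] <- rank(-sc, ties.method = "first")
        instRows[[length(instRows) + 1L]] <- data.frame(
          instance_id = iid, reference_id = d, stringsAsFactors = FALSE)
      }
    }
  }
  ranks <- do.call(cbind, rankCols)
  storage.mode(ranks) <- "integer"
  rownames(ranks) <- genes
  instances <- do.call(rbind, instRows)
  rownames(instances) <- NULL

  registry <- dfiRegistry(expression = expression, groups = groups,
                          referenceRanks = ranks, instances = instances)
  truth <- list(seed = seed, params = p, de_genes = deTruth,
                classes = do.call(rbind, classRows))
  list(registry = registry, truth = truth)
}

#' Serialize / read generator ground truth
#'
#' Ground truth is written as JSON next to the generated tables so that any
#' stage's output can be scored later without re-running the generator.
#'
#' @param truth the `truth` element of [genChemistry()] / [genExpression()].
#' @param path JSON file path.
#' @return `readGroundTruth` returns the truth list; `writeGroundTruth`
#'   returns `path` invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(tr), c("planted_active", "food_ranking",
                                    "twins", "classes")))
    if (!is.null(tr[[nm]])) tr[[nm]] <- as.data.frame(tr[[nm]])
  tr
}
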