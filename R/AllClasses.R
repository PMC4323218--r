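#' @import methods
NULL

# ---------------------------------------------------------------------------
# DfiConfig
# ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Holds every numeric threshold of the drug-food interaction pipeline plus
#' the random seed. Defaults are the published cutoffs: pchembl > 6 for
#' Ki/Kd/IC50/EC50, inhibition > 30\%, potency < 50 uM, positive-measurement
#' frequency > 0.5, Tanimoto >= 0.85 with |dMW| < 50 g/mol, PPI score > 400,
#' >= 3 shared drug-food pairs per target-target edge, FDR 0.05,
#' |enrichment score| > 0.75, permutation p < 0.01, non-null > 80\%, top-5
#' displayed edges.
#'
#' @slot params named list of numeric/logical settings (see [dfiConfig()]).
#' @slot seed integer random seed from which all pipeline randomness flows.
#' @export
setClass("DfiConfig", representation(params = "list", seed = "numeric"))

.dfiDefaults <- function() list(
  pchembl_min        = 6,
  inhibition_min_pct = 30,
  potency_max_uM     = 50,
  frequency_min      = 0.5,
  tc_min             = 0.85,
  mw_window          = 50,
  ppi_score_min      = 400,
  shared_pair_min    = 3,
  fdr_alpha          = 0.05,
  es_min             = 0.75,
  perm_p_max         = 0.01,
  nonnull_min_pct    = 80,
  top_edges_shown    = 5,
  # implementation choices exposed as configuration
  two_sided_range          = FALSE,  # require >= min drug affinity as well
  drug_range_positive_only = FALSE,  # restrict drug ranges to filter-positive rows
  pool_endpoints           = TRUE,   # pool Ki/Kd/IC50/EC50 on the nM scale
  fingerprint_bits         = 1024,
  n_permutations           = 10000,
  tag_list_cap             = Inf
)

setValidity("DfiConfig", function(object) {
  need <- names(.dfiDefaults())
  missing <- setdiff(need, names(object@params))
  if (length(missing))
    return(paste("missing config parameters:", paste(missing, collapse = ", ")))
  num <- object@params[setdiff(need, c("two_sided_range",
                                       "drug_range_positive_only",
                                       "pool_endpoints"))]
  if (!all(vapply(num, is.numeric, logical(1))))
    return("all threshold parameters must be numeric")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single non-missing number")
  TRUE
})

#' Create a pipeline configuration
#'
#' @param ... named overrides of the defaults listed in [DfiConfig-class].
#' @param seed integer seed; every stochastic stage derives its stream from
#'   this value.
#' @return A [DfiConfig-class] object.
#' @examples
#' cfg <- dfiConfig(seed = 7)
#' dfiParam(cfg, "tc_min")
#' @export
dfiConfig <- function(..., seed = 1L) {
  over <- list(...)
  params <- .dfiDefaults()
  unknown <- setdiff(names(over), names(params))
  if (length(unknown))
    stopf("unknown config parameter(s): %s", paste(unknown, collapse = ", "))
  params[names(over)] <- over
  new("DfiConfig", params = params, seed = as.numeric(seed))
}

#' Read a configuration parameter
#' @param config a [DfiConfig-class].
#' @param name parameter name.
#' @export
dfiParam <- function(config, name) {
  if (!name %in% names(config@params)) stopf("no config parameter '%s'", name)
  config@params[[name]]
}

#' Seed stored in a configuration
#' @param config a [DfiConfig-class].
#' @export
dfiSeed <- function(config) config@seed

#' Write / read a configuration as key=value lines
#' @param config a [DfiConfig-class].
#' @param path file path.
#' @return `readDfiConfig` returns a [DfiConfig-class]; `writeDfiConfig`
#'   returns `path` invisibly.
#' @export
writeDfiConfig <- function(config, path) {
  vals <- c(config@params, list(seed = config@seed))
  lines <- vapply(names(vals), function(k) {
    v <- vals[[k]]
    paste0(k, "=", if (is.logical(v)) tolower(as.character(v)) else
      format(v, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeDfiConfig
#' @export
readDfiConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2L])
    if (v %in% c("true", "false")) return(v == "true")
    if (v == "Inf") return(Inf)
    as.numeric(v)
  })
  names(vals) <- trimws(keys)
  seed <- vals[["seed"]] %||% 1L
  vals[["seed"]] <- NULL
  do.call(dfiConfig, c(vals, list(seed = seed)))
}

setMethod("show", "DfiConfig", function(object) {
  cat("DfiConfig (seed ", object@seed, ")\n", sep = "")
  p <- object@params
  for (k in names(p)) cat(sprintf("  %-26s %s\n", k, format(p[[k]])))
})

# ---------------------------------------------------------------------------
# DfiRegistry
# ---------------------------------------------------------------------------

#' Registry of all pipeline input tables
#'
#' The validated, unit-normalised container for one analysis: compounds,
#' food-compound memberships, proteins (with DrugBank-style category, disease
#' classes at ontology level 3, biological system, species), drug-protein
#' links, bioassay measurements (affinities normalised to nM), PPI edges,
#' ortholog mappings, and the optional expression-side tables. Construct it
#' with [loadTables()] or [dfiRegistry()]; never modify slots directly.
#'
#' @slot compounds data.frame: compound_id, smiles, mw, names, origin.
#' @slot foods data.frame: food_id, compound_id (long format).
#' @slot proteins data.frame: protein_id, protein_name, category,
#'   disease_classes ("|"-separated), biological_system, species.
#' @slot drugs data.frame: drug_id, compound_id, protein_id, role,
#'   disease_classes.
#' @slot measurements data.frame: compound_id, protein_id, endpoint, value,
#'   units, value_nm, pchembl.
#' @slot ppi data.frame: protein_a, protein_b, score.
#' @slot orthologs data.frame: source_id, source_species, human_id.
#' @slot expression numeric matrix genes x samples (may be 0 x 0).
#' @slot groups data.frame: sample_id, food_id, group.
#' @slot referenceRanks integer matrix ids x instances of ranks 1..G.
#' @slot instances data.frame: instance_id, reference_id.
#' @slot loadReport list with per-type counts and rejected rows.
#' @export
setClass("DfiRegistry", representation(
  compounds      = "data.frame",
  foods          = "data.frame",
  proteins       = "data.frame",
  drugs          = "data.frame",
  measurements   = "data.frame",
  ppi            = "data.frame",
  orthologs      = "data.frame",
  expression     = "matrix",
  groups         = "data.frame",
  referenceRanks = "matrix",
  instances      = "data.frame",
  loadReport     = "list"
))

.validCategories <- c("drug_target", "enzyme", "transporter", "carrier")
.validRoles      <- c("target", "enzyme", "transporter", "carrier")
.validOrigins    <- c("food", "drug", "reference_bioactive")
.validSpecies    <- c("human", "rat", "mouse")
.affinityEndpoints <- c("Ki", "Kd", "IC50", "EC50")
.validEndpoints  <- c(.affinityEndpoints, "inhibition", "potency")

setValidity("DfiRegistry", function(object) {
  errs <- character(0)
  cmp <- object@compounds; prt <- object@proteins
  if (anyDuplicated(cmp$compound_id))
    errs <- c(errs, "duplicate compound_id in compound registry")
  if (anyDuplicated(prt$protein_id))
    errs <- c(errs, "duplicate protein_id in protein registry")
  if (nrow(cmp) && !all(cmp$origin %in% .validOrigins))
    errs <- c(errs, "compound origin outside {food, drug, reference_bioactive}")
  if (nrow(prt) && !all(prt$category %in% .validCategories))
    errs <- c(errs, "protein category outside the DrugBank categories")
  if (nrow(prt) && !all(prt$species %in% .validSpecies))
    errs <- c(errs, "protein species outside {human, rat, mouse}")
  bad <- setdiff(object@foods$compound_id, cmp$compound_id)
  if (length(bad))
    errs <- c(errs, paste("food membership references unknown compound(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  bad <- setdiff(object@measurements$compound_id, cmp$compound_id)
  if (length(bad))
    errs <- c(errs, paste("measurement references unknown compound(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  bad <- setdiff(object@measurements$protein_id, prt$protein_id)
  if (length(bad))
    errs <- c(errs, paste("measurement references unknown protein(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  drg <- object@drugs
  bad <- setdiff(drg$compound_id, cmp$compound_id)
  if (length(bad))
    errs <- c(errs, paste("drug references unknown compound(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  bad <- setdiff(drg$protein_id, prt$protein_id)
  if (length(bad))
    errs <- c(errs, paste("drug link references unknown protein(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  if (nrow(drg)) {
    # a link's role must agree with the linked protein's category
    cat <- prt$category[match(drg$protein_id, prt$protein_id)]
    role2cat <- c(target = "drug_target", enzyme = "enzyme",
                  transporter = "transporter", carrier = "carrier")
    off <- which(role2cat[drg$role] != cat)
    if (length(off))
      errs <- c(errs, paste("drug link role disagrees with protein category for",
                            paste(utils::head(unique(drg$protein_id[off]), 5),
                                  collapse = ", ")))
  }
  bad <- setdiff(c(object@ppi$protein_a, object@ppi$protein_b), prt$protein_id)
  if (length(bad))
    errs <- c(errs, paste("PPI edge references unknown protein(s):",
                          paste(utils::head(bad, 5), collapse = ", ")))
  ms <- object@measurements
  if (nrow(ms)) {
    if (!all(ms$endpoint %in% .validEndpoints))
      errs <- c(errs, "unknown endpoint in measurement table")
    aff <- ms$endpoint %in% .affinityEndpoints
    if (any(aff & (is.na(ms$value_nm) | ms$value_nm <= 0)))
      errs <- c(errs, "affinity measurement with non-positive normalised value")
    inh <- ms$endpoint == "inhibition"
    if (any(inh & (ms$value < 0 | ms$value > 100)))
      errs <- c(errs, "inhibition measurement outside [0, 100]")
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

setMethod("show", "DfiRegistry", function(object) {
  cat("DfiRegistry\n")
  cat(sprintf("  compounds:    %5d  (food %d / drug %d / reference %d)\n",
              nrow(object@compounds),
              sum(object@compounds$origin == "food"),
              sum(object@compounds$origin == "drug"),
              sum(object@compounds$origin == "reference_bioactive")))
  cat(sprintf("  foods:        %5d memberships, %d foods\n",
              nrow(object@foods), length(unique(object@foods$food_id))))
  cat(sprintf("  proteins:     %5d\n", nrow(object@proteins)))
  cat(sprintf("  drug links:   %5d (%d drugs)\n", nrow(object@drugs),
              length(unique(object@drugs$drug_id))))
  cat(sprintf("  measurements: %5d\n", nrow(object@measurements)))
  cat(sprintf("  ppi edges:    %5d\n", nrow(object@ppi)))
  cat(sprintf("  orthologs:    %5d\n", nrow(object@orthologs)))
  if (nrow(object@expression))
    cat(sprintf("  expression:   %d genes x %d samples\n",
                nrow(object@expression), ncol(object@expression)))
  if (nrow(object@referenceRanks))
    cat(sprintf("  ref ranks:    %d ids x %d instances\n",
                nrow(object@referenceRanks), ncol(object@referenceRanks)))
})

# ---------------------------------------------------------------------------
# Networks
# ---------------------------------------------------------------------------

#' Weighted interaction networks
#'
#' `FoodNetwork` connects foods by the number of interacting proteins they
#' share; `TargetNetwork` connects drug targets of one disease class by the
#' number of shared drug-food pairs. Both store a node table and an edge
#' table with full provenance and are exported via [writeNetwork()] /
#' converted with [asIgraph()].
#'
#' @slot nodes data.frame of node attributes (first column is the node id).
#' @slot edges data.frame with columns `from`, `to`, `weight`, plus
#'   provenance columns.
#' @export
setClass("FoodNetwork", representation(nodes = "data.frame",
                                       edges = "data.frame"))

#' @rdname FoodNetwork-class
#' @slot diseaseClass disease-ontology class (level 3) the network is
#'   restricted to.
#' @slot nTargetsAffected number of targets of the class with at least one
#'   active food compound (the count printed inside the pie of the source
#'   figure style).
#' @export
setClass("TargetNetwork", representation(nodes = "data.frame",
                                         edges = "data.frame",
                                         diseaseClass = "character",
                                         nTargetsAffected = "integer"))

.validNet <- function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (!all(c("from", "to", "weight") %in% names(e)))
      return("edge table needs from/to/weight")
    if (any(e$from == e$to)) return("self-edges are not allowed")
    ids <- object@nodes[[1L]]
    if (!all(c(e$from, e$to) %in% ids))
      return("edge endpoint missing from node table")
  }
  TRUE
}
setValidity("FoodNetwork", .validNet)
setValidity("TargetNetwork", .validNet)

setMethod("show", "FoodNetwork", function(object) {
  cat(sprintf("FoodNetwork: %d foods, %d edges (shared interacting proteins)\n",
              nrow(object@nodes), nrow(object@edges)))
})
setMethod("show", "TargetNetwork", function(object) {
  cat(sprintf(
    "TargetNetwork [%s]: %d targets (%d affected by food), %d edges\n",
    object@diseaseClass, nrow(object@nodes), object@nTargetsAffected,
    nrow(object@edges)))
})
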