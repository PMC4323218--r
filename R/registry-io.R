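# Table readers/writers and registry construction (TSV with header is the
# canonical dialect; multi-valued cells are "|"-separated).

.schemas <- list(
  compounds    = c("compound_id", "smiles", "mw", "names", "origin"),
  foods        = c("food_id", "compound_id"),
  proteins     = c("protein_id", "protein_name", "category", "disease_classes",
                   "biological_system", "species"),
  drugs        = c("drug_id", "compound_id", "protein_id", "role",
                   "disease_classes"),
  measurements = c("compound_id", "protein_id", "endpoint", "value", "units",
                   "pchembl"),
  ppi          = c("protein_a", "protein_b", "score"),
  orthologs    = c("source_id", "source_species", "human_id"),
  groups       = c("sample_id", "food_id", "group"),
  instances    = c("instance_id", "reference_id")
)

.emptyTable <- function(name) {
  cols <- .schemas[[name]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  numCols <- intersect(cols, c("mw", "value", "pchembl", "score"))
  for (cc in numCols) df[[cc]] <- numeric(0)
  df
}

# Normalise affinity units to nM. Potency arrives in uM and is converted so a
# single scale serves the drug-activity-range rule (50 uM == 50,000 nM).
.unitToNM <- c(pM = 1e-3, nM = 1, uM = 1e3, mM = 1e6, M = 1e9)

.normalizeMeasurements <- function(ms) {
  rejects <- emptyDf(row = "integer", reason = "character",
                     detail = "character")
  if (nrow(ms) == 0L) {
    ms$value_nm <- numeric(0)
    return(list(measurements = ms, rejects = rejects))
  }
  ms$value <- as.numeric(ms$value)
  ms$pchembl <- suppressWarnings(as.numeric(ms$pchembl))
  ms$value_nm <- NA_real_
  bad <- rep(NA_character_, nrow(ms))

  unknown <- !(ms$endpoint %in% .validEndpoints)
  bad[unknown] <- "unknown_endpoint"

  aff <- ms$endpoint %in% .affinityEndpoints & is.na(bad)
  if (any(aff)) {
    fac <- .unitToNM[ms$units[aff]]
    i <- which(aff)
    bad[i[is.na(fac)]] <- "unknown_units"
    ok <- i[!is.na(fac)]
    ms$value_nm[ok] <- ms$value[ok] * fac[!is.na(fac)]
    bad[ok[is.na(ms$value_nm[ok]) | ms$value_nm[ok] <= 0]] <-
      "nonpositive_affinity"
  }
  pot <- ms$endpoint == "potency" & is.na(bad)
  if (any(pot)) {
    fac <- c(uM = 1e3, nM = 1)[ms$units[pot]]
    i <- which(pot)
    bad[i[is.na(fac)]] <- "unknown_units"
    ok <- i[!is.na(fac)]
    ms$value_nm[ok] <- ms$value[ok] * fac[!is.na(fac)]
    bad[ok[is.na(ms$value_nm[ok]) | ms$value_nm[ok] <= 0]] <-
      "nonpositive_potency"
  }
  inh <- ms$endpoint == "inhibition" & is.na(bad)
  bad[inh & (is.na(ms$value) | ms$value < 0 | ms$value > 100)] <-
    "inhibition_out_of_range"

  drop <- !is.na(bad)
  if (any(drop)) {
    rejects <- data.frame(row = which(drop), reason = bad[drop],
                          detail = paste(ms$compound_id[drop],
                                         ms$protein_id[drop],
                                         ms$endpoint[drop], sep = "/"),
                          stringsAsFactors = FALSE)
    warnf("%d measurement row(s) rejected (%s)", sum(drop),
          paste(unique(bad[drop]), collapse = ", "))
    ms <- ms[!drop, , drop = FALSE]
    rownames(ms) <- NULL
  }
  list(measurements = ms, rejects = rejects)
}

#' Construct a registry from in-memory tables
#'
#' Applies unit normalisation, rejects malformed measurement rows (each
#' rejected row is recorded exactly once in the load report with a
#' machine-readable reason code), and validates referential integrity: any
#' unresolvable foreign identifier is a hard error naming the offenders.
#'
#' @param compounds,foods,proteins,drugs,measurements,ppi,orthologs
#'   data.frames with the documented columns; missing tables default to
#'   empty.
#' @param expression optional numeric matrix genes x samples.
#' @param groups optional sample annotation (sample_id, food_id, group).
#' @param referenceRanks optional integer matrix ids x instances, each column
#'   a permutation of 1..G (rank 1 = most up-regulated).
#' @param instances optional instance annotation (instance_id, reference_id).
#' @return A validated [DfiRegistry-class].
#' @export
dfiRegistry <- function(compounds = .emptyTable("compounds"),
                        foods = .emptyTable("foods"),
                        proteins = .emptyTable("proteins"),
                        drugs = .emptyTable("drugs"),
                        measurements = .emptyTable("measurements"),
                        ppi = .emptyTable("ppi"),
                        orthologs = .emptyTable("orthologs"),
                        expression = matrix(numeric(0), 0, 0),
                        groups = .emptyTable("groups"),
                        referenceRanks = matrix(integer(0), 0, 0),
                        instances = .emptyTable("instances")) {
  for (nm in names(.schemas)[1:7]) {
    tab <- get(nm, inherits = FALSE)
    miss <- setdiff(.schemas[[nm]], names(tab))
    if (length(miss))
      stopf("table '%s' lacks column(s): %s", nm, paste(miss, collapse = ", "))
    rownames(tab) <- NULL
    assign(nm, tab, inherits = FALSE)
  }
  rownames(groups) <- NULL
  rownames(instances) <- NULL
  if (nrow(compounds)) compounds$mw <- suppressWarnings(as.numeric(compounds$mw))
  if (nrow(ppi)) ppi$score <- as.numeric(ppi$score)
  norm <- .normalizeMeasurements(measurements)
  counts <- c(compounds = nrow(compounds), foods = nrow(foods),
              proteins = nrow(proteins), drugs = nrow(drugs),
              measurements = nrow(norm$measurements), ppi = nrow(ppi),
              orthologs = nrow(orthologs))
  report <- list(counts = counts, rejected = norm$rejects)
  obj <- new("DfiRegistry",
             compounds = compounds, foods = foods, proteins = proteins,
             drugs = drugs, measurements = norm$measurements, ppi = ppi,
             orthologs = orthologs, expression = expression, groups = groups,
             referenceRanks = referenceRanks, instances = instances,
             loadReport = report)
  dfiLog(sprintf(
    "registry loaded: %s; %d row(s) rejected",
    paste(names(counts), counts, sep = "=", collapse = " "),
    nrow(norm$rejects)))
  obj
}

.readTsv <- function(path) {
  # empty cells are empty strings (set-valued columns), "NA" is missing
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = "NA")
}

#' Load pipeline input tables from a directory
#'
#' Reads the canonical TSV files (`compounds.tsv`, `foods.tsv`,
#' `proteins.tsv`, `drugs.tsv`, `measurements.tsv`, `ppi.tsv`,
#' `orthologs.tsv`, and the optional expression-side files
#' `expression.tsv`, `groups.tsv`, `reference_ranks.tsv`, `instances.tsv`),
#' normalises units and validates cross-references. Missing files yield
#' empty tables; a header that does not match the documented schema is an
#' error.
#'
#' @param dir directory containing the tables.
#' @param config a [DfiConfig-class] (currently only logged).
#' @return A validated [DfiRegistry-class] whose [loadReport()] records
#'   per-type counts and rejected rows.
#' @export
loadTables <- function(dir, config = dfiConfig()) {
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) return(.emptyTable(nm))
    tab <- .readTsv(p)
    miss <- setdiff(.schemas[[nm]], names(tab))
    if (length(miss))
      stopf("%s: header lacks column(s) %s", p, paste(miss, collapse = ", "))
    tab
  }
  args <- lapply(setNames(nm = names(.schemas)[1:7]), rd)
  exprPath <- file.path(dir, "expression.tsv")
  if (file.exists(exprPath)) {
    em <- utils::read.delim(exprPath, stringsAsFactors = FALSE,
                            check.names = FALSE)
    args$expression <- as.matrix(em[, -1, drop = FALSE])
    rownames(args$expression) <- em[[1L]]
    args$groups <- rd("groups")
  }
  rrPath <- file.path(dir, "reference_ranks.tsv")
  if (file.exists(rrPath)) {
    rr <- utils::read.delim(rrPath, stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(rr[, -1, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- rr[[1L]]
    args$referenceRanks <- m
    args$instances <- rd("instances")
  }
  do.call(dfiRegistry, args)
}

#' Write a registry back to canonical TSV tables
#'
#' Inverse of [loadTables()]: `loadTables(writeTables(x, dir))` reconstructs
#' an identical registry (normalised columns are re-derived on load).
#'
#' @param registry a [DfiRegistry-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTables <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # empty tables are skipped (a missing file loads back as an empty table),
  # so chemistry-side and expression-side registries can share a directory
  wr <- function(tab, nm, cols) {
    if (nrow(tab) == 0L) return(invisible(NULL))
    utils::write.table(tab[, cols, drop = FALSE],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(registry@compounds, "compounds", .schemas$compounds)
  wr(registry@foods, "foods", .schemas$foods)
  wr(registry@proteins, "proteins", .schemas$proteins)
  wr(registry@drugs, "drugs", .schemas$drugs)
  wr(registry@measurements, "measurements", .schemas$measurements)
  wr(registry@ppi, "ppi", .schemas$ppi)
  wr(registry@orthologs, "orthologs", .schemas$orthologs)
  if (nrow(registry@expression)) {
    em <- data.frame(gene_id = rownames(registry@expression),
                     registry@expression, check.names = FALSE)
    utils::write.table(em, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wr(registry@groups, "groups", .schemas$groups)
  }
  if (nrow(registry@referenceRanks)) {
    rr <- data.frame(id = rownames(registry@referenceRanks),
                     registry@referenceRanks, check.names = FALSE)
    utils::write.table(rr, file.path(dir, "reference_ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    wr(registry@instances, "instances", .schemas$instances)
  }
  invisible(dir)
}
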