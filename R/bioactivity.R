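# Measurement filtering, frequency-rule aggregation, and the
# drug-activity-range classification of food compounds.

#' Flag bioassay measurements as positive or negative
#'
#' Applies the endpoint-specific evidence criteria: for Ki, Kd, IC50 and
#' EC50 a pchembl value larger than 6; for inhibition a measured value
#' greater than 30\%; for potency a value lower than 50 uM (all strict
#' inequalities; thresholds from `config`). Rows lacking the field their
#' endpoint needs (e.g. a missing pchembl) are flagged negative.
#'
#' @param measurements measurement table (from [measurements()]) or a
#'   [DfiRegistry-class].
#' @param config a [DfiConfig-class].
#' @return The measurement table with a logical `positive` column appended.
#' @examples
#' reg <- inPaperFixture()
#' table(filterMeasurements(reg)$positive)
#' @export
filterMeasurements <- function(measurements, config = dfiConfig()) {
  if (is(measurements, "DfiRegistry")) measurements <- measurements@measurements
  ms <- measurements
  pos <- logical(nrow(ms))
  aff <- ms$endpoint %in% .affinityEndpoints
  pos[aff] <- !is.na(ms$pchembl[aff]) &
    ms$pchembl[aff] > dfiParam(config, "pchembl_min")
  inh <- ms$endpoint == "inhibition"
  pos[inh] <- !is.na(ms$value[inh]) &
    ms$value[inh] > dfiParam(config, "inhibition_min_pct")
  pot <- ms$endpoint == "potency"
  pos[pot] <- !is.na(ms$value_nm[pot]) &
    ms$value_nm[pot] < dfiParam(config, "potency_max_uM") * 1e3
  ms$positive <- pos
  ms
}

#' Aggregate flagged measurements into confident interactions
#'
#' Multiple measurements of the same compound on the same protein are
#' summarised by the frequency of positive measurements; only pairs with a
#' frequency strictly higher than 0.5 are considered confident. The
#' representative affinity is the geometric mean of the positive affinity
#' (Ki/Kd/IC50/EC50) values in nM, absent when no affinity endpoint
#' contributed.
#'
#' @param flagged output of [filterMeasurements()].
#' @param config a [DfiConfig-class].
#' @return data.frame with one row per retained (compound, protein) pair:
#'   `compound_id`, `protein_id`, `n_measurements`, `n_positive`,
#'   `positive_frequency`, `representative_affinity` (nM) and
#'   `endpoint_mix` ("|"-separated endpoints among positive rows).
#' @export
aggregateInteractions <- function(flagged, config = dfiConfig()) {
  out <- emptyDf(compound_id = "character", protein_id = "character",
                 n_measurements = "integer", n_positive = "integer",
                 positive_frequency = "numeric",
                 representative_affinity = "numeric",
                 endpoint_mix = "character")
  if (nrow(flagged) == 0L) return(out)
  key <- paste(flagged$compound_id, flagged$protein_id, sep = "\r")
  n <- tapply(flagged$positive, key, length)
  npos <- tapply(flagged$positive, key, sum)
  isAff <- flagged$endpoint %in% .affinityEndpoints
  repAff <- tapply(ifelse(flagged$positive & isAff, flagged$value_nm,
                          NA_real_),
                   key, geomMean)
  mix <- tapply(ifelse(flagged$positive, flagged$endpoint, NA_character_),
                key, function(e) paste(sort(unique(e[!is.na(e)])),
                                       collapse = "|"))
  keys <- names(n)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  res <- data.frame(
    compound_id = vapply(parts, `[`, character(1), 1L),
    protein_id = vapply(parts, `[`, character(1), 2L),
    n_measurements = as.integer(n),
    n_positive = as.integer(npos),
    positive_frequency = as.numeric(npos) / as.numeric(n),
    representative_affinity = as.numeric(repAff),
    endpoint_mix = as.character(mix),
    stringsAsFactors = FALSE)
  res <- res[res$positive_frequency > dfiParam(config, "frequency_min"), ,
             drop = FALSE]
  res <- orderBy(res, c("compound_id", "protein_id"))
  rownames(res) <- NULL
  res
}

# Per-drug representative affinity against each protein. By default every
# valid drug affinity measurement contributes (not only filter-positive
# rows): the published worked examples include food compounds matching drug
# affinities at or above 1 uM, which a positive-only range (capped below
# 1 uM by the pchembl filter) could never admit. Set
# `drug_range_positive_only = TRUE` for the stricter reading.
.drugAffinities <- function(registry, config) {
  ms <- filterMeasurements(registry@measurements, config)
  drugCompounds <- unique(registry@drugs$compound_id)
  ms <- ms[ms$compound_id %in% drugCompounds &
             ms$endpoint %in% .affinityEndpoints &
             !is.na(ms$value_nm), , drop = FALSE]
  if (isTRUE(dfiParam(config, "drug_range_positive_only")))
    ms <- ms[ms$positive, , drop = FALSE]
  if (nrow(ms) == 0L)
    return(emptyDf(compound_id = "character", protein_id = "character",
                   affinity = "numeric"))
  key <- paste(ms$compound_id, ms$protein_id, sep = "\r")
  aff <- tapply(ms$value_nm, key, geomMean)
  parts <- strsplit(names(aff), "\r", fixed = TRUE)
  data.frame(compound_id = vapply(parts, `[`, character(1), 1L),
             protein_id = vapply(parts, `[`, character(1), 2L),
             affinity = as.numeric(aff), stringsAsFactors = FALSE)
}

#' Call food compounds active or inactive against proteins
#'
#' A food compound is considered active against a protein when its
#' representative affinity falls within the activity range of the drugs
#' targeting the same protein; "within the range" is read as at least as
#' potent as the least potent drug (affinity <= max drug affinity in nM),
#' since requiring >= min as well would reject phytochemicals stronger than
#' every drug, which the published case studies include. The strict
#' two-sided variant is available via config `two_sided_range = TRUE`. For
#' proteins with no drug affinity data, the compound is compared to the
#' geometric mean of per-protein drug affinities over proteins of the same
#' category (macro average). Interactions carrying no affinity endpoint
#' (inhibition/potency only) are active by the frequency rule alone, with
#' basis recorded as `frequency_only`.
#'
#' @param interactions confident interactions from
#'   [aggregateInteractions()]; typically restricted to food compounds.
#' @param registry a [DfiRegistry-class] supplying drugs and proteins.
#' @param config a [DfiConfig-class].
#' @return data.frame: `compound_id`, `protein_id`, `is_active`, `basis`
#'   (`drug_range`, `category_mean_fallback` or `frequency_only`),
#'   `range_min`, `range_max`, `category_mean`, `representative_affinity`.
#' @export
classifyActivity <- function(interactions, registry, config = dfiConfig()) {
  da <- .drugAffinities(registry, config)
  prt <- registry@proteins

  # per-protein drug range and per-category macro geometric mean
  rngMin <- tapply(da$affinity, da$protein_id, min)
  rngMax <- tapply(da$affinity, da$protein_id, max)
  perProtein <- tapply(da$affinity, da$protein_id, geomMean)
  protCat <- prt$category[match(names(perProtein), prt$protein_id)]
  catMean <- tapply(as.numeric(perProtein), protCat, geomMean)

  n <- nrow(interactions)
  out <- data.frame(
    compound_id = interactions$compound_id,
    protein_id = interactions$protein_id,
    is_active = logical(n), basis = character(n),
    range_min = rep(NA_real_, n), range_max = rep(NA_real_, n),
    category_mean = rep(NA_real_, n),
    representative_affinity = interactions$representative_affinity,
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)

  hasRange <- interactions$protein_id %in% names(rngMax)
  cat_i <- prt$category[match(interactions$protein_id, prt$protein_id)]
  cm <- as.numeric(catMean[cat_i])
  aff <- interactions$representative_affinity
  noAff <- is.na(aff)

  out$basis <- ifelse(noAff, "frequency_only",
                      ifelse(hasRange, "drug_range", "category_mean_fallback"))
  out$is_active[noAff] <- TRUE

  dr <- which(!noAff & hasRange)
  if (length(dr)) {
    mx <- as.numeric(rngMax[interactions$protein_id[dr]])
    mn <- as.numeric(rngMin[interactions$protein_id[dr]])
    out$range_min[dr] <- mn
    out$range_max[dr] <- mx
    act <- aff[dr] <= mx
    if (isTRUE(dfiParam(config, "two_sided_range"))) act <- act & aff[dr] >= mn
    out$is_active[dr] <- act
  }
  fb <- which(!noAff & !hasRange)
  if (length(fb)) {
    out$category_mean[fb] <- cm[fb]
    out$is_active[fb] <- !is.na(cm[fb]) & aff[fb] <= cm[fb]
    if (any(is.na(cm[fb])))
      warnf(paste("%d interaction(s) on proteins with neither drug data nor",
                  "a category mean: called inactive"), sum(is.na(cm[fb])))
  }
  out
}

#' Per-food interaction profile
#'
#' Summarises active calls per food: number of bioactive phytochemicals,
#' number of distinct interacting proteins, and per-category protein counts.
#' Sorted by total interacting proteins (descending), reproducing a
#' "most-interacting foods" ranking.
#'
#' @param calls output of [classifyActivity()].
#' @param registry a [DfiRegistry-class] (food memberships + protein
#'   categories).
#' @return data.frame: `food_id`, `n_bioactive_compounds`,
#'   `n_interacting_proteins`, `n_drug_target`, `n_enzyme`, `n_transporter`,
#'   `n_carrier`.
#' @export
foodProteinProfile <- function(calls, registry) {
  act <- calls[calls$is_active, , drop = FALSE]
  fd <- registry@foods
  prt <- registry@proteins
  allFoods <- sort(unique(fd$food_id))
  out <- data.frame(food_id = allFoods, n_bioactive_compounds = 0L,
                    n_interacting_proteins = 0L, n_drug_target = 0L,
                    n_enzyme = 0L, n_transporter = 0L, n_carrier = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(act) && nrow(fd)) {
    m <- merge(fd, act, by = "compound_id")
    if (nrow(m)) {
      m$category <- prt$category[match(m$protein_id, prt$protein_id)]
      nC <- tapply(m$compound_id, m$food_id,
                   function(x) length(unique(x)))
      nP <- tapply(m$protein_id, m$food_id, function(x) length(unique(x)))
      out$n_bioactive_compounds <-
        as.integer(ifelse(is.na(nC[allFoods]), 0L, nC[allFoods]))
      out$n_interacting_proteins <-
        as.integer(ifelse(is.na(nP[allFoods]), 0L, nP[allFoods]))
      for (cc in .validCategories) {
        sel <- m[m$category == cc, , drop = FALSE]
        nn <- tapply(sel$protein_id, sel$food_id,
                     function(x) length(unique(x)))
        out[[paste0("n_", cc)]] <-
          as.integer(ifelse(is.na(nn[allFoods]), 0L, nn[allFoods]))
      }
    }
  }
  # deterministic ranking with ascending food_id as the tie-break
  out <- out[order(-out$n_interacting_proteins, -out$n_bioactive_compounds,
                   out$food_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
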