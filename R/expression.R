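# Expression arm: moderated t differential expression, tag lists,
# KS connectivity scoring, and the DE-vs-non-DE affinity comparison.

#' Moderated t-test differential expression
#'
#' Two-group differential expression with empirical-Bayes variance
#' moderation: per-gene pooled variances are shrunk towards a common prior
#' fitted by method of moments to the scaled inverse chi-square model
#' (`s_g^2 ~ s0^2 F(d, d0)`), giving moderated t statistics on `d + d0`
#' degrees of freedom. Benjamini-Hochberg q-values control the FDR;
#' significance is `fdr_q < fdr_alpha` (default 0.05), with direction taken
#' from the sign of the log fold change. Genes with zero variance in both
#' groups and zero fold change get p = 1 and are flagged.
#'
#' @param mat numeric matrix genes x samples, already normalised, on a log
#'   scale.
#' @param groups character/factor of length `ncol(mat)` with values
#'   `treatment` / `control`, or a `groups` data.frame with `sample_id` and
#'   `group` columns.
#' @param config a [DfiConfig-class] (uses `fdr_alpha`).
#' @return data.frame: `gene_id`, `log_fold_change`, `moderated_t`,
#'   `p_value`, `fdr_q`, `direction` (`up`/`down`/`ns`), `flagged`.
#'   Attributes `d0` and `s0_sq` expose the fitted prior.
#' @export
differentialExpression <- function(mat, groups, config = dfiConfig()) {
  if (is.data.frame(groups)) {
    groups <- groups$group[match(colnames(mat), groups$sample_id)]
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("treatment", "control")))
    stopf("groups must be 'treatment' or 'control'")
  i1 <- which(groups == "treatment"); i0 <- which(groups == "control")
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < 2L || n0 < 2L) stopf("need >= 2 samples per group")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m0 <- rowMeans(mat[, i0, drop = FALSE])
  lfc <- m1 - m0
  ss <- rowSums((mat[, i1, drop = FALSE] - m1)^2) +
    rowSums((mat[, i0, drop = FALSE] - m0)^2)
  d <- n1 + n0 - 2L
  s2 <- ss / d

  # method-of-moments fit of the scaled inverse chi-square prior:
  # E[s2] = s0^2 d0/(d0-2), Var[s2]/E[s2]^2 = 2 (d + d0 - 2) / (d (d0 - 4))
  m <- mean(s2); v <- stats::var(s2)
  c0 <- if (m > 0) v / m^2 else 0
  if (is.na(c0) || c0 * d <= 2) {
    d0 <- Inf; s0sq <- m
  } else {
    d0 <- (4 * c0 * d + 2 * d - 4) / (c0 * d - 2)
    s0sq <- m * (d0 - 2) / d0
  }
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2post * (1 / n1 + 1 / n0))
  tmod <- ifelse(se > 0, lfc / se, 0)
  dfTotal <- d + d0
  p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
  flagged <- se == 0
  p[flagged] <- 1
  q <- stats::p.adjust(p, method = "BH")
  alpha <- dfiParam(config, "fdr_alpha")
  # q-values can equal 1 exactly, so alpha >= 1 means "call everything"
  sig <- if (alpha >= 1) !flagged else q < alpha
  direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  res <- data.frame(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                    log_fold_change = lfc, moderated_t = tmod, p_value = p,
                    fdr_q = q, direction = direction, flagged = flagged,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0sq
  res
}

#' Build up/down tag lists from differential expression results
#'
#' Significant genes are split by direction into the up- and down-regulated
#' tag lists, ordered by significance (ascending p). Identifiers are mapped
#' to the reference profile's id space through `idMap`; unmapped tags are
#' dropped and counted. An empty pair of lists is an error (nothing to
#' score).
#'
#' @param de output of [differentialExpression()].
#' @param idMap optional data.frame with columns `from`, `to`; NULL keeps
#'   ids unchanged.
#' @param cap optional maximum tags per list (most significant kept).
#' @return list with `up`, `down` (character vectors) and attributes
#'   `n_unmapped_up`, `n_unmapped_down`.
#' @export
buildTagLists <- function(de, idMap = NULL, cap = Inf) {
  sig <- de[de$direction != "ns", , drop = FALSE]
  sig <- sig[order(sig$p_value, sig$gene_id, method = "radix"), ,
             drop = FALSE]
  mapIds <- function(ids) {
    if (is.null(idMap)) return(list(ids = ids, dropped = 0L))
    hit <- idMap$to[match(ids, idMap$from)]
    list(ids = hit[!is.na(hit)], dropped = sum(is.na(hit)))
  }
  up <- mapIds(sig$gene_id[sig$direction == "up"])
  dn <- mapIds(sig$gene_id[sig$direction == "down"])
  if (length(up$ids) == 0L && length(dn$ids) == 0L)
    stopf("both tag lists are empty: no significant gene survived mapping")
  if (is.finite(cap)) {
    up$ids <- utils::head(up$ids, cap)
    dn$ids <- utils::head(dn$ids, cap)
  }
  structure(list(up = up$ids, down = dn$ids),
            n_unmapped_up = up$dropped, n_unmapped_down = dn$dropped)
}

# Weighted KS running statistic of a tag list against one ranked list.
# pos: ranks (1 = top) of the tags; n: length of the ranking.
.ksStat <- function(pos, n) {
  t <- length(pos)
  if (t == 0L) return(0)
  v <- sort(pos)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

.instanceScores <- function(up, down, ranks) {
  n <- nrow(ranks)
  vapply(seq_len(ncol(ranks)), function(j) {
    ku <- .ksStat(ranks[up, j], n)
    kd <- .ksStat(ranks[down, j], n)
    if (sign(ku) == sign(kd)) 0 else ku - kd
  }, numeric(1))
}

.scaleScores <- function(s) {
  p <- max(s); q <- min(s)
  out <- numeric(length(s))
  if (p > 0) out[s > 0] <- s[s > 0] / p
  if (q < 0) out[s < 0] <- s[s < 0] / abs(q)
  out
}

#' Connectivity score of a tag-list pair against reference rank profiles
#'
#' Implements the Kolmogorov-Smirnov connectivity scoring convention of the
#' reference-profile method: per instance, a weighted KS statistic is
#' computed for the up and the down tag list against the ranked reference
#' list; the instance score is 0 when the two statistics agree in sign and
#' `KS_up - KS_down` otherwise, then scaled across instances so the largest
#' positive score maps to +1 and the most negative to -1. Instances are
#' grouped by reference compound; the reference-level enrichment score is
#' the mean of its scaled instance scores. The permutation p-value resamples
#' random tag lists of the same sizes (seeded); the non-null percentage is
#' the share of a reference's instances with a nonzero score whose sign
#' agrees with the reference-level score. A reference is classified
#' `correlated` / `anticorrelated` only if |score| > 0.75, permutation
#' p < 0.01 and non-null percentage > 80 (all strict; thresholds from
#' `config`), else `null`.
#'
#' @param tags list with `up` and `down` character vectors (see
#'   [buildTagLists()]).
#' @param ranks integer matrix ids x instances; each column ranks all ids
#'   1..G, 1 = most up-regulated.
#' @param instances optional data.frame `instance_id`, `reference_id`
#'   grouping columns of `ranks` into reference sets; by default each
#'   column is its own reference.
#' @param config a [DfiConfig-class].
#' @param nPerm number of tag-list permutations (default config
#'   `n_permutations`).
#' @param seed integer seed for the permutation stream (default config
#'   seed).
#' @return data.frame per reference: `reference_id`, `enrichment_score`,
#'   `permutation_p`, `nonnull_pct`, `n_instances`, `classification`.
#'   Scaled per-instance scores are attached as attribute
#'   `instance_scores`.
#' @export
connectivityScore <- function(tags, ranks, instances = NULL,
                              config = dfiConfig(), nPerm = NULL,
                              seed = NULL) {
  up <- unique(tags$up); down <- unique(tags$down)
  g <- rownames(ranks)
  if (length(up) > nrow(ranks) || length(down) > nrow(ranks))
    stopf("tag list longer than the reference ranking")
  missUp <- setdiff(up, g); missDown <- setdiff(down, g)
  if (length(missUp) || length(missDown)) {
    warnf("%d tag id(s) absent from the reference ranking were dropped",
          length(missUp) + length(missDown))
    up <- setdiff(up, missUp); down <- setdiff(down, missDown)
  }
  if (length(up) == 0L && length(down) == 0L)
    stopf("no tag id maps into the reference ranking")
  if (is.null(instances) || nrow(instances) == 0L)
    instances <- data.frame(instance_id = colnames(ranks),
                            reference_id = colnames(ranks),
                            stringsAsFactors = FALSE)
  refOf <- instances$reference_id[match(colnames(ranks),
                                        instances$instance_id)]
  if (anyNA(refOf)) stopf("instance annotation misses ranked instance(s)")
  nPerm <- nPerm %||% dfiParam(config, "n_permutations")
  seed <- seed %||% dfiSeed(config)

  raw <- .instanceScores(up, down, ranks)
  scaled <- .scaleScores(raw)
  refs <- sort(unique(refOf))
  score <- vapply(refs, function(r) mean(scaled[refOf == r]), numeric(1))
  nonnull <- vapply(refs, function(r) {
    s <- raw[refOf == r]
    tgt <- sign(score[match(r, refs)])
    if (tgt == 0) return(0)
    100 * mean(s != 0 & sign(s) == tgt)
  }, numeric(1))

  # permutation null: random tag lists of the same sizes, full rescoring
  exceed <- setNames(numeric(length(refs)), refs)
  if (nPerm > 0) {
    set.seed(seed)
    for (b in seq_len(nPerm)) {
      ids <- sample(g, length(up) + length(down))
      pu <- ids[seq_along(up)]
      pd <- ids[seq_along(down) + length(up)]
      sPerm <- .scaleScores(.instanceScores(pu, pd, ranks))
      for (ri in seq_along(refs)) {
        ms <- mean(sPerm[refOf == refs[ri]])
        if (abs(ms) >= abs(score[ri])) exceed[ri] <- exceed[ri] + 1
      }
    }
  }
  pval <- (1 + exceed) / (nPerm + 1)
  cls <- connectivityClass(score, pval, nonnull, config)
  res <- data.frame(reference_id = refs,
                    enrichment_score = unname(score),
                    permutation_p = unname(pval),
                    nonnull_pct = unname(nonnull),
                    n_instances = as.integer(table(refOf)[refs]),
                    classification = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "instance_scores") <-
    data.frame(instance_id = colnames(ranks), reference_id = refOf,
               score = scaled, stringsAsFactors = FALSE)
  res
}

#' Classify a connectivity result
#'
#' A food-drug relationship is non-null only when all three criteria hold
#' strictly: |enrichment score| higher than 0.75, permutation p-value less
#' than 0.01, and non-null percentage above 80 (thresholds from `config`).
#' A score of exactly 0.75 is therefore `null`. The sign of the score
#' separates `correlated` from `anticorrelated`.
#'
#' @param es,p,nonnullPct vectors of enrichment scores, permutation
#'   p-values and non-null percentages.
#' @param config a [DfiConfig-class].
#' @return character vector: `correlated` / `anticorrelated` / `null`.
#' @export
connectivityClass <- function(es, p, nonnullPct, config = dfiConfig()) {
  ifelse(abs(es) > dfiParam(config, "es_min") &
           p < dfiParam(config, "perm_p_max") &
           nonnullPct > dfiParam(config, "nonnull_min_pct"),
         ifelse(es > 0, "correlated", "anticorrelated"), "null")
}

#' Food-drug connectivity network
#'
#' Collects non-null connectivity classifications into a food-drug edge
#' table (edge weight = |enrichment score|) and counts connected drugs per
#' disease class.
#'
#' @param results data.frame: rbind of [connectivityScore()] outputs with a
#'   `food_id` column prepended.
#' @param drugClasses optional data.frame `reference_id`,
#'   `disease_classes` ("|"-separated).
#' @return list: `edges` (food_id, reference_id, classification, weight),
#'   `class_counts` (disease class, n connected drugs; NULL without
#'   `drugClasses`).
#' @export
classifyConnections <- function(results, drugClasses = NULL) {
  edges <- results[results$classification != "null",
                   c("food_id", "reference_id", "classification",
                     "enrichment_score"), drop = FALSE]
  edges$weight <- abs(edges$enrichment_score)
  edges$enrichment_score <- NULL
  rownames(edges) <- NULL
  counts <- NULL
  if (!is.null(drugClasses) && nrow(edges)) {
    cls <- splitSet(drugClasses$disease_classes[
      match(unique(edges$reference_id), drugClasses$reference_id)])
    tab <- table(unlist(cls))
    counts <- data.frame(disease_class = names(tab),
                         n_drugs = as.integer(tab),
                         stringsAsFactors = FALSE)
  }
  list(edges = edges, class_counts = counts)
}

#' Compare binding affinities of DE-gene vs non-DE-gene targets
#'
#' Restricted to compounds targeting at least one differentially expressed
#' gene AND at least one non-DE gene, affinities are pooled by target DE
#' status and compared with a two-sample Wilcoxon rank-sum test; a
#' per-compound paired summary (geometric mean affinity per side) is also
#' returned.
#'
#' @param links data.frame: `compound_id`, `gene_id`,
#'   `affinity_nm`.
#' @param deGenes character vector of DE gene ids.
#' @return list: `p_value`, `statistic` (Wilcoxon W for non-DE vs DE),
#'   `n_compounds`, `affinities_de`, `affinities_nonde`, `per_compound`
#'   (compound_id, geomean_de, geomean_nonde).
#' @export
deVsNonDeAffinity <- function(links, deGenes) {
  links <- links[!is.na(links$affinity_nm), , drop = FALSE]
  links$de <- links$gene_id %in% deGenes
  hasBoth <- vapply(split(links$de, links$compound_id),
                    function(x) any(x) && any(!x), logical(1))
  keep <- names(hasBoth)[hasBoth]
  if (length(keep) == 0L)
    stopf("no compound targets both a DE and a non-DE gene")
  sub <- links[links$compound_id %in% keep, , drop = FALSE]
  affDe <- sub$affinity_nm[sub$de]
  affNon <- sub$affinity_nm[!sub$de]
  wt <- stats::wilcox.test(affNon, affDe, exact = NULL)
  perCompound <- do.call(rbind, lapply(split(sub, sub$compound_id),
    function(x) data.frame(compound_id = x$compound_id[1L],
                           geomean_de = geomMean(x$affinity_nm[x$de]),
                           geomean_nonde = geomMean(x$affinity_nm[!x$de]),
                           stringsAsFactors = FALSE)))
  rownames(perCompound) <- NULL
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_compounds = length(keep),
       affinities_de = affDe, affinities_nonde = affNon,
       per_compound = perCompound)
}
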