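# Chemical space: circular fingerprints + physicochemical descriptors,
# similarity matching, target transfer, PPI expansion, ortholog mapping.

.FP_RAW <- "ECFP4"  # circular fingerprint of radius 2, folded to 1024 bits

.foldFingerprint <- function(m, bits) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)  # single-molecule case
  if (ncol(m) == bits) { storage.mode(m) <- "integer"; return(m) }
  if (ncol(m) %% bits != 0L)
    stopf("cannot fold %d-bit fingerprint into %d bits", ncol(m), bits)
  k <- ncol(m) %/% bits
  out <- matrix(0L, nrow(m), bits)
  for (i in seq_len(k))
    out <- out | m[, ((i - 1L) * bits + 1L):(i * bits), drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

.parseMol <- function(smiles) {
  ref <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  if (is.null(ref) || length(ref) != 1L) return(NULL)
  ref[[1L]]
}

#' Compute the 1029-column descriptor matrix
#'
#' For each parseable structure: a 1024-bit circular fingerprint of radius 2
#' plus Topological Polar Surface Area (A^2), octanol/water partition
#' coefficient (SlogP), Molecular Weight (g/mol), and Lipinski hydrogen bond
#' acceptor and donor counts - 1029 columns in total. Unparseable structures
#' are reported in the rejects table, never silently dropped. A canonical
#' structure key (InChI) is computed alongside for exact-structure matching.
#'
#' @param compounds data.frame with `compound_id` and `smiles` columns (a
#'   full compound table or any subset), or a [DfiRegistry-class].
#' @param config a [DfiConfig-class]; `fingerprint_bits` controls the folded
#'   width (default 1024).
#' @return An object of class `DfiDescriptors`: list with `matrix`
#'   (compounds x 1029, rownames = compound ids), `inchi` (named character),
#'   `mw` (named numeric) and `rejects` (data.frame compound_id, reason).
#' @export
computeDescriptors <- function(compounds, config = dfiConfig()) {
  if (is(compounds, "DfiRegistry")) compounds <- compounds@compounds
  bits <- dfiParam(config, "fingerprint_bits")
  ids <- compounds$compound_id
  smiles <- compounds$smiles
  refs <- vector("list", length(ids))
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) next
    m <- .parseMol(smiles[i])
    if (is.null(m)) next
    refs[[i]] <- m
    ok[i] <- TRUE
  }
  props <- NULL; fp <- NULL
  if (any(ok)) {
    mols <- refs[ok]
    props <- ChemmineOB::prop_OB(mols)
    ok2 <- props$MW > 0  # zero-atom molecules signal a parse failure
    if (!all(ok2)) {
      ok[which(ok)[!ok2]] <- FALSE
      props <- props[ok2, , drop = FALSE]
      mols <- mols[ok2]
    }
    if (length(mols)) {
      fpRaw <- ChemmineOB::fingerprint_OB(mols, .FP_RAW)
      fp <- .foldFingerprint(fpRaw, bits)
    }
  }
  rejects <- emptyDf(compound_id = "character", reason = "character")
  if (any(!ok)) {
    rejects <- data.frame(compound_id = ids[!ok],
                          reason = "unparseable_structure",
                          stringsAsFactors = FALSE)
    warnf("%d structure(s) could not be parsed: %s", sum(!ok),
          paste(utils::head(ids[!ok], 5), collapse = ", "))
  }
  if (!any(ok)) {
    mat <- matrix(numeric(0), 0, bits + 5L)
  } else {
    mat <- cbind(fp, tpsa = props$TPSA, slogp = props$logP, mw = props$MW,
                 hba = props$HBA1, hbd = props$HBD)
  }
  colnames(mat) <- c(sprintf("fp_%04d", seq_len(bits)),
                     "tpsa", "slogp", "mw", "hba", "hbd")
  rownames(mat) <- ids[ok]
  stopifnot(ncol(mat) == bits + 5L)
  inchi <- setNames(rep(NA_character_, sum(ok)), ids[ok])
  for (id in ids[ok]) {
    v <- tryCatch(suppressWarnings(ChemmineOB::convertFormat(
      "SMILES", "INCHI", smiles[match(id, ids)])), error = function(e) "")
    inchi[id] <- trimws(v)
  }
  structure(list(matrix = mat,
                 inchi = inchi,
                 mw = setNames(mat[, "mw"], rownames(mat)),
                 rejects = rejects),
            class = "DfiDescriptors")
}

#' @export
print.DfiDescriptors <- function(x, ...) {
  cat(sprintf("DfiDescriptors: %d compounds x %d columns (%d rejected)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$rejects)))
  invisible(x)
}

#' Tanimoto similarity between fingerprint matrices
#'
#' TC = |A and B| / |A or B| over on-bits. Pairs where both fingerprints are
#' empty get 0.
#'
#' @param a,b 0/1 matrices with one fingerprint per row (`b` defaults to
#'   `a`).
#' @return Matrix of Tanimoto coefficients, `nrow(a)` x `nrow(b)`.
#' @export
tanimotoSimilarity <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  common <- tcrossprod(a, b)
  tot <- outer(rowSums(a), rowSums(b), "+") - common
  tc <- ifelse(tot > 0, common / tot, 0)
  dimnames(tc) <- list(rownames(a), rownames(b))
  tc
}

#' Principal component analysis of the descriptor matrix
#'
#' Columns are standardised to unit variance (binary fingerprint columns
#' included) before the decomposition, so the five physicochemical columns
#' neither dominate nor vanish against the 1024 fingerprint bits. Constant
#' columns are dropped with a warning.
#'
#' @param x numeric matrix (or `DfiDescriptors`), compounds in rows.
#' @param k number of components to return (default `min(dim)`).
#' @return list: `scores` (n x k), `explained` (variance fractions,
#'   non-increasing, summing to <= 1), `rotation`, `dropped` (names of
#'   constant columns).
#' @export
pcaProjection <- function(x, k = NULL) {
  if (inherits(x, "DfiDescriptors")) x <- x$matrix
  if (nrow(x) < 2L) stopf("PCA needs at least 2 compounds")
  v <- apply(x, 2L, stats::var)
  dropped <- colnames(x)[v == 0 | is.na(v)]
  if (length(dropped)) {
    warnf("dropping %d constant column(s) before PCA", length(dropped))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  if (is.null(k)) k <- length(p$sdev)
  k <- min(k, length(p$sdev))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       rotation = p$rotation[, seq_len(k), drop = FALSE],
       dropped = dropped)
}

#' Match query compounds to reference compounds
#'
#' Exact structure matches (canonical InChI equality) are found first; only
#' queries without an exact match are then matched by similarity: Tanimoto
#' coefficient >= 0.85 on the circular fingerprint AND molecular weight
#' difference < 50 g/mol (both thresholds from `config`, both per the
#' published rule; the MW window is strict). All qualifying references are
#' returned, ordered per query by TC descending with the reference id as
#' the deterministic tie-break.
#'
#' @param queries,references `DfiDescriptors` objects from
#'   [computeDescriptors()].
#' @param config a [DfiConfig-class].
#' @return data.frame: `query_compound_id`, `reference_compound_id`,
#'   `tanimoto`, `mw_delta`, `match_kind` (`exact_structure` / `similar`).
#' @export
matchCompounds <- function(queries, references, config = dfiConfig()) {
  stopifnot(inherits(queries, "DfiDescriptors"),
            inherits(references, "DfiDescriptors"))
  tcMin <- dfiParam(config, "tc_min")
  mwWin <- dfiParam(config, "mw_window")
  nb <- dfiParam(config, "fingerprint_bits")
  out <- emptyDf(query_compound_id = "character",
                 reference_compound_id = "character",
                 tanimoto = "numeric", mw_delta = "numeric",
                 match_kind = "character")
  qids <- rownames(queries$matrix); rids <- rownames(references$matrix)
  if (length(qids) == 0L || length(rids) == 0L) return(out)
  fpq <- queries$matrix[, seq_len(nb), drop = FALSE]
  fpr <- references$matrix[, seq_len(nb), drop = FALSE]
  tc <- tanimotoSimilarity(fpq, fpr)
  dmw <- abs(outer(queries$mw[qids], references$mw[rids], "-"))

  exact <- outer(queries$inchi[qids], references$inchi[rids],
                 function(a, b) !is.na(a) & !is.na(b) & nzchar(a) & a == b)
  res <- list()
  for (i in seq_along(qids)) {
    hit <- which(exact[i, ])
    kind <- "exact_structure"
    if (length(hit) == 0L) {
      hit <- which(tc[i, ] >= tcMin & dmw[i, ] < mwWin)
      kind <- "similar"
    }
    if (length(hit) == 0L) next
    df <- data.frame(query_compound_id = qids[i],
                     reference_compound_id = rids[hit],
                     tanimoto = tc[i, hit], mw_delta = dmw[i, hit],
                     match_kind = kind, stringsAsFactors = FALSE)
    df <- df[order(-df$tanimoto, df$reference_compound_id,
                   method = "radix"), , drop = FALSE]
    res[[length(res) + 1L]] <- df
  }
  if (length(res) == 0L) return(out)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Transfer protein targets through compound matches
#'
#' Each confident interaction of a matched reference compound is copied to
#' the query compound. Links inherited through an exact structure match are
#' labelled `direct`; links inherited through a similarity match are
#' labelled `similarity`. Provenance (reference compound, match kind,
#' Tanimoto) is carried on every row, so each inferred link traces to
#' exactly one (match, reference interaction) pair.
#'
#' @param matches output of [matchCompounds()].
#' @param referenceInteractions confident interactions (from
#'   [aggregateInteractions()]) of the reference compounds.
#' @return data.frame: `compound_id` (query), `protein_id`, `link_kind`
#'   (`direct`/`similarity`), `reference_compound_id`, `tanimoto`,
#'   `representative_affinity`.
#' @export
transferTargets <- function(matches, referenceInteractions) {
  out <- emptyDf(compound_id = "character", protein_id = "character",
                 link_kind = "character", reference_compound_id = "character",
                 tanimoto = "numeric", representative_affinity = "numeric")
  if (nrow(matches) == 0L || nrow(referenceInteractions) == 0L) return(out)
  m <- merge(matches,
             referenceInteractions[, c("compound_id", "protein_id",
                                       "representative_affinity")],
             by.x = "reference_compound_id", by.y = "compound_id")
  if (nrow(m) == 0L) return(out)
  out <- data.frame(
    compound_id = m$query_compound_id,
    protein_id = m$protein_id,
    link_kind = ifelse(m$match_kind == "exact_structure", "direct",
                       "similarity"),
    reference_compound_id = m$reference_compound_id,
    tanimoto = m$tanimoto,
    representative_affinity = m$representative_affinity,
    stringsAsFactors = FALSE)
  out <- orderBy(out, c("compound_id", "protein_id",
                        "reference_compound_id"))
  rownames(out) <- NULL
  out
}

#' Expand protein links with first-degree PPI partners
#'
#' Adds interaction partners with a PPI confidence score strictly higher
#' than 400 (config `ppi_score_min`) as `indirect_ppi` links. Expansion is
#' applied only to proteins reached through exact structure matches
#' (`link_kind == "direct"`); similarity-transferred links are never
#' expanded. Partners are restricted to human, rat and mouse proteins.
#'
#' @param links data.frame with `compound_id`, `protein_id`, `link_kind`
#'   (from [transferTargets()]; rows with other link kinds pass through).
#' @param registry a [DfiRegistry-class] supplying `ppi` and `proteins`.
#' @param config a [DfiConfig-class].
#' @return `links` with appended `indirect_ppi` rows carrying `via_protein`.
#' @export
expandViaPPI <- function(links, registry, config = dfiConfig()) {
  ppi <- registry@ppi
  prt <- registry@proteins
  if (!"via_protein" %in% names(links))
    links$via_protein <- NA_character_
  if (nrow(links) == 0L || nrow(ppi) == 0L) return(links)
  keep <- ppi$score > dfiParam(config, "ppi_score_min")
  okSpecies <- prt$protein_id[prt$species %in% .validSpecies]
  keep <- keep & ppi$protein_a %in% okSpecies & ppi$protein_b %in% okSpecies
  ppi <- ppi[keep, , drop = FALSE]
  if (nrow(ppi) == 0L) return(links)
  # undirected adjacency
  adj <- rbind(data.frame(a = ppi$protein_a, b = ppi$protein_b),
               data.frame(a = ppi$protein_b, b = ppi$protein_a))
  seeds <- links[links$link_kind == "direct", , drop = FALSE]
  if (nrow(seeds) == 0L) return(links)
  m <- merge(seeds, adj, by.x = "protein_id", by.y = "a")
  if (nrow(m) == 0L) return(links)
  add <- data.frame(
    compound_id = m$compound_id,
    protein_id = m$b,
    link_kind = "indirect_ppi",
    reference_compound_id = m$reference_compound_id %||% NA_character_,
    tanimoto = m$tanimoto %||% NA_real_,
    representative_affinity = NA_real_,
    via_protein = m$protein_id.y %||% m$protein_id,
    stringsAsFactors = FALSE)
  # merge renamed the seed protein column; recover it explicitly
  add$via_protein <- m$protein_id
  add <- unique(add)
  out <- rbind(links[, names(add), drop = FALSE], add)
  out <- orderBy(out, c("compound_id", "protein_id", "link_kind"))
  rownames(out) <- NULL
  out
}

#' Map rat/mouse identifiers to human orthologs
#'
#' Human identifiers pass through unchanged; rat and mouse identifiers are
#' replaced by their human orthologs from the mapping table. One-to-many
#' ortholog rows retain every human id. Unmapped rodent ids are dropped and
#' counted.
#'
#' @param ids character vector of protein (or gene) identifiers.
#' @param species character vector, same length: `human`, `rat` or `mouse`.
#' @param orthologTable data.frame `source_id`, `source_species`,
#'   `human_id` (e.g. from [orthologs()]).
#' @return data.frame `input_id`, `species`, `human_id` (unmapped rodent
#'   ids absent), with attributes `n_unmapped` and `unmapped`.
#' @export
mapOrthologs <- function(ids, species, orthologTable) {
  stopifnot(length(ids) == length(species))
  keep <- species == "human"
  human <- data.frame(input_id = ids[keep], species = species[keep],
                      human_id = ids[keep], stringsAsFactors = FALSE)
  rodent <- data.frame(input_id = ids[!keep], species = species[!keep],
                       stringsAsFactors = FALSE)
  mapped <- merge(rodent, orthologTable,
                  by.x = c("input_id", "species"),
                  by.y = c("source_id", "source_species"))
  unmapped <- setdiff(rodent$input_id, mapped$input_id)
  if (length(unmapped))
    dfiLog(sprintf("%d rodent id(s) without human ortholog dropped",
                   length(unmapped)))
  out <- rbind(human, mapped[, c("input_id", "species", "human_id")])
  out <- orderBy(out, c("input_id", "human_id"))
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "unmapped") <- unmapped
  out
}
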