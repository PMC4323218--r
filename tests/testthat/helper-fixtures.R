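# Shared fixtures and independent brute-force oracles.

options(dfinet.quiet = TRUE)

# A minimal hand-built registry: two foods, three compounds, three proteins,
# two drugs, measurements chosen so compound C1 is in range on P1/P2 and C2
# is out of range on P1.
miniRegistry <- function() {
  dfiRegistry(
    compounds = data.frame(
      compound_id = c("C1", "C2", "C3", "DX", "DY"),
      smiles = c("c1ccc(CCO)cc1", "c1ccc(CCCO)cc1", "CCO", "CCN", "CCC"),
      mw = NA_real_,
      names = c("c-one", "c-two", "c-three", "drug-x", "drug-y"),
      origin = c("food", "food", "food", "drug", "drug"),
      stringsAsFactors = FALSE),
    foods = data.frame(
      food_id = c("apple", "apple", "kale", "kale"),
      compound_id = c("C1", "C2", "C2", "C3"),
      stringsAsFactors = FALSE),
    proteins = data.frame(
      protein_id = c("P1", "P2", "P3"),
      protein_name = c("prot one", "prot two", "prot three"),
      category = c("drug_target", "drug_target", "enzyme"),
      disease_classes = c("cancer", "cancer|neurological", ""),
      biological_system = c("signal_transduction", "metabolism",
                            "metabolism"),
      species = "human", stringsAsFactors = FALSE),
    drugs = data.frame(
      drug_id = c("DRX", "DRX", "DRY"),
      compound_id = c("DX", "DX", "DY"),
      protein_id = c("P1", "P2", "P1"),
      role = c("target", "target", "target"),
      disease_classes = "cancer", stringsAsFactors = FALSE),
    measurements = data.frame(
      compound_id = c("C1", "C1", "C2", "C3", "DX", "DX", "DY"),
      protein_id = c("P1", "P2", "P1", "P3", "P1", "P2", "P1"),
      endpoint = c("IC50", "Ki", "IC50", "inhibition", "Ki", "Ki", "Ki"),
      value = c(100, 20, 5000, 55, 10, 40, 500),
      units = c("nM", "nM", "nM", "%", "nM", "nM", "nM"),
      pchembl = c(7, 7.7, 5.3 + 1, 3, 8, 7.4, 6.3),
      stringsAsFactors = FALSE))
}

# Brute-force re-aggregation of a flagged measurement table, independent of
# the tapply-based implementation.
oracleAggregate <- function(flagged, freqMin = 0.5) {
  keys <- unique(flagged[, c("compound_id", "protein_id")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    rows <- flagged[flagged$compound_id == keys$compound_id[i] &
                      flagged$protein_id == keys$protein_id[i], ]
    freq <- sum(rows$positive) / nrow(rows)
    if (freq > freqMin) {
      aff <- rows$value_nm[rows$positive &
                             rows$endpoint %in% c("Ki", "Kd", "IC50",
                                                  "EC50")]
      aff <- aff[!is.na(aff)]
      out[[length(out) + 1L]] <- data.frame(
        compound_id = keys$compound_id[i],
        protein_id = keys$protein_id[i],
        positive_frequency = freq,
        representative_affinity = if (length(aff))
          exp(mean(log(aff))) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(compound_id = character(0),
                      protein_id = character(0),
                      positive_frequency = numeric(0),
                      representative_affinity = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$compound_id, res$protein_id), , drop = FALSE]
}

# Random flagged measurement table for property tests.
randomFlagged <- function(n, nCompounds = 12, nProteins = 8) {
  data.frame(
    compound_id = sample(sprintf("c%02d", seq_len(nCompounds)), n,
                         replace = TRUE),
    protein_id = sample(sprintf("p%02d", seq_len(nProteins)), n,
                        replace = TRUE),
    endpoint = sample(c("Ki", "IC50", "inhibition"), n, replace = TRUE),
    value_nm = 10^runif(n, 0, 4),
    positive = runif(n) < 0.6,
    stringsAsFactors = FALSE)
}

# Fabricated descriptor sets (random fingerprints) for matching oracles:
# no chemistry needed to exercise the matching logic.
fakeDescriptors <- function(ids, bits = 64, density = 0.3,
                            mw = NULL, inchi = NULL) {
  fp <- matrix(as.integer(runif(length(ids) * bits) < density),
               length(ids), bits)
  extra <- matrix(runif(length(ids) * 5), length(ids), 5)
  m <- cbind(fp, extra)
  colnames(m) <- c(sprintf("fp_%04d", seq_len(bits)),
                   "tpsa", "slogp", "mw", "hba", "hbd")
  if (is.null(mw)) mw <- runif(length(ids), 100, 500)
  m[, "mw"] <- mw
  rownames(m) <- ids
  if (is.null(inchi)) inchi <- setNames(paste0("InChI=FAKE/", ids), ids)
  structure(list(matrix = m, inchi = inchi,
                 mw = setNames(mw, ids),
                 rejects = data.frame(compound_id = character(0),
                                      reason = character(0))),
            class = "DfiDescriptors")
}

# Brute-force all-pairs similarity matching oracle.
oracleMatch <- function(q, r, tcMin = 0.85, mwWin = 50, bits = 64) {
  out <- list()
  for (qi in rownames(q$matrix)) {
    exact <- character(0)
    for (ri in rownames(r$matrix))
      if (!is.na(q$inchi[qi]) && q$inchi[qi] == r$inchi[ri])
        exact <- c(exact, ri)
    if (length(exact)) {
      for (ri in exact)
        out[[length(out) + 1L]] <- data.frame(
          query_compound_id = qi, reference_compound_id = ri,
          match_kind = "exact_structure", stringsAsFactors = FALSE)
      next
    }
    for (ri in rownames(r$matrix)) {
      a <- q$matrix[qi, seq_len(bits)]; b <- r$matrix[ri, seq_len(bits)]
      tc <- if (sum(a | b) == 0) 0 else sum(a & b) / sum(a | b)
      if (tc >= tcMin && abs(q$mw[qi] - r$mw[ri]) < mwWin)
        out[[length(out) + 1L]] <- data.frame(
          query_compound_id = qi, reference_compound_id = ri,
          match_kind = "similar", stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(query_compound_id = character(0),
                      reference_compound_id = character(0),
                      match_kind = character(0)))
  res <- do.call(rbind, out)
  res[order(res$query_compound_id, res$reference_compound_id), ,
      drop = FALSE]
}

# Exact rank-sum p-value by full enumeration of group assignments.
oracleWilcoxP <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  ws <- apply(combs, 2L, function(idx)
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
  mean(abs(ws - nx * (n - nx) / 2) >= abs(wObs - nx * (n - nx) / 2))
}

chemCallsOf <- function(reg, cfg = dfiConfig()) {
  inter <- aggregateInteractions(filterMeasurements(reg, cfg), cfg)
  foodInter <- inter[inter$compound_id %in% foods(reg)$compound_id, ,
                     drop = FALSE]
  list(interactions = inter,
       calls = classifyActivity(foodInter, reg, cfg))
}
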