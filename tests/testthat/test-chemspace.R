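cfg <- dfiConfig()

test_that("descriptor matrix has 1029 columns with sane physicochemistry", {
  tab <- data.frame(
    compound_id = c("water", "phenol", "aspirin", "water2"),
    smiles = c("O", "c1ccccc1O", "CC(=O)Oc1ccccc1C(=O)O", "O"),
    stringsAsFactors = FALSE)
  d <- computeDescriptors(tab, cfg)
  expect_equal(ncol(d$matrix), 1029L)
  expect_equal(nrow(d$matrix), 4L)
  expect_true(all(d$matrix[, 1:1024] %in% c(0L, 1L)))
  w <- d$matrix["water", ]
  expect_gte(w[["hba"]], 1)
  expect_gte(w[["hbd"]], 1)
  expect_equal(w[["mw"]], 18, tolerance = 0.05)
  # determinism: the same structure under two ids gives identical vectors
  expect_equal(unname(d$matrix["water", ]), unname(d$matrix["water2", ]))
  expect_identical(unname(d$inchi["water"]), unname(d$inchi["water2"]))
})

test_that("unparseable structures are reported, not silently dropped", {
  tab <- data.frame(compound_id = c("ok", "broken"),
                    smiles = c("CCO", "not-a-smiles((("),
                    stringsAsFactors = FALSE)
  expect_warning(d <- computeDescriptors(tab, cfg), "parse")
  expect_equal(rownames(d$matrix), "ok")
  expect_equal(d$rejects$compound_id, "broken")
  expect_equal(ncol(d$matrix), 1029L)
})

test_that("PCA standardises, orders variance and matches an eigen oracle", {
  set.seed(5)
  # rank-1 data: first component carries all variance
  base <- runif(30)
  line <- cbind(a = base, b = 2 * base, c = -base + 3)
  p1 <- pcaProjection(line)
  expect_equal(p1$explained[1L], 1, tolerance = 1e-12)

  x <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, letters[1:6]))
  p <- pcaProjection(x)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)
  # independent oracle: eigendecomposition of the correlation matrix
  ev <- eigen(cor(x), symmetric = TRUE)
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-9)
  sc <- scale(x) %*% ev$vectors
  # scores agree up to per-component sign
  for (k in 1:6)
    expect_equal(abs(p$scores[, k]), abs(sc[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  # constant columns are dropped with a warning
  expect_warning(pd <- pcaProjection(cbind(x, const = 1)), "constant")
  expect_equal(pd$dropped, "const")
})

test_that("Tanimoto is symmetric with unit self-similarity", {
  set.seed(11)
  fp <- matrix(as.integer(runif(20 * 64) < 0.3), 20, 64)
  tc <- tanimotoSimilarity(fp)
  expect_equal(tc, t(tc))
  nz <- rowSums(fp) > 0
  expect_true(all(diag(tc)[nz] == 1))
  # disjoint on-bits give zero
  a <- matrix(c(1L, 1L, 0L, 0L), 1); b <- matrix(c(0L, 0L, 1L, 1L), 1)
  expect_equal(tanimotoSimilarity(a, b)[1, 1], 0)
})

test_that("similarity matching equals a brute-force all-pairs scan", {
  set.seed(42)
  cfg64 <- dfiConfig(fingerprint_bits = 64)
  for (trial in 1:100) {
    nq <- sample(3:10, 1); nr <- sample(3:10, 1)
    q <- fakeDescriptors(sprintf("q%02d", seq_len(nq)),
                         mw = runif(nq, 100, 260))
    r <- fakeDescriptors(sprintf("r%02d", seq_len(nr)),
                         mw = runif(nr, 100, 260))
    # occasionally plant an exact structure duplicate
    if (trial %% 3 == 0) r$inchi[1L] <- q$inchi[1L]
    got <- matchCompounds(q, r, cfg64)
    want <- oracleMatch(q, r)
    gotKey <- paste(got$query_compound_id, got$reference_compound_id,
                    got$match_kind)
    wantKey <- paste(want$query_compound_id, want$reference_compound_id,
                     want$match_kind)
    expect_setequal(gotKey, wantKey)
  }
})

test_that("matches are ordered by TC with deterministic tie-break", {
  fpQ <- matrix(1L, 1, 64)
  q <- fakeDescriptors("q", mw = 200)
  q$matrix[1, 1:64] <- 1L
  r <- fakeDescriptors(c("rB", "rA", "rC"), mw = c(200, 200, 200))
  for (id in c("rB", "rA", "rC")) r$matrix[id, 1:64] <- 1L
  r$inchi[] <- paste0("other", 1:3)  # no exact match
  got <- matchCompounds(q, r, dfiConfig(fingerprint_bits = 64))
  expect_equal(got$reference_compound_id, c("rA", "rB", "rC"))
  expect_true(all(got$tanimoto == 1))
  expect_true(all(got$match_kind == "similar"))
})

test_that("an exact match suppresses similarity matches for that query", {
  q <- fakeDescriptors("q", mw = 200)
  r <- fakeDescriptors(c("rExact", "rSim"), mw = c(420, 200))
  r$inchi["rExact"] <- q$inchi["q"]
  r$matrix["rSim", 1:64] <- q$matrix["q", 1:64]
  got <- matchCompounds(q, r, dfiConfig(fingerprint_bits = 64))
  expect_equal(got$reference_compound_id, "rExact")
  expect_equal(got$match_kind, "exact_structure")
})

test_that("target transfer copies confident links with full provenance", {
  empty <- matchCompounds(fakeDescriptors("q"),
                          fakeDescriptors("r"),
                          dfiConfig(fingerprint_bits = 64))
  refInter <- data.frame(compound_id = "r1",
                         protein_id = c("P1", "P2", "P3"),
                         representative_affinity = c(1, 2, 3),
                         stringsAsFactors = FALSE)
  expect_equal(nrow(transferTargets(empty[0, ], refInter)), 0L)
  m <- data.frame(query_compound_id = "q1", reference_compound_id = "r1",
                  tanimoto = 1, mw_delta = 0,
                  match_kind = "exact_structure", stringsAsFactors = FALSE)
  got <- transferTargets(m, refInter)
  expect_equal(nrow(got), 3L)
  expect_true(all(got$link_kind == "direct"))
  expect_true(all(got$reference_compound_id == "r1"))
  # provenance is lossless: each inferred link maps to one (match,
  # interaction) pair
  expect_equal(anyDuplicated(got[, c("compound_id", "protein_id",
                                     "reference_compound_id")]), 0L)
})

test_that("planted twin compounds inherit exactly the planted target sets", {
  g <- genChemistry(3)
  reg <- g$registry
  cmp <- compounds(reg)
  qd <- computeDescriptors(cmp[cmp$origin == "food", ], cfg)
  rd <- computeDescriptors(cmp[cmp$origin == "reference_bioactive", ], cfg)
  mt <- matchCompounds(qd, rd, cfg)
  inter <- aggregateInteractions(filterMeasurements(reg, cfg), cfg)
  refInter <- inter[inter$compound_id %in%
                      cmp$compound_id[cmp$origin == "reference_bioactive"], ]
  links <- transferTargets(mt, refInter)
  tw <- g$truth$twins
  for (i in seq_len(nrow(tw))) {
    got <- sort(unique(links$protein_id[
      links$compound_id == tw$query_compound_id[i]]))
    want <- strsplit(tw$planted_targets[i], "|", fixed = TRUE)[[1L]]
    expect_equal(got, want)
  }
  expect_true(all(links$link_kind == "similarity"))
})

test_that("PPI expansion respects match kind, score cutoff and equals BFS", {
  reg0 <- miniRegistry()
  ppi <- data.frame(protein_a = c("P1", "P2"), protein_b = c("P2", "P3"),
                    score = c(400, 401), stringsAsFactors = FALSE)
  reg <- dfiRegistry(compounds = compounds(reg0), foods = foods(reg0),
                     proteins = proteins(reg0), drugs = drugs(reg0),
                     measurements = measurements(reg0)[, c(
                       "compound_id", "protein_id", "endpoint", "value",
                       "units", "pchembl")],
                     ppi = ppi)
  links <- data.frame(compound_id = c("C1", "C2"),
                      protein_id = c("P2", "P2"),
                      link_kind = c("direct", "similarity"),
                      reference_compound_id = NA_character_,
                      tanimoto = NA_real_,
                      representative_affinity = NA_real_,
                      stringsAsFactors = FALSE)
  out <- expandViaPPI(links, reg, cfg)
  added <- out[out$link_kind == "indirect_ppi", ]
  # only the direct seed expands; score 400 edge (P1-P2) is excluded
  expect_equal(added$compound_id, "C1")
  expect_equal(added$protein_id, "P3")
  expect_equal(added$via_protein, "P2")

  # random-graph equivalence with one-step BFS + score filter
  set.seed(9)
  for (trial in 1:30) {
    n <- 12
    ids <- sprintf("P%02d", 1:n)
    prt <- data.frame(protein_id = ids, protein_name = ids,
                      category = "drug_target", disease_classes = "",
                      biological_system = "", species = "human",
                      stringsAsFactors = FALSE)
    ne <- 20
    ab <- t(replicate(ne, sample(ids, 2)))
    ppiR <- data.frame(protein_a = ab[, 1], protein_b = ab[, 2],
                       score = sample(200:800, ne, replace = TRUE),
                       stringsAsFactors = FALSE)
    regR <- dfiRegistry(proteins = prt, ppi = ppiR)
    seeds <- sample(ids, 3)
    lk <- data.frame(compound_id = "q", protein_id = seeds,
                     link_kind = "direct",
                     reference_compound_id = NA_character_,
                     tanimoto = NA_real_,
                     representative_affinity = NA_real_,
                     stringsAsFactors = FALSE)
    out <- expandViaPPI(lk, regR, cfg)
    got <- sort(unique(out$protein_id[out$link_kind == "indirect_ppi"]))
    keep <- ppiR[ppiR$score > 400, ]
    want <- sort(unique(c(keep$protein_b[keep$protein_a %in% seeds],
                          keep$protein_a[keep$protein_b %in% seeds])))
    expect_equal(got, want)
  }
})

test_that("ortholog mapping passes humans through and handles gaps", {
  tab <- data.frame(source_id = c("r1", "r1", "m1"),
                    source_species = c("rat", "rat", "mouse"),
                    human_id = c("h1", "h1b", "h2"),
                    stringsAsFactors = FALSE)
  # all-human input is the identity
  out <- mapOrthologs(c("a", "b"), c("human", "human"), tab)
  expect_equal(out$human_id, c("a", "b"))
  # one rat id with mappings: replaced, one-to-many retained
  out2 <- mapOrthologs(c("r1", "hx"), c("rat", "human"), tab)
  expect_setequal(out2$human_id, c("h1", "h1b", "hx"))
  # unmapped rodent ids are dropped and counted (set-difference oracle)
  set.seed(2)
  ids <- sprintf("g%03d", 1:50)
  species <- sample(c("rat", "mouse"), 50, replace = TRUE)
  mappable <- sample(ids, 45)
  tab2 <- data.frame(source_id = mappable,
                     source_species = species[match(mappable, ids)],
                     human_id = toupper(mappable),
                     stringsAsFactors = FALSE)
  out3 <- mapOrthologs(ids, species, tab2)
  expect_equal(nrow(out3), 45L)
  expect_equal(attr(out3, "n_unmapped"), 5L)
  expect_setequal(attr(out3, "unmapped"), setdiff(ids, mappable))
})
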