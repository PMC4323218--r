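cfg <- dfiConfig()

# registry with configurable (food -> protein) activity for network tests
callsFixture <- function(foodProteins) {
  foodsDf <- do.call(rbind, lapply(names(foodProteins), function(f)
    data.frame(food_id = f, compound_id = paste0("c_", f),
               stringsAsFactors = FALSE)))
  prots <- sort(unique(unlist(foodProteins)))
  reg <- dfiRegistry(
    compounds = data.frame(compound_id = foodsDf$compound_id, smiles = "",
                           mw = NA_real_, names = "", origin = "food",
                           stringsAsFactors = FALSE),
    foods = foodsDf,
    proteins = data.frame(protein_id = prots, protein_name = prots,
                          category = "drug_target", disease_classes = "",
                          biological_system = "", species = "human",
                          stringsAsFactors = FALSE))
  calls <- do.call(rbind, lapply(names(foodProteins), function(f)
    if (length(foodProteins[[f]]))
      data.frame(compound_id = paste0("c_", f),
                 protein_id = foodProteins[[f]], is_active = TRUE,
                 basis = "drug_range", range_min = NA_real_,
                 range_max = NA_real_, category_mean = NA_real_,
                 representative_affinity = 10, stringsAsFactors = FALSE)))
  list(registry = reg, calls = calls)
}

test_that("food-food edges are exact shared-protein counts", {
  fx <- callsFixture(list(A = c("P1", "P2", "P3"),
                          B = c("P1", "P2", "P3", "P4"),
                          C = c("P9")))
  net <- buildFoodNetwork(fx$calls, fx$registry)
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)           # C is disjoint from A and B
  expect_equal(e$from, "A"); expect_equal(e$to, "B")
  expect_equal(e$weight, 3L)
  n <- networkNodes(net)
  expect_equal(n$n_interacting_proteins[n$food_id == "B"], 4L)
  expect_equal(n$n_bioactive_compounds[n$food_id == "B"], 1L)
})

test_that("food network matches pairwise set-intersection oracle", {
  set.seed(30)
  prots <- sprintf("P%02d", 1:20)
  sets <- setNames(lapply(1:30, function(i)
    sample(prots, sample(0:8, 1))), sprintf("F%02d", 1:30))
  fx <- callsFixture(sets)
  net <- buildFoodNetwork(fx$calls, fx$registry)
  e <- networkEdges(net)
  ids <- names(sets)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    w <- length(intersect(sets[[ids[i]]], sets[[ids[j]]]))
    row <- e[e$from == ids[i] & e$to == ids[j], ]
    if (w == 0) expect_equal(nrow(row), 0L) else
      expect_equal(row$weight, w)
  }
  # weights are symmetric by construction of the undirected edge list
  g <- asIgraph(net)
  expect_false(igraph::is_directed(g))
})

targetRegistry <- function(nFoodsPerTarget) {
  # two targets T1, T2 in class "cancer"; drugs D1..D3 target both; foods
  # hold distinct active compounds per target
  prt <- data.frame(protein_id = c("T1", "T2"),
                    protein_name = c("t-one", "t-two"),
                    category = "drug_target", disease_classes = "cancer",
                    biological_system = "", species = "human",
                    stringsAsFactors = FALSE)
  nd <- 1L
  drugsDf <- data.frame(drug_id = "D1", compound_id = "dc1",
                        protein_id = c("T1", "T2"), role = "target",
                        disease_classes = "cancer",
                        stringsAsFactors = FALSE)
  foodsIds <- sprintf("F%d", seq_len(max(nFoodsPerTarget)))
  cmp <- data.frame(
    compound_id = c("dc1", paste0("c", foodsIds)), smiles = "",
    mw = NA_real_, names = "",
    origin = c("drug", rep("food", length(foodsIds))),
    stringsAsFactors = FALSE)
  foodsDf <- data.frame(food_id = foodsIds,
                        compound_id = paste0("c", foodsIds),
                        stringsAsFactors = FALSE)
  reg <- dfiRegistry(compounds = cmp, foods = foodsDf, proteins = prt,
                     drugs = drugsDf)
  calls <- rbind(
    data.frame(compound_id = paste0("c", foodsIds[seq_len(
      nFoodsPerTarget[1L])]), protein_id = "T1", stringsAsFactors = FALSE),
    data.frame(compound_id = paste0("c", foodsIds[seq_len(
      nFoodsPerTarget[2L])]), protein_id = "T2", stringsAsFactors = FALSE))
  calls$is_active <- TRUE
  calls$basis <- "drug_range"
  calls$range_min <- NA_real_; calls$range_max <- NA_real_
  calls$category_mean <- NA_real_; calls$representative_affinity <- 10
  list(registry = reg, calls = calls)
}

test_that("target-target edges require >= 3 shared drug-food pairs", {
  # one drug x three shared foods = 3 shared pairs -> edge
  fx3 <- targetRegistry(c(3L, 3L))
  net3 <- buildTargetNetwork(fx3$calls, fx3$registry, "cancer", cfg)
  expect_equal(nrow(networkEdges(net3)), 1L)
  expect_equal(networkEdges(net3)$weight, 3L)
  expect_equal(net3@nTargetsAffected, 2L)
  # only two shared pairs -> no edge, nodes remain
  fx2 <- targetRegistry(c(2L, 2L))
  net2 <- buildTargetNetwork(fx2$calls, fx2$registry, "cancer", cfg)
  expect_equal(nrow(networkEdges(net2)), 0L)
  expect_equal(nrow(networkNodes(net2)), 2L)
  # unknown disease class: empty network with a warning
  expect_warning(net0 <- buildTargetNetwork(fx2$calls, fx2$registry,
                                            "unheard-of", cfg),
                 "no drug target")
  expect_equal(nrow(networkNodes(net0)), 0L)
})

test_that("planted pair-count matrix thresholds into the adjacency", {
  g <- genChemistry(13, params = list(flip_rate = 0, affinity_sigma = 0))
  cc <- chemCallsOf(g$registry, cfg)
  sets <- g$truth$target_pair_members
  prt <- proteins(g$registry)
  for (cl in c("cancer", "neurological")) {
    net <- buildTargetNetwork(cc$calls, g$registry, cl, cfg)
    inClass <- vapply(strsplit(prt$disease_classes, "|", fixed = TRUE),
                      function(s) cl %in% s, logical(1))
    targets <- sort(prt$protein_id[prt$category == "drug_target" & inClass])
    e <- networkEdges(net)
    for (i in seq_along(targets)) for (j in seq_along(targets)) {
      if (i >= j) next
      si <- if (is.null(sets[[targets[i]]])) character(0) else
        sets[[targets[i]]]
      sj <- if (is.null(sets[[targets[j]]])) character(0) else
        sets[[targets[j]]]
      w <- length(intersect(si, sj))
      row <- e[e$from == targets[i] & e$to == targets[j], ]
      if (w >= 3) expect_equal(row$weight, w) else
        expect_equal(nrow(row), 0L)
    }
  }
})

test_that("top-k edge display keeps per-node heaviest with lexical ties", {
  mkNet <- function(edges) {
    ids <- sort(unique(c(edges$from, edges$to)))
    new("FoodNetwork",
        nodes = data.frame(food_id = ids, n_bioactive_compounds = 0L,
                           n_interacting_proteins = 0L,
                           stringsAsFactors = FALSE),
        edges = edges)
  }
  # a node with 3 edges and k = 5 keeps everything
  e3 <- data.frame(from = "A", to = c("B", "C", "D"), weight = c(3L, 2L, 1L),
                   stringsAsFactors = FALSE)
  expect_equal(nrow(networkEdges(topKEdges(mkNet(e3), 5))), 3L)
  # per-node ranking of equal weights is lexical on the edge key; with
  # union semantics an edge survives if either endpoint keeps it, so on an
  # equal-weight triangle at k = 1 each node keeps its lexically first
  # incident edge and only B|C is dropped
  e7 <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                   weight = 2L, stringsAsFactors = FALSE)
  kept <- networkEdges(topKEdges(mkNet(e7), 1))
  expect_setequal(paste(kept$from, kept$to), c("A B", "A C"))
  # a leaf endpoint keeps its only edge even when the hub ranks it last
  eStar <- data.frame(from = "A", to = sprintf("N%d", 1:7), weight = 2L,
                      stringsAsFactors = FALSE)
  expect_equal(nrow(networkEdges(topKEdges(mkNet(eStar), 5))), 7L)
  # idempotence and brute-force equivalence on random graphs
  set.seed(77)
  for (trial in 1:30) {
    ids <- sprintf("V%02d", 1:10)
    ne <- 25
    pairs <- unique(t(apply(
      matrix(replicate(ne, sample(ids, 2)), nrow = 2), 2, sort)))
    e <- data.frame(from = pairs[, 1], to = pairs[, 2],
                    weight = sample(1:5, nrow(pairs), replace = TRUE),
                    stringsAsFactors = FALSE)
    k <- sample(1:4, 1)
    net <- mkNet(e)
    got <- networkEdges(topKEdges(net, k))
    twice <- networkEdges(topKEdges(topKEdges(net, k), k))
    expect_equal(got, twice)
    # oracle: per-node sort and take union
    key <- paste(e$from, e$to, sep = "|")
    wantKeep <- rep(FALSE, nrow(e))
    for (v in ids) {
      inc <- which(e$from == v | e$to == v)
      if (!length(inc)) next
      ord <- inc[order(-e$weight[inc], key[inc])]
      wantKeep[head(ord, k)] <- TRUE
    }
    expect_setequal(paste(got$from, got$to), paste(e$from, e$to)[wantKeep])
  }
})

test_that("strongest-binder annotation reproduces the worked examples", {
  reg <- inPaperFixture()
  cc <- chemCallsOf(reg, cfg)
  a1 <- annotateStrongestBinder(cc$calls, reg, "aromatase", "pd",
                                interactions = cc$interactions)
  expect_equal(a1$best_compound, "naringenin")
  expect_equal(a1$best_affinity_nm, 2.9)
  expect_equal(a1$endpoint, "IC50")
  expect_true(grepl("licorice", a1$foods))
  expect_true(grepl("Letrozole", a1$drugs))
  a2 <- annotateStrongestBinder(cc$calls, reg, "aromatase", "pk",
                                interactions = cc$interactions)
  expect_equal(a2$best_affinity_nm, 1000)
  expect_equal(a2$protein_id, "AROMATASE_E")
  # single candidate is selected regardless of affinity
  a3 <- annotateStrongestBinder(cc$calls, reg, "D(2) dopamine receptor",
                                "pd")
  expect_equal(a3$best_compound, "aporphine")
  expect_equal(a3$best_affinity_nm, 527)
  # no active phytochemical in context -> NULL with warning
  expect_warning(
    a4 <- annotateStrongestBinder(cc$calls, reg, "carbonic anhydrase",
                                  "pk"),
    "no pk-context")
  expect_null(a4)
  # display truncation caps the lists but not the selection
  a5 <- annotateStrongestBinder(cc$calls, reg, "aromatase", "pd",
                                topN = 3)
  expect_lte(length(strsplit(a5$drugs, "|", fixed = TRUE)[[1L]]), 3L)
  expect_equal(a5$best_affinity_nm, 2.9)
})

test_that("enrichment follows exp = (tpc/tdt) * tpa with both tests", {
  inputs <- data.frame(category = c("zero", "all", "mid"),
                       tpc = c(0, 1806, 100),
                       observed = c(0, 186, 25),
                       stringsAsFactors = FALSE)
  enr <- categoryEnrichment(inputs, tdt = 1806, tpa = 186)
  expect_equal(enr$expected[enr$category == "zero"], 0)
  expect_equal(enr$expected[enr$category == "all"], 186)
  expect_equal(enr$expected[enr$category == "mid"], 100 * 186 / 1806)
  expect_equal(enr$expected[enr$category == "mid"], 10.2990, tolerance = 1e-4)
  expect_true(is.na(enr$binom_p[enr$category == "zero"]))
  expect_false(is.null(attr(enr, "t_test")))
  expect_error(categoryEnrichment(inputs, tdt = 0, tpa = 5), "tdt")
  # expected counts sum to tpa when categories partition the targets
  set.seed(4)
  tpc <- c(400, 700, 706)
  obs <- c(40, 80, 66)
  enr2 <- categoryEnrichment(
    data.frame(category = letters[1:3], tpc = tpc, observed = obs),
    tdt = sum(tpc), tpa = sum(obs))
  expect_equal(sum(enr2$expected), sum(obs))
})

test_that("network export writes edge list, node table and GraphML", {
  fx <- callsFixture(list(A = c("P1", "P2"), B = c("P1", "P2"), C = "P1"))
  net <- buildFoodNetwork(fx$calls, fx$registry)
  pref <- file.path(withr::local_tempdir(), "net")
  files <- writeNetwork(net, pref)
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(files[3L], format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
  expect_equal(igraph::gsize(g), nrow(networkEdges(net)))
})
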