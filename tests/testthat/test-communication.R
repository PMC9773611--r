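test_that("pair and total affinity match hand sums and the brute-force oracle", {
  e1 <- c(L = 2, R = 0); e2 <- c(L = 0, R = 3)
  expect_equal(pairAffinity(e1, e2, list(ligand = "L", receptor = "R")), 6)
  expect_equal(pairAffinity(e2, e1, list(ligand = "L", receptor = "R")), 0)
  # hand example: one pair, two cells
  e <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("L", "R"), c("c1", "c2")))
  db <- data.frame(ligand = "L", receptor = "R")
  a <- affinityMatrix(totalAffinity(e, db))
  expect_equal(a["c1", "c2"], 1)
  expect_equal(a["c1", "c1"], 0)
  # duplicated pair doubles affinity when deduplication is off
  a2 <- affinityMatrix(totalAffinity(e, rbind(db, db), dedupe = FALSE))
  expect_equal(a2, 2 * a)
  expect_equal(affinityMatrix(totalAffinity(e, rbind(db, db))), a)
  # randomized 50-cell x 30-pair fixture against the quadruple loop
  set.seed(14)
  genes <- paste0("g", 1:70)
  em <- matrix(rexp(70 * 50), 70, 50,
               dimnames = list(genes, paste0("c", 1:50)))
  db30 <- data.frame(ligand = sample(genes, 30),
                     receptor = sample(genes, 30))
  aff <- totalAffinity(em, db30)
  expect_lt(max(abs(affinityMatrix(aff) - oracleTotalAffinity(em, db30))),
            1e-8)
  # low-rank block path equals the materialized path
  affLow <- totalAffinity(em, db30, maxCells = 10)
  expect_equal(length(affLow@matrix), 0)
  gDense <- affinityKNN(aff, k = 5)
  gLow <- affinityKNN(affLow, k = 5, blockSize = 7)
  expect_identical(graphEdgeSet(gDense), graphEdgeSet(gLow))
  expect_error(totalAffinity(em, data.frame(ligand = "nope",
                                            receptor = "nah")), "no ligand")
})

test_that("affinity is permutation-invariant and scales quadratically", {
  set.seed(15)
  genes <- paste0("g", 1:30)
  e <- matrix(rexp(30 * 20), 30, 20,
              dimnames = list(genes, paste0("c", 1:20)))
  db <- data.frame(ligand = sample(genes, 10), receptor = sample(genes, 10))
  a <- affinityMatrix(totalAffinity(e, db))
  pg <- sample(30); pc <- sample(20)
  aPerm <- affinityMatrix(totalAffinity(e[pg, pc], db))
  expect_equal(aPerm, a[pc, pc])
  # scaling expression by c scales affinities by c^2, contributions unchanged
  a3 <- affinityMatrix(totalAffinity(3 * e, db))
  expect_equal(a3, 9 * a)
  cl <- rep(c("X", "Y"), each = 10)
  names(cl) <- colnames(e)
  c1 <- lrContribution(e, cl, db, "X", "Y")
  c2 <- lrContribution(3 * e, cl, db, "X", "Y")
  expect_equal(c1$contribution, c2$contribution)
  expect_equal(c2$affinity, 9 * c1$affinity)
})

test_that("affinity kNN keeps the strongest partners with deterministic ties", {
  # 3 cells, k = 1: hand-enumerated union graph
  lig <- matrix(c(1, 0, 0,
                  5, 2, 0), 3, 2,
                dimnames = list(c("c1", "c2", "c3"), NULL))
  # craft an explicit affinity matrix instead: A(1,2)=5, A(1,3)=1, A(2,3)=2
  aff <- methods::new("AffinityMatrix",
                      ligandExpr = lig, receptorExpr = lig * 0,
                      matrix = matrix(c(0, 5, 1,
                                        5, 0, 2,
                                        1, 2, 0), 3, 3,
                                      dimnames = list(paste0("c", 1:3),
                                                      paste0("c", 1:3))),
                      pairs = data.frame(ligand = "x", receptor = "y"))
  g <- affinityKNN(aff, k = 1)
  expect_identical(graphEdgeSet(g), rbind(c(1L, 2L), c(2L, 3L)))
  # identical cells: all off-diagonal affinities tie; neighbor = first cell id
  affT <- methods::new("AffinityMatrix",
                       ligandExpr = lig, receptorExpr = lig * 0,
                       matrix = matrix(1, 3, 3) - diag(3),
                       pairs = data.frame(ligand = "x", receptor = "y"))
  gt <- affinityKNN(affT, k = 1)
  expect_identical(graphEdgeSet(gt), rbind(c(1L, 2L), c(1L, 3L)))
  # k = n - 1 gives the complete graph
  expect_warning(gc3 <- affinityKNN(affT, k = 3), "complete")
  expect_equal(igraph::ecount(gc3), 3)
})

test_that("cluster connectivity equals the direct observed/expected count", {
  # two clusters with no inter-cluster edges
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- paste0("c", 1:10)
  cl <- stats::setNames(rep(c("A", "B"), each = 5), paste0("c", 1:10))
  comm <- clusterConnectivity(g, cl)
  expect_equal(connectivity(comm)["A", "B"], 0)
  expect_false(significanceMask(comm)["A", "B"])
  # random 100-cell fixture against direct counting
  set.seed(16)
  gr <- igraph::sample_gnm(100, 400)
  igraph::V(gr)$name <- paste0("c", 1:100)
  clr <- stats::setNames(sample(c("A", "B", "C"), 100, replace = TRUE),
                         paste0("c", 1:100))
  commR <- clusterConnectivity(gr, clr)
  em <- igraph::as_edgelist(gr, names = TRUE)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    obs <- sum((clr[em[, 1]] == pair[1] & clr[em[, 2]] == pair[2]) |
                 (clr[em[, 1]] == pair[2] & clr[em[, 2]] == pair[1]))
    expected <- 400 * sum(clr == pair[1]) * sum(clr == pair[2]) / choose(100, 2)
    expect_equal(connectivity(commR)[pair[1], pair[2]], obs / expected,
                 tolerance = 1e-12)
  }
  # symmetry and mask consistency
  expect_equal(connectivity(commR), t(connectivity(commR)))
  msk <- significanceMask(commR)
  expect_true(all(msk == (connectivity(commR) > 0.05 &
                            !diag(TRUE, 3))))
})

test_that("closeness centrality matches Floyd-Warshall and ranks hubs first", {
  # path A - B - C with unit connectivities: B most central
  conn <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  conn["A", "B"] <- conn["B", "A"] <- 1
  conn["B", "C"] <- conn["C", "B"] <- 1
  comm <- methods::new("CommunicationGraph", connectivity = conn,
                       cutoff = 0.05,
                       clusterSizes = stats::setNames(rep(10L, 3),
                                                      LETTERS[1:3]),
                       nEdges = 100L)
  cc <- closenessCentrality(comm)
  expect_identical(cc$cluster[1], "B")
  # 5-node weighted fixture against the all-pairs shortest-path oracle
  set.seed(17)
  w5 <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  for (i in 1:4) for (j in (i + 1):5)
    if (stats::runif(1) < 0.7) w5[i, j] <- w5[j, i] <- stats::runif(1, 0.06, 2)
  comm5 <- methods::new("CommunicationGraph", connectivity = w5,
                        cutoff = 0.05,
                        clusterSizes = stats::setNames(rep(10L, 5),
                                                       LETTERS[1:5]),
                        nEdges = 100L)
  cc5 <- closenessCentrality(comm5)
  lw <- ifelse(w5 > 0.05, 1 / w5, Inf)
  d <- oracleFloydWarshall(lw)
  ref <- vapply(1:5, function(i) {
    di <- d[i, -i]; r <- is.finite(di)
    if (!any(r)) 0 else sum(r) / sum(di[r])
  }, numeric(1))
  expect_equal(cc5$closeness[match(LETTERS[1:5], cc5$cluster)], ref,
               tolerance = 1e-12)
  # planted hub cohort: hub is rank 1 and all planted axes are significant
  sce <- defaultCohort(); tr <- cohortTruth(sce)
  aff <- totalAffinity(sce, tr$lrDatabase)
  g <- affinityKNN(aff, k = 15)
  commH <- clusterConnectivity(g, tr$cellClusters)
  ccH <- closenessCentrality(commH)
  expect_identical(ccH$cluster[1], tr$hubCluster)
  planted <- connectivity(commH)[cbind(tr$lrAxes$sender, tr$lrAxes$receiver)]
  expect_true(all(planted > 0.05))
  # isolated cluster gets closeness 0
  connI <- conn; connI["C", ] <- connI[, "C"] <- 0
  commI <- methods::new("CommunicationGraph", connectivity = connI,
                        cutoff = 0.05,
                        clusterSizes = stats::setNames(rep(10L, 3),
                                                       LETTERS[1:3]),
                        nEdges = 100L)
  ccI <- closenessCentrality(commI)
  expect_equal(ccI$closeness[ccI$cluster == "C"], 0)
})

test_that("ligand-receptor contributions normalize to 1 and match the double loop", {
  set.seed(18)
  genes <- paste0("g", 1:80)
  e <- matrix(rexp(80 * 30), 80, 30,
              dimnames = list(genes, paste0("c", 1:30)))
  cl <- stats::setNames(rep(c("M", "N", "O"), each = 10), colnames(e))
  db <- data.frame(ligand = sample(genes, 30), receptor = sample(genes, 30))
  tab <- lrContribution(e, cl, db, "M", "N")
  expect_equal(tab$affinity, oracleLRMeans(e, cl, db, "M", "N"),
               tolerance = 1e-10)
  expect_equal(sum(tab$contribution), 1, tolerance = 1e-9)
  # single pair gets contribution 1; stated two-pair arithmetic
  t1 <- lrContribution(e, cl, db[1, , drop = FALSE], "M", "N")
  expect_equal(t1$contribution, 1)
  e2 <- matrix(c(2, 1, 3, 2), 2, 2,
               dimnames = list(c("gl", "gr"), c("c1", "c2")))
  # construct means so pair affinities are 6 and 4
  eM <- matrix(c(3, 2,
                 1, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("L1", "L2"), c("m1", "m2")))
  eFull <- rbind(eM, R1 = c(0, 0), R2 = c(0, 0))
  eN <- matrix(c(0, 0, 0, 0, 2, 2, 4, 4), 4, 2, byrow = TRUE,
               dimnames = list(c("L1", "L2", "R1", "R2"), c("n1", "n2")))
  eAll <- cbind(eFull, eN)
  clAll <- stats::setNames(c("M", "M", "N", "N"), colnames(eAll))
  t2 <- lrContribution(eAll, clAll,
                       data.frame(ligand = c("L1", "L2"),
                                  receptor = c("R1", "R2")), "M", "N")
  expect_equal(t2$affinity, c(5, 4))      # mean(3,2)*2 and mean(1,1)*4
  expect_equal(t2$contribution, c(5 / 9, 4 / 9))
  # directionality: M->N and N->M differ, their sums are symmetric
  tMN <- lrContribution(e, cl, db, "M", "N")
  tNM <- lrContribution(e, cl, db, "N", "M")
  expect_false(isTRUE(all.equal(tMN$affinity, tNM$affinity)))
  totalBoth <- sum(tMN$affinity) + sum(tNM$affinity)
  aff <- affinityMatrix(totalAffinity(e, db))
  mIdx <- which(cl == "M"); nIdx <- which(cl == "N")
  expect_equal(totalBoth,
               sum(aff[mIdx, nIdx]) / length(mIdx) / length(nIdx),
               tolerance = 1e-10)
  # zero expression: empty result with a warning
  ez <- e * 0
  expect_warning(tz <- lrContribution(ez, cl, db, "M", "N"), "zero")
  expect_equal(nrow(tz), 0)
})
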