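# Correlation networks: construction, core intersection, first neighbors,
# topology metrics, exports and growth associations.

test_that("pairwise correlations match the direct formula", {
  x <- randomMatrix(12, 5, seed = 1)
  pc <- pairwiseCorrelations(x)
  for (i in 1:4) for (j in (i + 1):5) {
    r <- cor(x[, i], x[, j])
    expect_equal(pc$r[i, j], r, tolerance = 1e-12)
    tstat <- r * sqrt((12 - 2) / (1 - r^2))
    expect_equal(pc$p[i, j], 2 * pt(-abs(tstat), df = 10), tolerance = 1e-12)
    # cross-check against cor.test
    expect_equal(pc$p[i, j], cor.test(x[, i], x[, j])$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(pc$r)), rep(1, 5))
  expect_equal(unname(diag(pc$p)), rep(0, 5))
  # affine copies correlate perfectly with p = 0
  xa <- cbind(a = x[, 1], b = 3 * x[, 1] + 2)
  pca <- pairwiseCorrelations(xa)
  expect_equal(pca$r["a", "b"], 1)
  expect_equal(pca$p["a", "b"], 0)
  expect_error(pairwiseCorrelations(x[1:3, ]), "4 samples")
})

test_that("network construction thresholds edges and drops isolated nodes", {
  x <- randomMatrix(20, 6, seed = 2)
  x[, 2] <- x[, 1] + rnorm(20, 0, 0.05)   # one strong pair
  pc <- pairwiseCorrelations(x)
  net <- buildPeriodNetwork(pc, rThreshold = 0.85, fdrCutoff = 0.05,
                            period = "A")
  e <- networkEdges(net)
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$from, e$to), c("m01", "m02"))
  expect_equal(e$sign, "pos")
  expect_setequal(networkNodes(net), c("m01", "m02"))   # isolates dropped
  # an impossible threshold empties the network
  none <- buildPeriodNetwork(pc, rThreshold = 1, fdrCutoff = 0.05)
  expect_equal(length(networkNodes(none)), 0L)
  expect_equal(nrow(networkEdges(none)), 0L)
})

test_that("edge counts are monotone in both thresholds", {
  study <- generateStudy(syntheticConfig(seed = 7, nMetabolites = 40))
  x <- metaboliteMatrix(normalizeTIC(study$experiment))
  p <- periodLabels(study$experiment)
  pc <- pairwiseCorrelations(x[p == "A", ])
  nEdges <- function(rt, fc) nrow(networkEdges(buildPeriodNetwork(pc, rt, fc)))
  expect_gte(nEdges(0.5, 0.05), nEdges(0.85, 0.05))
  expect_gte(nEdges(0.85, 0.05), nEdges(0.95, 0.05))
  expect_gte(nEdges(0.85, 0.05), nEdges(0.85, 0.001))
})

test_that("network construction is invariant to sample order", {
  x <- randomMatrix(16, 8, seed = 3)
  x[, 4] <- x[, 7] + rnorm(16, 0, 0.1)
  set.seed(5)
  perm <- sample(16)
  n1 <- buildPeriodNetwork(pairwiseCorrelations(x), 0.5, 0.2)
  n2 <- buildPeriodNetwork(pairwiseCorrelations(x[perm, ]), 0.5, 0.2)
  expect_equal(networkEdges(n1), networkEdges(n2), tolerance = 1e-12)
  expect_identical(networkNodes(n1), networkNodes(n2))
})

test_that("the planted clique is fully connected within every period", {
  study <- generateStudy(syntheticConfig(seed = 15))
  x <- metaboliteMatrix(normalizeTIC(study$experiment))
  p <- periodLabels(study$experiment)
  members <- study$truth$cliques[[1]]$members
  nets <- lapply(c("A", "B", "C"), function(per) {
    buildPeriodNetwork(pairwiseCorrelations(x[p == per, ]),
                       rThreshold = 0.85, fdrCutoff = 0.05, period = per)
  })
  for (net in nets) {
    keys <- edgeKeys(net)
    pairs <- combn(sort(members), 2)
    wanted <- paste(pairs[1, ], pairs[2, ], sep = "\r")
    expect_true(all(wanted %in% keys))
  }
  # and the core intersection recovers exactly the planted clique
  core <- coreNetwork(nets[[1]], nets[[2]], nets[[3]])
  expect_setequal(networkNodes(core), members)
  expect_equal(nrow(networkEdges(core)), choose(length(members), 2))
})

test_that("null data produce (almost) no edges at the working thresholds", {
  set.seed(21)
  x <- matrix(rnorm(36 * 50), 36, 50,
              dimnames = list(NULL, sprintf("m%02d", 1:50)))
  net <- buildPeriodNetwork(pairwiseCorrelations(x), 0.85, 0.05)
  expect_lte(nrow(networkEdges(net)), 1L)
})

test_that("core intersection summarises attributes and is idempotent", {
  nA <- networkFromEdges(c("a", "b", "a"), c("b", "c", "d"), period = "A",
                         r = c(0.9, 0.92, 0.88))
  nB <- networkFromEdges(c("a", "b"), c("b", "c"), period = "B",
                         r = c(0.95, 0.9))
  nC <- networkFromEdges(c("a", "x"), c("b", "y"), period = "C",
                         r = c(0.85, 0.9))
  core <- coreNetwork(nA, nB, nC)
  e <- networkEdges(core)
  expect_equal(nrow(e), 1L)                    # only a-b survives all periods
  expect_equal(c(e$from, e$to), c("a", "b"))
  expect_equal(e$r, mean(c(0.9, 0.95, 0.85)))
  expect_equal(networkPeriod(core), "core")
  # intersecting the core with itself changes nothing topological
  again <- coreNetwork(core, core, core)
  expect_setequal(networkNodes(again), networkNodes(core))
  expect_equal(edgeKeys(again), edgeKeys(core))
  # disjoint networks give an empty core
  nZ <- networkFromEdges("u", "v", period = "B")
  empty <- coreNetwork(nA, nZ, nC)
  expect_equal(length(networkNodes(empty)), 0L)
  expect_equal(nrow(networkEdges(empty)), 0L)
})

test_that("node-mode core keeps persistent hubs even if partners rotate", {
  # node "h" has some qualifying edge in all periods, but no single edge
  # persists across all three
  nA <- networkFromEdges("h", "p1", period = "A")
  nB <- networkFromEdges("h", "p2", period = "B")
  nC <- networkFromEdges("h", "p3", period = "C")
  edgeCore <- coreNetwork(nA, nB, nC, mode = "edge")
  nodeCore <- coreNetwork(nA, nB, nC, mode = "node")
  expect_equal(length(networkNodes(edgeCore)), 0L)
  expect_equal(networkNodes(nodeCore), "h")
  expect_equal(nrow(networkEdges(nodeCore)), 0L)
})

test_that("first neighbors induce the core plus adjacent nodes", {
  # period network is a path a-b-c-d-e; core is just {b}
  per <- networkFromEdges(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                          period = "A")
  core <- methods::new("PeriodNetwork", period = "core", nodes = "b",
                       edges = networkEdges(per)[0, ])
  fn <- firstNeighbors(core, per)
  expect_setequal(networkNodes(fn), c("a", "b", "c"))
  keys <- edgeKeys(fn)
  expect_setequal(keys, c("a\rb", "b\rc"))
  expect_equal(networkPeriod(fn), "A_first_neighbors")
  # a core node absent from the period contributes only itself
  lonely <- methods::new("PeriodNetwork", period = "core", nodes = "z",
                         edges = networkEdges(per)[0, ])
  fl <- firstNeighbors(lonely, per)
  expect_equal(networkNodes(fl), "z")
  expect_equal(nrow(networkEdges(fl)), 0L)
  # first neighbors of the whole period network is the identity
  full <- methods::new("PeriodNetwork", period = "core",
                       nodes = networkNodes(per), edges = networkEdges(per))
  expect_equal(edgeKeys(firstNeighbors(full, per)), edgeKeys(per))
})

test_that("topology metrics reproduce closed forms for K3 and a star", {
  k3 <- networkFromEdges(c("a", "a", "b"), c("b", "c", "c"))
  mk3 <- topologyMetrics(k3)
  expect_equal(mk3$n_nodes, 3)
  expect_equal(mk3$n_edges, 3)
  expect_equal(mk3$avg_neighbors, 2)
  expect_equal(mk3$diameter, 1)
  expect_equal(mk3$radius, 1)
  expect_equal(mk3$char_path_length, 1)
  expect_equal(mk3$clustering_coefficient, 1)
  expect_equal(mk3$density, 1)
  expect_equal(mk3$heterogeneity, 0)
  expect_equal(mk3$centralization, 0)
  expect_equal(mk3$n_components, 1)

  # star K_{1,4}: hub h, leaves l1..l4
  star <- networkFromEdges(rep("h", 4), paste0("l", 1:4))
  ms <- topologyMetrics(star)
  expect_equal(ms$n_nodes, 5)
  expect_equal(ms$n_edges, 4)
  expect_equal(ms$diameter, 2)
  expect_equal(ms$radius, 1)
  expect_equal(ms$char_path_length, (4 * 1 + 6 * 2) / 10)
  expect_equal(ms$clustering_coefficient, 0)
  expect_equal(ms$density, 0.4)
  expect_equal(ms$centralization, 1)
  # degrees (4,1,1,1,1): population SD / mean = sqrt(1.44)/1.6 = 0.75
  expect_equal(ms$heterogeneity, 0.75)
  expect_equal(ms$n_components, 1)

  expect_error(topologyMetrics(networkFromAdjacency(matrix(0, 0, 0))),
               "empty")
})

test_that("metrics handle disconnected graphs and isolated nodes", {
  # triangle plus an isolated node
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[1, 3] <- adj[3, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  net <- networkFromAdjacency(adj)
  m <- topologyMetrics(net)
  expect_equal(m$n_components, 2)
  expect_equal(m$diameter, 1)            # largest component is the triangle
  expect_equal(m$char_path_length, 1)    # only connected pairs counted
  expect_equal(m$clustering_coefficient, 3 / 4)
  expect_equal(m, bruteGraphMetrics(adj), tolerance = 1e-12)
})

test_that("SIF export writes signed triples and round-trips topology", {
  dir <- withr_like_tempdir()
  k3 <- networkFromEdges(c("a", "a", "b"), c("b", "c", "c"),
                         r = c(0.9, -0.88, 0.92))
  path <- file.path(dir, "k3.sif")
  exportNetwork(k3, path, format = "sif")
  lines <- readLines(path)
  expect_equal(length(lines), 3L)
  expect_true("a\tneg\tc" %in% lines)
  back <- readNetwork(path, format = "sif", period = "A")
  expect_setequal(networkNodes(back), networkNodes(k3))
  expect_equal(edgeKeys(back), edgeKeys(k3))
  expect_equal(networkEdges(back)$sign, networkEdges(k3)$sign)
  expect_true(all(is.na(networkEdges(back)$r)))

  # empty network round-trips as empty
  empty <- newPeriodNetwork("B", character(0), emptyEdgeFrame())
  ep <- file.path(dir, "empty.sif")
  exportNetwork(empty, ep, format = "sif")
  backEmpty <- readNetwork(ep, format = "sif")
  expect_equal(length(networkNodes(backEmpty)), 0L)
  expect_equal(nrow(networkEdges(backEmpty)), 0L)

  # isolated nodes survive as single-name lines
  iso <- methods::new("PeriodNetwork", period = "A", nodes = c("a", "b", "z"),
                      edges = networkEdges(networkFromEdges("a", "b")))
  ip <- file.path(dir, "iso.sif")
  exportNetwork(iso, ip, format = "sif")
  backIso <- readNetwork(ip, format = "sif")
  expect_setequal(networkNodes(backIso), c("a", "b", "z"))
})

test_that("GraphML export round-trips the network exactly", {
  dir <- withr_like_tempdir()
  net <- networkFromEdges(c("alanine", "serine <x>"), c("glycine", "valine"),
                          period = "B", r = c(0.91234567891234, -0.87))
  path <- file.path(dir, "net.graphml")
  exportNetwork(net, path, format = "graphml")
  back <- readNetwork(path, format = "graphml")
  expect_equal(networkPeriod(back), "B")
  expect_setequal(networkNodes(back), networkNodes(net))
  eb <- networkEdges(back)[order(networkEdges(back)$from), ]
  en <- networkEdges(net)[order(networkEdges(net)$from), ]
  rownames(eb) <- rownames(en) <- NULL
  expect_identical(eb$r, en$r)        # %.17g preserves doubles exactly
  expect_identical(eb$p, en$p)
  expect_identical(eb$fdr, en$fdr)
  expect_equal(eb$from, en$from)      # XML escaping round-trips "<x>"
})

test_that("edge-TSV export round-trips the edge table", {
  dir <- withr_like_tempdir()
  net <- networkFromEdges(c("a", "b"), c("b", "c"), r = c(0.9, -0.95))
  path <- file.path(dir, "net.tsv")
  exportNetwork(net, path, format = "tsv")
  back <- readNetwork(path, format = "tsv", period = "toy")
  expect_equal(networkEdges(back)$r, networkEdges(net)$r, tolerance = 1e-12)
  expect_equal(edgeKeys(back), edgeKeys(net))
})

test_that("growth associations recover a coupled metabolite and stay null otherwise", {
  # self-correlation sanity: a column equal to the phenotype has r = 1
  x <- randomMatrix(20, 3, seed = 2)
  pheno <- rnorm(20)
  ga <- growthAssociation(cbind(x, self = pheno), pheno, "ratio")
  expect_equal(ga$r[ga$metabolite == "self"], 1)
  expect_equal(ga$p[ga$metabolite == "self"], 0)
  expect_error(growthAssociation(x, rep(1, 20), "ratio"), "constant")

  # planted coupling on the allometric ratio is found at FDR < 0.05
  cfg <- syntheticConfig(seed = 33, effectSizeD = 0, coreCliques = list(),
                         xenoNames = character(0),
                         ratioCoupled = list(name = "glycerol", loading = 0.8))
  study <- generateStudy(cfg)
  xm <- log(metaboliteMatrix(study$experiment))
  ratio <- allometricRatio(study$birds$liver_mass_g, study$birds$body_mass_g)
  ga2 <- growthAssociation(xm, ratio, "allometric_ratio")
  hit <- ga2[ga2$fdr < 0.05, ]
  expect_true("glycerol" %in% hit$metabolite)
  expect_lte(nrow(hit), 5L)   # essentially only the coupled metabolite
})

test_that("xenometabolite annotation is case-insensitive exact matching", {
  ann <- annotateXenometabolites(c("nornicotine", "glucose", "MALEIMIDE"))
  expect_equal(ann$is_xeno, c(TRUE, FALSE, TRUE))
  expect_equal(ann$source[1], "environmental nicotine metabolite")
  expect_true(is.na(ann$source[2]))
  expect_match(ann$source[3], "plastic")
})
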