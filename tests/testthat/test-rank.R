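plantedCohort <- function(shift = 5, seed = 21, nGenes = 20, nPer = 5) {
  co <- toyCohort(nPer = nPer, nGenes = nGenes, seed = seed, noise = 1)
  X <- exprsMatrix(co)
  X["G01", clusterLabels(co) == "II"] <-
    X["G01", clusterLabels(co) == "II"] + shift
  ImmuneCohort(X, scale = "log2", cluster = clusterLabels(co))
}

test_that("a strongly shifted gene attains aggregate rank 1", {
  co <- plantedCohort(shift = 5)
  rt <- rankOneVsRest(co, "II")
  expect_s4_class(rt, "RankingTable")
  tb <- rankingFrame(rt)
  expect_identical(tb$gene[1], "G01")
  expect_identical(tb$aggRank, seq_len(nrow(tb)))
  expect_setequal(tb$gene, rownames(co))
})

test_that("aggregate ranks match an independent five-ranker oracle", {
  set.seed(17)
  m <- matrix(rnorm(5 * 8, 5, 1), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  lab <- c("I", "I", "II", "II", "III", "III", "IV", "IV")
  co <- ImmuneCohort(m, scale = "log2", cluster = lab)
  rt <- rankOneVsRest(co, "I")
  tb <- rankingFrame(rt)

  sc <- oracleScores(m, lab == "I")
  ranks <- apply(-sc, 2, rank)
  agg <- rowMeans(ranks)
  oracleOrder <- rownames(m)[order(agg, rownames(m))]
  expect_identical(tb$gene, oracleOrder)
  got <- as.matrix(tb[match(rownames(m), tb$gene),
                      c("score_t", "score_auc", "score_snr",
                        "score_meandiff", "score_mi")])
  dimnames(got) <- dimnames(sc)
  expect_equal(got, sc, tolerance = 1e-10)
})

test_that("identical genes receive adjacent ranks in lexicographic order", {
  co <- plantedCohort(shift = 0, seed = 33, nGenes = 6)
  X <- exprsMatrix(co)
  X["G05", ] <- X["G02", ]  # exact duplicate column profile
  co2 <- ImmuneCohort(X, scale = "log2", cluster = clusterLabels(co))
  tb <- rankingFrame(rankOneVsRest(co2, "III"))
  i2 <- which(tb$gene == "G02"); i5 <- which(tb$gene == "G05")
  expect_identical(i5, i2 + 1L)  # adjacent, G02 before G05
})

test_that("ranking is invariant to per-gene constant shifts", {
  co <- plantedCohort(shift = 3, seed = 9)
  tb1 <- rankingFrame(rankOneVsRest(co, "II"))
  X <- exprsMatrix(co)
  X["G07", ] <- X["G07", ] + 100  # shift one gene everywhere
  tb2 <- rankingFrame(rankOneVsRest(
    ImmuneCohort(X, scale = "log2", cluster = clusterLabels(co)), "II"))
  expect_identical(tb1$gene, tb2$gene)
})

test_that("zero-variance genes rank worst and small clusters error", {
  co <- plantedCohort(shift = 4, seed = 13)
  X <- exprsMatrix(co)
  X["G09", ] <- 7  # constant gene
  tb <- rankingFrame(rankOneVsRest(
    ImmuneCohort(X, scale = "log2", cluster = clusterLabels(co)), "II"))
  expect_identical(tb$gene[nrow(tb)], "G09")

  lab <- clusterLabels(co)
  lab[lab == "II"] <- c("II", rep("I", sum(lab == "II") - 1))
  expect_error(rankOneVsRest(
    ImmuneCohort(exprsMatrix(co), scale = "log2", cluster = lab), "II"),
    "at least 2")
  expect_error(rankOneVsRest(co, "V"), "not present")
})

test_that("under permuted labels a planted gene's rank is uniform", {
  co <- plantedCohort(shift = 5, seed = 29, nGenes = 50, nPer = 5)
  m <- nrow(co)
  set.seed(101)
  ranks <- vapply(1:100, function(i) {
    lab <- sample(clusterLabels(co))
    names(lab) <- colnames(co)
    tb <- rankingFrame(rankOneVsRest(
      ImmuneCohort(exprsMatrix(co), scale = "log2", cluster = lab), "II"))
    which(tb$gene == "G01")
  }, integer(1))
  # Kolmogorov-Smirnov distance to Uniform(0,1) of the scaled ranks;
  # 0.195 is the alpha = 0.001 critical value for n = 100
  u <- (ranks - 0.5) / m
  D <- unname(suppressWarnings(ks.test(u, "punif")$statistic))
  expect_lt(D, 0.195)
})

test_that("the ranking grid yields one table per panel x cluster", {
  pa <- GenePanel(sprintf("G%02d", 1:10), "pa")
  pb <- GenePanel(sprintf("G%02d", 6:15), "pb")
  reg <- panelRegistry(list(pa, pb))
  co <- toyCohort(nPer = 3, nGenes = 15, seed = 7)
  tabs <- buildRankingTables(co, reg, combined = FALSE)
  expect_length(tabs, 8)  # 2 panels x 4 clusters
  tabsC <- buildRankingTables(co, reg, combined = TRUE)
  expect_length(tabsC, 12)
  expect_length(grep("^combined:", names(tabsC)), 4)
  # each table ranks exactly the panel genes present in the matrix
  expect_setequal(rankingFrame(tabs[["pa:I"]])$gene, panelGenes(pa))
})

test_that("top-fraction union obeys overlap arithmetic and nesting", {
  co <- toyCohort(nPer = 4, nGenes = 100, seed = 19)
  tabs <- lapply(c("I", "II", "III", "IV"),
                 function(cl) rankOneVsRest(co, cl))
  # identical tables: union of top 5% of four copies of one table
  one <- tabs[[1]]
  expect_length(topFractionUnion(list(one, one, one, one), 0.05), 5)

  # disjoint tops: construct tables whose top-5 sets do not overlap
  mk <- function(genes) {
    tb <- rankingFrame(one)
    tb <- tb[match(genes, tb$gene), ]
    tb$aggRank <- seq_len(nrow(tb))
    rownames(tb) <- NULL
    new("RankingTable", panel = "x", targetCluster = "I", table = tb)
  }
  g <- rankingFrame(one)$gene
  rot <- lapply(c(0, 25, 50, 75), function(off)
    mk(c(g[(off + 1):100], if (off > 0) g[1:off])))
  expect_length(topFractionUnion(rot, 0.05), 20)

  # q1 <= q2 => signature(q1) subset of signature(q2)
  s1 <- signatureGenes(topFractionUnion(tabs, 0.05))
  s2 <- signatureGenes(topFractionUnion(tabs, 0.20))
  expect_true(all(s1 %in% s2))

  expect_error(topFractionUnion(tabs, 0), "\\(0, 1]")
  expect_error(topFractionUnion(tabs, 0.005), "selects no genes")
})
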