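randomModel <- function(nGenes = 8, seed = 1, spread = 3) {
  set.seed(seed)
  g <- sprintf("G%02d", seq_len(nGenes))
  main <- matrix(rnorm(nGenes * 4, 0, spread), nGenes, 4,
                 dimnames = list(g, c("I", "II", "III", "IV")))
  alt <- matrix(rnorm(nGenes * 4, 0, spread), nGenes, 4,
                dimnames = list(g, c("I", "II", "III", "IV")))
  new("CentroidModel", genes = g, clusters = c("I", "II", "III", "IV"),
      main = main, alt = alt, zscore = FALSE,
      center = numeric(), scale = numeric())
}

test_that("centroids are the stated group means (8 vectors)", {
  # cluster I samples all equal to a constant vector v => main[I] == v
  v <- c(A = 1, B = 2, C = 3)
  m <- cbind(s1 = v, s2 = v, s3 = c(4, 4, 4), s4 = c(0, 1, 0),
             s5 = c(2, 2, 2), s6 = c(1, 0, 1))
  rownames(m) <- names(v)
  co <- ImmuneCohort(m, scale = "log2",
                     cluster = c("I", "I", "II", "II", "III", "IV"))
  mod <- fitCentroids(co, c("A", "B", "C"))
  expect_identical(dim(centroidMatrix(mod, "main")), c(3L, 4L))
  expect_identical(dim(centroidMatrix(mod, "alt")), c(3L, 4L))
  expect_equal(centroidMatrix(mod, "main")[, "I"], v)

  # four singleton clusters: alt[I] is the mean of the other 3 samples
  co1 <- ImmuneCohort(m[, 3:6], scale = "log2",
                      cluster = c("I", "II", "III", "IV"))
  mod1 <- fitCentroids(co1, c("A", "B", "C"))
  expect_equal(unname(centroidMatrix(mod1, "alt")[, "I"]),
               unname(rowMeans(m[, 4:6])))
})

test_that("weighted main centroids recover the overall mean", {
  co <- toyCohort(nPer = 4, nGenes = 6, seed = 12)
  mod <- fitCentroids(co, rownames(co))
  lab <- clusterLabels(co)
  nc <- table(lab)[c("I", "II", "III", "IV")]
  weighted <- centroidMatrix(mod, "main") %*% as.numeric(nc)
  expect_lt(max(abs(weighted / ncol(co) - rowMeans(exprsMatrix(co)))),
            1e-9)
})

test_that("fitting guards: missing clusters error, missing genes warn", {
  co <- toyCohort(nPer = 3, nGenes = 5, seed = 6)
  lab <- clusterLabels(co)
  lab[lab == "IV"] <- "III"
  expect_error(fitCentroids(
    ImmuneCohort(exprsMatrix(co), scale = "log2", cluster = lab),
    rownames(co)), "IV")
  expect_warning(mod <- fitCentroids(co, c(rownames(co), "ABSENT")),
                 "missing")
  expect_identical(mod@genes, rownames(co))
})

test_that("assignment follows the strict dual-centroid rule", {
  mod <- randomModel(seed = 2)
  # a sample sitting exactly on a main centroid is assigned there
  s <- centroidMatrix(mod, "main")[, "II"]
  expect_identical(assignSample(s, mod), "II")

  # exact equidistance to main and alt of the argmin cluster
  g <- "G01"
  main <- matrix(c(0, 5, 6, 7), 1, 4,
                 dimnames = list(g, c("I", "II", "III", "IV")))
  alt <- matrix(c(2, 5, 6, 7), 1, 4,
                dimnames = list(g, c("I", "II", "III", "IV")))
  tie <- new("CentroidModel", genes = g,
             clusters = c("I", "II", "III", "IV"), main = main,
             alt = alt, zscore = FALSE, center = numeric(),
             scale = numeric())
  expect_identical(assignSample(c(G01 = 1), tie), "UNCLASSIFIED")

  # tie among main-centroid minima: unclassified with a warning
  main2 <- main; main2[, "II"] <- -main2[, "I"] - 2  # d to I == d to II
  tie2 <- new("CentroidModel", genes = g,
              clusters = c("I", "II", "III", "IV"), main = main2,
              alt = alt, zscore = FALSE, center = numeric(),
              scale = numeric())
  expect_warning(lab <- assignSample(c(G01 = -1), tie2), "tie")
  expect_identical(lab, "UNCLASSIFIED")

  expect_error(assignSample(c(G01 = NA_real_), tie), "non-finite")
  expect_error(assignSample(1:3, mod), "length")
})

test_that("assignment matches a brute-force distance enumerator", {
  for (inst in 1:100) {
    mod <- randomModel(nGenes = 6, seed = inst, spread = 1.5)
    set.seed(1000 + inst)
    s <- rnorm(6, 0, 2)
    names(s) <- mod@genes
    expect_identical(assignSample(s, mod),
                     bruteAssign(s, centroidMatrix(mod, "main"),
                                 centroidMatrix(mod, "alt")))
  }
})

test_that("cohort assignment is translation invariant and subsets nearest-centroid", {
  co <- toyCohort(nPer = 5, nGenes = 8, seed = 31)
  mod <- fitCentroids(co, rownames(co))
  res <- assignCohort(co, mod)
  expect_s4_class(res, "AssignmentResult")

  # translation: add a constant vector to training and test samples
  shift <- rnorm(nrow(co))
  coShift <- ImmuneCohort(exprsMatrix(co) + shift, scale = "log2",
                          cluster = clusterLabels(co))
  modShift <- fitCentroids(coShift, rownames(co))
  expect_identical(assignedLabels(assignCohort(coShift, modShift)),
                   assignedLabels(res))

  # each sample agrees with plain nearest-centroid or is UNCLASSIFIED
  d <- assignmentDistances(res)
  nearest <- colnames(d$main)[apply(d$main, 1, which.min)]
  lab <- assignedLabels(res)
  expect_true(all(lab == nearest | lab == "UNCLASSIFIED"))

  expect_error(assignCohort(co[, 0], mod), "empty")
})

test_that("decisions are equivariant under cluster relabeling", {
  co <- toyCohort(nPer = 5, nGenes = 8, seed = 44)
  mod <- fitCentroids(co, rownames(co))
  lab1 <- assignedLabels(assignCohort(co, mod))

  perm <- c(I = "III", II = "IV", III = "I", IV = "II")
  co2 <- ImmuneCohort(exprsMatrix(co), scale = "log2",
                      cluster = unname(perm[clusterLabels(co)]))
  mod2 <- fitCentroids(co2, rownames(co))
  lab2 <- assignedLabels(assignCohort(co2, mod2))
  mapped <- ifelse(lab1 == "UNCLASSIFIED", "UNCLASSIFIED",
                   unname(perm[lab1]))
  expect_identical(lab2, mapped)
})

test_that("models serialize to the TSV bundle and back", {
  co <- toyCohort(nPer = 3, nGenes = 6, seed = 55)
  mod <- fitCentroids(co, rownames(co), zscore = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCentroidModel(mod, f)
  back <- readCentroidModel(f)
  expect_equal(centroidMatrix(back, "main"), centroidMatrix(mod, "main"))
  expect_equal(centroidMatrix(back, "alt"), centroidMatrix(mod, "alt"))
  expect_identical(back@zscore, TRUE)
  expect_identical(assignedLabels(assignCohort(co, back)),
                   assignedLabels(assignCohort(co, mod)))
})
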