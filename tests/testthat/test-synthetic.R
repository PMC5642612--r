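demoPanel <- GenePanel(sprintf("PNL%03d", 1:40), "demo")

test_that("generated cohorts are reproducible and carry the gradient", {
  cfg <- syntheticConfig(clusterSizes = c(10, 10, 10, 10),
                         gradient = c(0, 1, 2, 3), noiseSd = 0.01,
                         nBackgroundGenes = 30, baselineMean = 8, seed = 11)
  co <- generateCohort(cfg, demoPanel)
  expect_s4_class(co, "ImmuneCohort")
  expect_identical(expressionScale(co), "log2")
  expect_identical(dim(co), c(70L, 40L))
  expect_true(all(clusterLabels(co) %in% c("I", "II", "III", "IV")))

  # fixed seed => identical matrix on repeated calls
  co2 <- generateCohort(cfg, demoPanel)
  expect_identical(exprsMatrix(co), exprsMatrix(co2))

  # responsive genes: empirical IV-minus-I mean difference close to 3
  X <- exprsMatrix(co)
  lab <- clusterLabels(co)
  resp <- rownames(co)[rowData(co)$status == "responsive"]
  expect_length(resp, 20)  # responsiveFraction 0.5 of 40 panel genes
  d <- rowMeans(X[resp, lab == "IV"]) - rowMeans(X[resp, lab == "I"])
  expect_true(all(d >= 2.9 & d <= 3.1))

  # signal monotonicity at vanishing noise: cluster means non-decreasing
  cmeans <- sapply(c("I", "II", "III", "IV"),
                   function(cl) rowMeans(X[resp, lab == cl]))
  expect_true(all(apply(cmeans, 1, function(r) !is.unsorted(r))))

  # background genes show no shift
  bg <- rownames(co)[rowData(co)$status == "background"]
  dbg <- rowMeans(X[bg, lab == "IV"]) - rowMeans(X[bg, lab == "I"])
  expect_true(all(abs(dbg) < 0.1))
})

test_that("a flat gradient produces null two-sample t-statistics", {
  cfg <- syntheticConfig(clusterSizes = c(15, 15, 15, 15),
                         gradient = c(0, 0, 0, 0), noiseSd = 1,
                         nBackgroundGenes = 200, seed = 5)
  co <- generateCohort(cfg, demoPanel)
  lab <- clusterLabels(co)
  y <- lab == "IV"
  tstats <- apply(exprsMatrix(co), 1, function(x)
    t.test(x[y], x[!y])$statistic)
  # null-distributed: mean near 0, spread near 1, no systematic signal
  expect_lt(abs(mean(tstats)), 0.2)
  expect_gt(sd(tstats), 0.7)
  expect_lt(sd(tstats), 1.4)
  expect_gt(mean(abs(tstats) < 2), 0.9)
})

test_that("jointly permuting cluster sizes and gradient relabels the cohort", {
  cfg1 <- syntheticConfig(clusterSizes = c(5, 6, 7, 8),
                          gradient = c(0, 1, 2, 3),
                          nBackgroundGenes = 10, seed = 42)
  perm <- c(3, 1, 4, 2)
  cfg2 <- suppressWarnings(
    syntheticConfig(clusterSizes = cfg1$clusterSizes[perm],
                    gradient = cfg1$gradient[perm],
                    nBackgroundGenes = 10, seed = 42))
  co1 <- generateCohort(cfg1, demoPanel)
  co2 <- generateCohort(cfg2, demoPanel)
  lab1 <- clusterLabels(co1); lab2 <- clusterLabels(co2)
  lv <- c("I", "II", "III", "IV")
  # cluster i of cohort 2 carries the data of cluster perm[i] of cohort 1
  for (i in 1:4)
    expect_equal(unname(exprsMatrix(co2)[, lab2 == lv[i]]),
                 unname(exprsMatrix(co1)[, lab1 == lv[perm[i]]]))
})

test_that("raw-scale export round-trips through the log2 transform", {
  cfg <- syntheticConfig(clusterSizes = c(4, 4, 4, 4),
                         nBackgroundGenes = 20, seed = 2)
  co <- generateCohort(cfg, demoPanel)
  raw <- asRawScale(co)
  expect_identical(expressionScale(raw), "raw")
  expect_true(all(exprsMatrix(raw) >= 0))
  back <- log2Transform(raw, pseudocount = 1)
  expect_lt(max(abs(exprsMatrix(back) - exprsMatrix(co))), 1e-9)
})

test_that("degenerate configurations are rejected", {
  expect_error(syntheticConfig(noiseSd = 0))
  expect_error(syntheticConfig(clusterSizes = c(0, 5, 5, 5)))
  expect_error(syntheticConfig(responsiveFraction = 1.5))
  expect_warning(syntheticConfig(gradient = c(3, 1, 2, 0)),
                 "non-decreasing")
})

test_that("synthetic catalogs plant exactly the requested overlap", {
  genes <- sprintf("LIST%02d", 1:20)
  cat10 <- generateAnnotation(categorySizes = c(50, 50, 50),
                              referenceSize = 1000, overlapWith = genes,
                              enrichedCategory = 1, overlapSize = 10,
                              seed = 9)
  er <- runOverrepresentation(genes, cat10)
  tb <- enrichmentFrame(er)
  expect_identical(tb$k[tb$category == "CAT001"], 10L)
  expect_identical(tb$category[1], "CAT001")  # planted category ranks first

  cat0 <- generateAnnotation(categorySizes = c(50, 50), referenceSize = 1000,
                             overlapWith = genes, enrichedCategory = 1,
                             overlapSize = 0, seed = 9)
  tb0 <- enrichmentFrame(runOverrepresentation(genes, cat0))
  expect_identical(tb0$k[tb0$category == "CAT001"], 0L)

  expect_error(generateAnnotation(categorySizes = c(5), referenceSize = 100,
                                  overlapWith = genes, overlapSize = 10),
               "larger than")
})

test_that("chance-level categories average fold enrichment near 1", {
  genes <- sprintf("LIST%02d", 1:20)
  fe <- vapply(1:100, function(s) {
    cat <- generateAnnotation(categorySizes = c(50, 50), referenceSize = 500,
                              overlapWith = genes, enrichedCategory = 1,
                              overlapSize = 0, seed = s)
    tb <- enrichmentFrame(runOverrepresentation(genes, cat))
    tb$FE[tb$category == "CAT002"]  # untouched, chance-level category
  }, numeric(1))
  expect_lt(abs(mean(fe) - 1), 0.2)
})
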