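test_that("cosine distance hits its closed-form anchor points", {
  a <- c(1, 2, 3)
  expect_equal(nna_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(nna_distance(c(1, 0), c(0, 5)), 1, tolerance = 1e-12)
  expect_equal(nna_distance(a, -a), 2, tolerance = 1e-12)
  expect_equal(nna_distance(a, 2 * a), 0, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(nna_distance(x, y), nna_distance(y, x), tolerance = 1e-15)
  expect_error(nna_distance(c(0, 0), a[1:2]), "zero vector")
  expect_error(nna_distance(1:3, 1:4), "dimensions differ")
})

test_that("nearest-neighbour prediction follows the argmin and tie rules", {
  train <- rbind(c(1, 0), c(0, 1), c(1, 1))
  lab <- c("negative", "positive", "negative")
  expect_identical(nna_predict(train, c(0, 1), labels = lab), "positive")
  # two equidistant neighbours: lower index wins
  tie_train <- rbind(c(1, 0), c(0, 1))
  expect_identical(nna_predict(tie_train, c(1, 1),
                               labels = c("negative", "positive")),
                   "negative")
  expect_error(nna_predict(train, c(1, 2, 3), labels = lab), "features")
  # separable clusters: all queries near a cluster take its label
  set.seed(23)
  tr <- rbind(matrix(rnorm(40, 5), 20), matrix(rnorm(40, -5), 20))
  lb <- rep(c("positive", "negative"), each = 20)
  q <- rbind(matrix(rnorm(20, 5), 10), matrix(rnorm(20, -5), 10))
  expect_identical(nna_predict(tr, q, labels = lb),
                   rep(c("positive", "negative"), each = 10))
})

test_that("nna_predict agrees with exhaustive pairwise distances", {
  set.seed(31)
  for (i in 1:100) {
    tr <- matrix(rnorm(15 * 4), 15, 4)
    lb <- sample(c("positive", "negative"), 15, TRUE)
    q <- rnorm(4)
    d <- apply(tr, 1, function(r) nna_distance(r, q))
    expect_identical(nna_predict(tr, q, labels = lb), lb[which.min(d)])
  }
})

test_that("jackknife matches forced outcomes and the per-sample refit oracle", {
  # two mutual nearest neighbours with opposite labels: both misclassified
  x <- rbind(c(1, 0.1), c(1, 0.11))
  cc <- jackknife(x, labels = c("positive", "negative"))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  # perfectly separated clusters: error-free
  set.seed(17)
  x2 <- rbind(matrix(rnorm(30, 8), 15), matrix(rnorm(30, -8), 15))
  cc2 <- jackknife(x2, labels = rep(c("positive", "negative"), each = 15))
  expect_identical(cc2$FP + cc2$FN, 0L)
  # random instances against the naive oracle
  set.seed(29)
  for (i in 1:20) {
    xi <- matrix(rnorm(20 * 6), 20, 6)
    li <- sample(c("positive", "negative"), 20, TRUE)
    if (length(unique(li)) < 2) li[1] <- setdiff(c("positive", "negative"),
                                                 li[2])
    expect_identical(unclass(jackknife(xi, labels = li)),
                     unclass(jackknife_oracle(xi, li)))
  }
  expect_error(jackknife(x, integer(), labels = c("a", "b")),
               "empty feature subset")
})

test_that("duplicated samples are always recovered by leave-one-out", {
  set.seed(41)
  base <- matrix(rnorm(10 * 5), 10, 5)
  lab <- sample(c("positive", "negative"), 10, TRUE)
  x <- rbind(base, base)
  cc <- jackknife(x, labels = c(lab, lab))
  m <- compute_metrics(cc)
  expect_equal(unname(m["accuracy"]), 1)
})

test_that("metrics reproduce hand arithmetic and degenerate conventions", {
  m <- compute_metrics(list(TP = 5, FN = 3, TN = 7, FP = 1))
  expect_equal(unname(m["sensitivity"]), 5 / 8)
  expect_equal(unname(m["specificity"]), 7 / 8)
  expect_equal(unname(m["accuracy"]), 12 / 16)
  expect_equal(unname(m["mcc"]),
               (5 * 7 - 1 * 3) / sqrt(6 * 8 * 8 * 10))
  perfect <- compute_metrics(list(TP = 333, FN = 0, TN = 1665, FP = 0))
  expect_equal(unname(perfect), c(1, 1, 1, 1))
  # all-negative predictions on a mixed set: Sn = 0, MCC = 0 by the
  # zero-denominator convention
  allneg <- compute_metrics(list(TP = 0, FN = 10, TN = 50, FP = 0))
  expect_equal(unname(allneg["sensitivity"]), 0)
  expect_equal(unname(allneg["mcc"]), 0)
  # MCC is symmetric under class swap
  set.seed(53)
  for (i in 1:10) {
    c1 <- as.list(stats::setNames(sample(0:30, 4, TRUE),
                                  c("TP", "TN", "FP", "FN")))
    c2 <- list(TP = c1$TN, TN = c1$TP, FP = c1$FN, FN = c1$FP)
    if (sum(unlist(c1)) == 0) next
    expect_equal(compute_metrics(c1)[["mcc"]], compute_metrics(c2)[["mcc"]],
                 tolerance = 1e-12)
  }
})

test_that("IFS sweeps prefixes, matches per-prefix jackknife, and is stable", {
  set.seed(61)
  n <- 60
  x <- matrix(rnorm(n * 8), n, 8)
  x[1:15, 1:2] <- x[1:15, 1:2] + 3
  lab <- rep(c("positive", "negative"), c(15, 45))
  fm <- feature_matrix(x, lab)
  rk <- mrmr_rank(fm)
  tab <- ifs(fm, rk)
  expect_identical(tab$records$k, 1:8)
  # every record equals an independent jackknife on that prefix
  for (k in c(1, 3, 8)) {
    cc <- jackknife(fm, rk$order[1:k])
    expect_identical(tab$records$TP[k], cc$TP)
    expect_identical(tab$records$FN[k], cc$FN)
    expect_equal(tab$records$mcc[k], unname(compute_metrics(cc)["mcc"]),
                 tolerance = 1e-12)
  }
  # optimal k is the smallest prefix attaining the maximum MCC
  expect_identical(tab$optimal_k,
                   tab$records$k[which.max(tab$records$mcc)])
  # bitwise reproducible
  expect_identical(ifs(fm, rk)$records, tab$records)
  # single feature: one record
  one <- ifs(feature_matrix(x[, 1, drop = FALSE], lab), 1L)
  expect_identical(nrow(one$records), 1L)
  expect_identical(one$optimal_k, 1L)
  # appending noise features never changes earlier records
  x_noise <- cbind(x, matrix(rnorm(n * 4), n, 4))
  tab2 <- ifs(feature_matrix(x_noise, lab), c(rk$order, 9:12))
  expect_equal(tab2$records[1:8, ], tab$records, tolerance = 1e-12)
  expect_gte(max(tab$records$mcc), max(tab2$records$mcc) - 1e-12)
  expect_error(ifs(fm, c(1L, 1L, 2:7)), "permutation")
})

test_that("feature-set analysis counts by family and site", {
  sch <- build_schema(10)
  full <- analyze_feature_set(sch, seq_len(727))
  expect_equal(full$counts_by_family,
               c(PSSM = 420L, AAFactor = 100L, Disorder = 21L,
                 SecondaryStructure = 63L, Accessibility = 42L,
                 InterfaceSurface = 40L, GainLoss = 20L,
                 CarbonDeviation = 21L))
  expect_identical(sum(full$counts_by_site), 727L)
  empty <- analyze_feature_set(sch, integer())
  expect_true(all(empty$counts_by_family == 0L))
  pssm10 <- which(sch$site == 10 & sch$family == "PSSM")
  an <- analyze_feature_set(sch, pssm10)
  expect_identical(unname(an$counts_by_family[["PSSM"]]), 20L)
  expect_identical(unname(an$counts_by_site[["10"]]), 20L)
  expect_identical(an$n, 20L)
  expect_error(analyze_feature_set(sch, c(1L, 1L)), "duplicate")
})
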