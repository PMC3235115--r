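test_that("mutual information matches closed forms and the summation oracle", {
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x), 1.0, tolerance = 1e-12)
  # product empirical table: independent by construction
  g <- expand.grid(a = 0:2, b = 0:3)
  expect_equal(mutual_information(g$a, g$b), 0, tolerance = 1e-12)
  # printed 2x2 joint count table (40, 10 / 5, 45)
  x2 <- rep(c("u", "u", "v", "v"), c(40, 10, 5, 45))
  y2 <- rep(c("s", "t", "s", "t"), c(40, 10, 5, 45))
  direct <- 0
  for (a in c("u", "v")) for (b in c("s", "t")) {
    pxy <- sum(x2 == a & y2 == b) / 100
    direct <- direct +
      pxy * log2(pxy / ((sum(x2 == a) / 100) * (sum(y2 == b) / 100)))
  }
  expect_equal(mutual_information(x2, y2), direct, tolerance = 1e-12)
  expect_equal(mutual_information(x2, y2), mi_oracle(x2, y2),
               tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5), "lengths differ")
})

test_that("MI is symmetric, non-negative, and bounded by the entropies", {
  entropy <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  set.seed(100)
  for (i in 1:20) {
    x <- sample(0:3, 60, TRUE)
    y <- sample(0:2, 60, TRUE)
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    expect_lte(mi, min(entropy(x), entropy(y)) + 1e-12)
  }
  # y determines x => MI = H(x)
  x <- sample(0:2, 90, TRUE)
  y <- c("p", "q", "r")[x + 1]
  expect_equal(mutual_information(x, y), entropy(x), tolerance = 1e-12)
})

test_that("discretization follows the mean-sigma and quantile rules", {
  expect_identical(discretize(rep(4.2, 50)), rep(0L, 50))
  v <- c(-10, 0, 10)
  expect_identical(discretize(v), c(0L, 1L, 2L))
  set.seed(3)
  z <- rnorm(2000)
  d <- discretize(z)
  expect_identical(sort(unique(d)), c(0L, 1L, 2L))
  # boundary handling: values exactly at mu +/- k*sigma fall outside
  # the middle state
  v2 <- c(0, 1, 2)  # mu = 1, sd = 1
  expect_identical(discretize(v2), c(0L, 1L, 2L))
  eq <- discretize(seq_len(90), discretization_rule("equal-frequency", 3))
  expect_identical(as.integer(table(eq)), rep(30L, 3))
})

test_that("mrmr_rank reproduces a brute-force greedy recomputation", {
  set.seed(42)
  for (i in 1:10) {
    p <- sample(2:8, 1)
    n <- sample(20:80, 1)
    x <- matrix(sample(0:2, n * p, TRUE), n, p)
    y <- sample(c("a", "b"), n, TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("a", "b"), y[2])
    r <- mrmr_rank(x, y, rule = discretization_rule("none"))
    expect_identical(r$order, mrmr_oracle(x, y))
    expect_identical(r$round_index[r$order], seq_len(p))
  }
})

test_that("mrmr_rank selects pure relevance first and penalizes duplicates", {
  set.seed(7)
  n <- 120
  y <- rep(c("positive", "negative"), each = n / 2)
  informative <- ifelse(y == "positive", 1L, 0L)
  informative[sample(n, 10)] <- sample(0:1, 10, TRUE)  # mild noise
  x <- cbind(n1 = sample(0:2, n, TRUE),
             sig = informative,
             dup = informative,
             n2 = sample(0:2, n, TRUE))
  r <- mrmr_rank(x, y, rule = discretization_rule("none"))
  # round 1 takes a maximal-relevance feature (the signal column)
  rel <- vapply(1:4, function(j) mi_oracle(x[, j], y), numeric(1))
  expect_equal(r$relevance, rel, tolerance = 1e-12)
  expect_identical(r$order[1], 2L)
  # the identical twin is maximally redundant: selected strictly later
  expect_gt(r$round_index[3], r$round_index[2])
  # single feature: trivially ranked
  r1 <- mrmr_rank(x[, 2, drop = FALSE], y,
                  rule = discretization_rule("none"))
  expect_identical(r1$order, 1L)
  expect_error(mrmr_rank(x, rep("a", n)), "constant")
})

test_that("mrmr_rank is invariant to sample order", {
  set.seed(55)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6)
  x[1:20, 1] <- x[1:20, 1] + 2
  y <- rep(c("positive", "negative"), c(20, 60))
  r1 <- mrmr_rank(x, y)
  perm <- sample(n)
  r2 <- mrmr_rank(x[perm, ], y[perm])
  expect_identical(r1$order, r2$order)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-12)
})

test_that("planted informative columns surface in the top ranks", {
  hits <- integer(5)
  for (s in 1:5) {
    spec <- synthetic_spec(n_positive = 100, neg_ratio = 5, seed = 400 + s,
                           n_features = 200,
                           informative_columns = seq(5, 200, by = 20),
                           effect_size = 3)
    fm <- generate_matrix(spec)
    r <- mrmr_rank(fm)
    hits[s] <- sum(spec$informative_columns %in% r$order[1:20])
  }
  expect_true(all(hits >= 8))
})
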