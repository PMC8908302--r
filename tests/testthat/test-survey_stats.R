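test_that("PCA first-component loadings behave on structured item sets", {
  X <- parallel_item_pair(1, n = 8)  # perfectly correlated pair
  l <- pca_first_loadings(X)
  expect_equal(unname(l[1]), unname(l[2]), tolerance = 1e-12)
  expect_gt(sum(l), 0)

  # an item uncorrelated with the other two gets the smallest |loading|
  set.seed(19)
  n <- 200
  f <- rnorm(n)
  X3 <- cbind(a = f + rnorm(n, sd = 0.4), b = f + rnorm(n, sd = 0.4),
              c = rnorm(n))
  l3 <- pca_first_loadings(X3)
  expect_equal(names(which.min(abs(l3))), "c")

  # oracle: same loadings from prcomp on standardized data
  pr <- prcomp(scale(X3))
  oracle <- pr$rotation[, 1] * pr$sdev[1]
  if (sum(oracle) < 0) oracle <- -oracle
  expect_equal(unname(l3), unname(oracle), tolerance = 1e-8)

  # identical up to sign: equal magnitude, opposite sign
  Xs <- cbind(u = X3[, "a"], v = -X3[, "a"], w = X3[, "b"])
  ls <- pca_first_loadings(Xs)
  expect_equal(abs(unname(ls["u"])), abs(unname(ls["v"])), tolerance = 1e-10)
  expect_lt(ls["u"] * ls["v"], 0)

  expect_error(pca_first_loadings(cbind(a = rep(3, 5), b = rnorm(5))), "a")
})

test_that("item retention applies threshold plus manual exclusions", {
  l <- c(good = 0.85, weak = 0.39)
  expect_equal(retain_items(l, 0.45), "good")
  expect_equal(sort(retain_items(l, 0)), c("good", "weak"))
  expect_error(retain_items(l, 0.9), "no items")
  # a 0.56 item can only be dropped manually, as in the shipped codebook
  l2 <- c(a = 0.85, b = 0.58, c = 0.56)
  expect_equal(sort(retain_items(l2, 0.45, manual_exclusions = "c")),
               c("a", "b"))
  expect_error(retain_items(l, 1.5), "threshold")
})

test_that("alpha and omega match closed forms on parallel items", {
  X <- parallel_item_pair(0.5, n = 8)
  expect_equal(cronbach_alpha(X), 2 * 0.5 / 1.5, tolerance = 1e-10)
  expect_equal(mcdonald_omega(X), 4 * 0.5 / (4 * 0.5 + 2 * 0.5),
               tolerance = 1e-6)
  # all items identical -> alpha = 1
  Z <- cbind(x = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(Z), 1)
})

test_that("alpha equals the brute-force variance formula on a hand table", {
  X <- rbind(c(1, 2, 2), c(3, 3, 4), c(2, 1, 3), c(5, 4, 4), c(4, 4, 5))
  k <- 3
  item_vars <- total_var <- 0
  for (j in 1:k) {
    m <- mean(X[, j])
    item_vars <- item_vars + sum((X[, j] - m)^2) / (nrow(X) - 1)
  }
  tot <- rowSums(X)
  total_var <- sum((tot - mean(tot))^2) / (nrow(X) - 1)
  expect_equal(cronbach_alpha(X), k / (k - 1) * (1 - item_vars / total_var),
               tolerance = 1e-12)
  expect_error(cronbach_alpha(X[1:2, ]), "complete respondents")
})

test_that("omega recovers the generating value on simulated one-factor data", {
  set.seed(77)
  n <- 500; k <- 6
  lam <- c(0.8, 0.75, 0.7, 0.65, 0.6, 0.55)
  f <- rnorm(n)
  X <- sapply(lam, function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  omega_true <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  expect_equal(mcdonald_omega(X), omega_true, tolerance = 0.05)
  # classical ordering: alpha below omega for congeneric items
  expect_lte(cronbach_alpha(X), mcdonald_omega(X) + 0.01)
})

test_that("omega is invariant to per-item positive rescaling; alpha to common", {
  set.seed(78)
  n <- 60
  f <- rnorm(n)
  X <- sapply(c(0.8, 0.7, 0.6), function(l) l * f + sqrt(1 - l^2) * rnorm(n))
  Xs <- sweep(X, 2, c(2.5, 0.3, 10), `*`)
  expect_equal(mcdonald_omega(Xs), mcdonald_omega(X), tolerance = 1e-6)
  expect_equal(cronbach_alpha(3 * X + 1), cronbach_alpha(X),
               tolerance = 1e-10)
})

test_that("composite scores average retained items with a missing rule", {
  X <- data.frame(a = c(5, 3, 2), b = c(5, 4, NA), c = c(5, 5, NA))
  expect_equal(composite_score(X, c("a", "b", "c")), c(5, 4, NA))
  X7 <- as.data.frame(matrix(NA_real_, 1, 7,
                             dimnames = list(NULL, letters[1:7])))
  X7[1, 1:3] <- c(4, 4, 4)  # 3 of 7 answered < ceiling(7/2) = 4
  expect_true(is.na(composite_score(X7, letters[1:7])))
  X7[1, 4] <- 4
  expect_equal(composite_score(X7, letters[1:7]), 4)
})

test_that("describe reports N/mean/median/sd/min/max", {
  d <- describe(data.frame(x = c(1, 2, 3), y = c(7, NA, NA)))
  expect_equal(d$mean, c(2, 7))
  expect_equal(d$median, c(2, 7))
  expect_equal(d$sd, c(1, NA))
  expect_equal(d$N, c(3L, 1L))
  expect_equal(d$min, c(1, 7))
  expect_equal(d$max, c(3, 7))
  set.seed(5)
  v <- rnorm(40)
  dv <- describe(data.frame(v = v))
  expect_equal(dv$sd, sqrt(sum((v - mean(v))^2) / 39), tolerance = 1e-12)
})

test_that("correlation table matches brute-force r and p with flags", {
  x <- c(1, 3, 2, 5, 4, 6)
  y <- c(2, 3, 2, 6, 4, 5)
  ct <- correlate(data.frame(x = x, y = y))
  o <- oracle_pearson(x, y)
  expect_equal(ct$r["x", "y"], o$r, tolerance = 1e-12)
  expect_equal(ct$p["x", "y"], o$p, tolerance = 1e-12)
  expect_equal(ct$flag["x", "y"], sig_flags(o$p))

  ct2 <- correlate(data.frame(a = x, b = x, c = -x))
  expect_equal(ct2$r["a", "b"], 1)
  expect_equal(ct2$r["a", "c"], -1)
  expect_true(isSymmetric(ct2$r))
  expect_equal(unname(diag(ct2$r)), rep(1, 3))

  # pairwise deletion and degenerate pairs
  d <- data.frame(u = c(1, 2, 3, 4, NA), v = c(2, 1, 4, NA, 5),
                  w = c(1, 1, 1, 1, 1))
  ct3 <- correlate(d)
  expect_equal(ct3$n["u", "v"], 3L)
  expect_true(is.na(ct3$r["u", "w"]))
  expect_equal(sig_flags(c(0.005, 0.03, 0.07, 0.5, NA)),
               c("**", "*", "†", "", ""))
})

test_that("the packaged codebook loads and scores a synthetic survey", {
  cb <- load_codebook()
  expect_equal(sum(cb$scale == "pro_community"), 9L)
  expect_equal(length(scale_items(cb, "pro_community")), 7L)
  expect_equal(length(scale_items(cb, "openness")), 4L)

  tr <- generate_truth(tiny_scenario(), seed = 3)
  sv <- generate_survey(tr, seed = 5)
  pc <- composite_score(sv, scale_items(cb, "pro_community"))
  op <- composite_score(sv, scale_items(cb, "openness"))
  expect_equal(length(pc), tr$N)
  expect_true(all(pc >= 1 & pc <= 5, na.rm = TRUE))
  expect_true(all(op >= 1 & op <= 5, na.rm = TRUE))
  expect_gt(cronbach_alpha(sv[, scale_items(cb, "pro_community")]), 0)
})
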