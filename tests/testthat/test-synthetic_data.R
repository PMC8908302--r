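test_that("generate_truth plants disjoint supports and fixed schedules", {
  sc <- tiny_scenario()
  tr <- generate_truth(sc, seed = 1)
  expect_equal(tr$K_true, 3L)
  expect_equal(lengths(tr$memberships), c(4L, 4L, 4L))
  expect_equal(length(unique(unlist(tr$memberships))), 12L)  # disjoint

  # each U row positive only on dyads internal to its membership
  for (k in 1:3) {
    pos <- tr$U_true[k, ] > 0
    internal <- tr$dyads$pairs[, 1] %in% tr$memberships[[k]] &
      tr$dyads$pairs[, 2] %in% tr$memberships[[k]]
    expect_true(all(!pos | internal))
    expect_equal(sum(internal), choose(4, 2))
  }

  # event layer active only on its listed days
  day_of_epoch <- rep(seq_len(tr$grid$n_days), each = tr$grid$epochs_per_day)
  active_days <- unique(day_of_epoch[tr$H_true[, 1] > 0])
  expect_setequal(active_days,
                  sc$layers[[1]]$days[sc$layers[[1]]$days <= tr$grid$n_days])
  expect_true(all(tr$H_true >= 0))

  # determinism
  tr2 <- generate_truth(sc, seed = 1)
  expect_identical(tr$U_true, tr2$U_true)
  expect_identical(tr$memberships, tr2$memberships)
  bad <- sc; bad$membership_sizes <- c(40L, 4L, 4L)
  expect_error(generate_truth(bad, seed = 1), "larger than N")
})

test_that("observe_contacts follows its noise models", {
  sc <- tiny_scenario(N = 6L, sizes = c(2L, 2L, 2L), end = "2018-01-02")
  tr <- generate_truth(sc, seed = 2)

  zero <- tr; zero$H_true[] <- 0
  expect_equal(sum(as.matrix(observe_contacts(zero, "rounded"))), 0)

  # rounded model with integer rates reproduces H U exactly
  int_tr <- tr
  int_tr$H_true <- round(tr$H_true)
  int_tr$U_true <- round(tr$U_true * 0 + (tr$U_true > 0) * 2)
  exact <- int_tr$H_true %*% int_tr$U_true
  expect_equal(as.matrix(observe_contacts(int_tr, "rounded", cap = NULL)),
               exact)

  expect_error(observe_contacts(tr, cap = -2), "cap")
  # determinism of the poisson draw
  y1 <- as.matrix(observe_contacts(tr, "poisson", seed = 9))
  y2 <- as.matrix(observe_contacts(tr, "poisson", seed = 9))
  expect_identical(y1, y2)
})

test_that("poisson observation means match the planted rates", {
  sc <- tiny_scenario(N = 6L, sizes = c(2L, 2L, 2L), end = "2018-01-01")
  tr <- generate_truth(sc, seed = 3)
  rate <- tr$H_true %*% tr$U_true
  cells <- which(rate > 0.5, arr.ind = TRUE)[1:3, , drop = FALSE]
  n_rep <- 1000L
  acc <- matrix(0, n_rep, nrow(cells))
  for (r in seq_len(n_rep)) {
    Y <- as.matrix(observe_contacts(tr, "poisson", cap = NULL, seed = r))
    acc[r, ] <- Y[cells]
  }
  for (c in seq_len(nrow(cells))) {
    mu <- rate[cells[c, , drop = FALSE]]
    se <- sqrt(mu / n_rep)
    expect_lt(abs(mean(acc[, c]) - mu), 3 * se + 1e-9)
  }
})

test_that("emitted detection logs rebuild the exact contact matrix", {
  for (s in 1:3) {
    cm <- random_contact_matrix(5, seed = 60 + s, lambda = 0.3)
    log <- emit_detection_log(cm, seed = s)
    expect_equal(nrow(log), sum(as.matrix(cm)))
    cm2 <- build_contact_matrix(log, cm$grid, cm$dyads)
    expect_equal(as.matrix(cm2), as.matrix(cm))
  }
  # single cell with y = 3 -> 3 records in that epoch for that pair
  d <- build_dyad_index(c("a", "b"))
  g <- build_epoch_grid("2018-01-01", "2018-01-01", 30)
  Y <- Matrix::sparseMatrix(i = 5, j = 1, x = 3, dims = c(48, 1))
  cm1 <- proxnet:::new_contact_matrix(Y, g, d)
  log1 <- emit_detection_log(cm1, seed = 1)
  expect_equal(nrow(log1), 3L)
  expect_true(all(epoch_index(g, log1$timestamp) == 5L))
  expect_setequal(unique(log1$observer_id), c("a", "b"))  # directions alternate

  empty <- proxnet:::new_contact_matrix(
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(48, 1)), g, d)
  expect_equal(nrow(emit_detection_log(empty)), 0L)
})

test_that("evaluate_recovery scores exact, permuted, and unrelated models", {
  tr <- generate_truth(tiny_scenario(), seed = 5)
  exact <- structure(list(H = tr$H_true, U = tr$U_true, K = 3L),
                     class = "factor_model")
  r1 <- evaluate_recovery(tr, exact)
  expect_equal(r1$u_cor, rep(1, 3), tolerance = 1e-12)
  expect_equal(r1$membership$recall, rep(1, 3))

  perm <- c(3L, 1L, 2L)
  scrambled <- structure(list(H = tr$H_true[, perm] * 4,
                              U = tr$U_true[perm, ] * 0.25, K = 3L),
                         class = "factor_model")
  r2 <- evaluate_recovery(tr, scrambled)
  expect_equal(r2$u_cor, rep(1, 3), tolerance = 1e-12)
  expect_equal(r2$h_cor, rep(1, 3), tolerance = 1e-12)

  # unrelated random model: mean matched |r| near zero at J >= 100
  tr_big <- generate_truth(tiny_scenario(N = 16L, sizes = c(5L, 5L, 5L)),
                           seed = 6)
  set.seed(99)
  rand <- structure(list(H = matrix(runif(tr_big$grid$I * 3), ncol = 3),
                         U = matrix(runif(3 * tr_big$dyads$J), nrow = 3),
                         K = 3L), class = "factor_model")
  r3 <- evaluate_recovery(tr_big, rand)
  expect_gte(tr_big$dyads$J, 100)
  expect_lt(mean(abs(r3$u_cor)), 0.3)

  expect_error(evaluate_recovery(tr, structure(list(K = 2L),
                                               class = "factor_model")),
               "rank differs")
})

test_that("factor matching maximizes total correlation (exhaustive check)", {
  score <- rbind(c(0.9, 0.1, 0.2), c(0.2, 0.1, 0.8), c(0.1, 0.7, 0.3))
  expect_equal(proxnet:::match_factors(score), c(1L, 3L, 2L))
  expect_equal(sort(unlist(lapply(proxnet:::permutations_of(3), paste,
                                  collapse = ""))),
               sort(c("123", "132", "213", "231", "312", "321")))
})

test_that("generate_survey plants effects with the requested sign", {
  sc <- tiny_scenario(N = 60L, sizes = c(20L, 20L, 20L))
  tr <- generate_truth(sc, seed = 7)
  sv <- generate_survey(tr, seed = 11)
  expect_identical(sv, generate_survey(tr, seed = 11))  # determinism
  cb <- load_codebook()
  traits <- attr(sv, "planted_traits")

  pc <- composite_score(sv, scale_items(cb, "pro_community"))
  r_pc <- cor(pc, traits[, 1])
  expect_gt(r_pc, 0.3)  # planted positive effect of factor 1

  # zero-effect scale: correlation within sampling error of 0
  op <- composite_score(sv, scale_items(cb, "openness"))
  r_op <- cor(op, traits[, 1])
  expect_lt(abs(r_op), 3 / sqrt(tr$N))
})
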