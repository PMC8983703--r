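test_that("the expert rule cascades reproduce every printed branch", {
  expect_equal(assign_class_rule(list(length = 40, helix_frac = 0.7,
                                      sheet_frac = 0.1), "original"), "small")
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.60,
                                      sheet_frac = 0.05), "original"), "alpha")
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.10,
                                      sheet_frac = 0.40), "original"), "beta")
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.30,
                                      sheet_frac = 0.30), "original"), "alphabeta")
  expect_equal(assign_class_rule(list(length = 52, helix_frac = 0.70,
                                      sheet_frac = 0), "optimized"), "small")
  expect_equal(assign_class_rule(list(length = 52, helix_frac = 0.70,
                                      sheet_frac = 0), "original"), "alpha")
  # optimized cascade thresholds differ: helix 55%, sheet 25%
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.56,
                                      sheet_frac = 0), "optimized"), "alpha")
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.56,
                                      sheet_frac = 0), "original"), "alphabeta")
  expect_equal(assign_class_rule(list(length = 100, helix_frac = 0.1,
                                      sheet_frac = 0.30), "optimized"), "beta")
})

test_that("the cascades are total and match a direct vectorized restatement", {
  grid <- expand.grid(length = c(10, 30, 49, 50, 54, 55, 60, 100, 300),
                      helix = seq(0, 1, by = 0.05),
                      sheet = seq(0, 1, by = 0.05))
  grid <- grid[grid$helix + grid$sheet <= 1, ]
  direct <- function(len, h, s, len_th, h_th, s_th) {
    ifelse(len < len_th, "small",
           ifelse(h >= h_th, "alpha",
                  ifelse(s >= s_th & h < 0.20, "beta", "alphabeta")))
  }
  got_o <- vapply(seq_len(nrow(grid)), function(i)
    assign_class_rule(list(length = grid$length[i], helix_frac = grid$helix[i],
                           sheet_frac = grid$sheet[i]), "original"), character(1))
  expect_equal(got_o, direct(grid$length, grid$helix, grid$sheet, 50, 0.60, 0.35))
  got_p <- vapply(seq_len(nrow(grid)), function(i)
    assign_class_rule(list(length = grid$length[i], helix_frac = grid$helix[i],
                           sheet_frac = grid$sheet[i]), "optimized"), character(1))
  expect_equal(got_p, direct(grid$length, grid$helix, grid$sheet, 55, 0.55, 0.25))
  expect_true(all(got_o %in% c("alpha", "beta", "alphabeta", "small")))
})

test_that("performance metrics follow the confusion-matrix formulas", {
  m <- classification_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(unname(m), c(1, 1, 1, 1))
  m2 <- classification_metrics(c(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(unname(m2), c(0.8, 0.75, 0.75, 0.75))

  expect_equal(unname(classification_metrics(c(TP = 0, FP = 0, TN = 9, FN = 1),
                                             "accuracy")), 0.9)
  expect_error(classification_metrics(c(TP = 0, FP = 0, TN = 9, FN = 1),
                                      "precision"), "precision")

  set.seed(3)
  for (i in 1:1000) {
    cts <- c(TP = sample(1:50, 1), FP = sample(0:50, 1),
             TN = sample(0:50, 1), FN = sample(0:50, 1))
    m <- classification_metrics(cts)
    expect_equal(m[["accuracy"]], (cts["TP"] + cts["TN"]) / sum(cts),
                 ignore_attr = TRUE)
    p <- cts[["TP"]] / (cts[["TP"]] + cts[["FP"]])
    r <- cts[["TP"]] / (cts[["TP"]] + cts[["FN"]])
    expect_equal(m[["f_measure"]], 2 / (1 / p + 1 / r))  # harmonic mean
  }
})

test_that("secondary-structure content recognizes ideal geometries", {
  helix <- make_ideal_helix(30)
  ch <- ss_content_from_structure(helix)
  expect_equal(ch$length, 30)
  expect_gt(ch$helix_frac, 0.8)
  expect_lt(ch$sheet_frac, 0.1)

  sheet <- make_ideal_sheet(12, n_strands = 2)
  cs <- ss_content_from_structure(sheet)
  expect_gt(cs$sheet_frac, 0.6)
  expect_lt(cs$helix_frac, 0.1)

  coil <- make_blob_protein(60, seed = 5)
  cc <- ss_content_from_structure(coil)
  expect_lt(cc$helix_frac, 0.2)

  tiny <- make_ideal_helix(5)
  tiny$atoms <- tiny$atoms[tiny$atoms$residue_index <= 3, ]
  tiny <- as_zd_structure(tiny$atoms)
  expect_error(ss_content_from_structure(tiny), "at least 5")
})

svm_training_data <- function(n_per = 100, seed = 1) {
  zdsurf:::with_seed(seed, {
    mk <- function(label, len, h, s, n) data.frame(
      length = pmax(20, round(rnorm(n, len, 15))),
      helix_frac = pmin(0.95, pmax(0, rnorm(n, h, 0.05))),
      sheet_frac = pmin(0.95, pmax(0, rnorm(n, s, 0.05))),
      label = label)
    d <- rbind(mk("alpha", 150, 0.75, 0.05, n_per),
               mk("beta", 150, 0.05, 0.55, n_per),
               mk("alphabeta", 200, 0.35, 0.30, n_per),
               mk("small", 35, 0.20, 0.10, n_per))
    d$sheet_frac <- pmin(d$sheet_frac, 1 - d$helix_frac)
    d
  })
}

test_that("the bagged SVM recovers separable classes and is seed-stable", {
  dat <- svm_training_data(100, seed = 2)
  model <- train_bagged_svm(dat, seed = 11)
  expect_equal(length(model$members), 20)
  pred <- predict_bagged_svm(model, dat)
  expect_gt(mean(pred == dat$label), 0.95)

  model_b <- train_bagged_svm(dat, seed = 11)
  expect_identical(predict_bagged_svm(model_b, dat), pred)

  expect_error(train_bagged_svm(dat[dat$label != "small", ]), "four classes")
})

test_that("label-shuffled SVM training collapses to chance", {
  dat <- svm_training_data(60, seed = 2)
  test <- svm_training_data(60, seed = 9)
  shuf <- dat
  set.seed(14)
  shuf$label <- sample(shuf$label)
  model <- train_bagged_svm(shuf, seed = 11)
  acc <- mean(predict_bagged_svm(model, test) == test$label)
  expect_gt(acc, 0.10)
  expect_lt(acc, 0.40)
})

test_that("fold assignment picks the best-scoring catalogue fold", {
  cl <- make_descriptor_clusters(2, 8, dim = 20, separation = 4, noise = 0.1,
                                 noise_spread = c(1, 1), seed = 6)
  catalogue <- split(cl$descriptors, cl$labels)

  one <- catalogue["f01"]
  expect_equal(assign_fold(cl$descriptors[[1]], one)$fold_id, "f01")

  # query identical to an exemplar lands in that exemplar's fold
  hit <- assign_fold(cl$descriptors[[9]], catalogue, k = 5)
  expect_equal(hit$fold_id, cl$labels[9])

  # recovery over many queries
  correct <- vapply(seq_along(cl$descriptors), function(i)
    assign_fold(cl$descriptors[[i]], catalogue, k = 5, seed = i)$fold_id ==
      cl$labels[i], logical(1))
  expect_gt(mean(correct), 0.9)

  expect_error(assign_fold(cl$descriptors[[1]], list()), "empty")
  expect_error(assign_fold(cl$descriptors[[1]], unname(catalogue)), "named")

  # aggregation by mean is also exposed
  hm <- assign_fold(cl$descriptors[[3]], catalogue, k = 5, aggregate = "mean")
  expect_true(hm$fold_id %in% names(catalogue))
})

test_that("fold recovery degrades monotonically with the noise-to-separation ratio", {
  accs <- vapply(c(0.05, 0.5, 1.4), function(sig) {
    cl <- make_descriptor_clusters(4, 10, dim = 20, separation = 3,
                                   noise = sig, noise_spread = c(1, 1),
                                   seed = 20)
    catalogue <- split(cl$descriptors, cl$labels)
    mean(vapply(seq_along(cl$descriptors), function(i)
      assign_fold(cl$descriptors[[i]], catalogue, k = 5, seed = i)$fold_id ==
        cl$labels[i], logical(1)))
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], 0.95)
})
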