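desc_from <- function(v, order = NULL, vert = 0, faces = 0) {
  if (is.null(order)) order <- zdsurf:::order_for_length(length(v))
  zdsurf:::new_zd_descriptor(order, v, NA_character_, vert, faces)
}

test_that("the direct descriptor score is 1/(1 + Euclidean distance)", {
  a <- desc_from(rep(1, 12), order = 5)
  expect_equal(zdzd_score(a, a)$value, 1.0)

  b <- a; b$values[3] <- b$values[3] + 1
  expect_equal(zdzd_score(a, b)$value, 0.5)

  # distance 9 sits exactly at the 0.1 decision threshold
  c9 <- a; c9$values[1] <- c9$values[1] + 9
  s <- zdzd_score(a, c9)
  expect_equal(s$value, 0.1)
  expect_true(s$same_fold)

  expect_equal(zdzd_score(b, a)$value, zdzd_score(a, b)$value)  # symmetry
  d1 <- zdzd_score(a, b)$value
  b2 <- a; b2$values[3] <- b2$values[3] + 2
  expect_lt(zdzd_score(a, b2)$value, d1)  # strictly decreasing in distance

  bad <- desc_from(rep(1, 6), order = 3)
  expect_error(zdzd_score(a, bad), "orders differ")
})

test_that("the encoder produces the configured activation shapes deterministically", {
  params <- nn_init_params(121, c(250, 200, 150), seed = 3)
  d <- desc_from(runif(121))
  enc <- nn_encode(d, params)
  expect_equal(lengths(enc), c(250L, 200L, 150L))
  expect_identical(enc, nn_encode(d, params))

  zero <- params
  for (i in seq_along(zero$enc)) zero$enc[[i]]$W[] <- 0
  enc0 <- nn_encode(d, zero)
  expect_true(all(unlist(enc0) == 0))
  expect_error(nn_encode(desc_from(runif(12), 5), params), "does not match")
})

test_that("pair features have the closed-form length and identity values", {
  expect_equal(pair_feature_length(121, c(250, 200, 150)), 1452L)
  expect_equal(pair_feature_length(3, c(2, 2, 2)), 28L)
  # closed formula on a sweep of configurations
  for (cfg in list(list(d = 9, w = c(5, 4, 3)), list(d = 121, w = c(250, 200, 150)),
                   list(d = 16, w = c(10, 10, 10)), list(d = 2, w = c(1, 1, 1)),
                   list(d = 6, w = c(30, 20, 10)))) {
    params <- nn_init_params(cfg$d, cfg$w, 4, seed = 1)
    a <- desc_from(runif(cfg$d))
    b <- desc_from(runif(cfg$d))
    feat <- build_pair_features(a, b, nn_encode(a, params), nn_encode(b, params))
    expect_equal(length(feat), 2 * cfg$d + 2 * sum(cfg$w) + 2 * 4 + 2)
  }

  params <- nn_init_params(121, c(250, 200, 150), seed = 5)
  a <- desc_from(runif(121) + 0.1, vert = 500, faces = 996)
  feat <- build_pair_features(a, a, nn_encode(a, params), nn_encode(a, params))
  expect_equal(length(feat), 1452)
  metrics <- feat[(2 * 121 + 2 * 600) + 1:8]
  # euclidean 0, cosine distance 0, manhattan 0, dot = |a|^2 (raw block)
  expect_equal(metrics[1:3], c(0, 0, 0))
  expect_equal(metrics[4], sum(a$values^2))
  expect_equal(metrics[5:7], c(0, 0, 0))
  expect_equal(feat[1451:1452], c(0, 0))  # same mesh counts
})

test_that("network scores are probabilities, symmetric, and 0.5 for a null head", {
  params <- nn_init_params(12, c(6, 5, 4), 3, seed = 2)
  a <- desc_from(runif(12), 5)
  b <- desc_from(runif(12), 5)
  s <- nn_score(a, b, params)
  expect_true(s$value >= 0 && s$value <= 1)
  expect_equal(nn_score(b, a, params)$value, s$value)  # symmetrized

  null_head <- params
  null_head$comp[[2]]$W[] <- 0
  null_head$comp[[2]]$b <- 0
  expect_equal(nn_score(a, b, null_head)$value, 0.5)

  # mode-dependent default thresholds
  amc <- a; amc$source_mode <- "main_chain"
  expect_equal(nn_score(amc, b, params)$threshold, 0.6)
  expect_equal(nn_score(a, b, params)$threshold, 0.5)
})

test_that("analytic gradients match finite differences through every path", {
  set.seed(6)
  d_in <- 3
  params <- nn_init_params(d_in, c(2, 2, 2), 4, seed = 7)
  # keep every ReLU unit active: an exactly-zero encoding sits on the
  # (measure-zero) discontinuity of the cosine metric where finite
  # differences are meaningless
  for (i in seq_along(params$enc)) params$enc[[i]]$b[] <- 0.3
  A <- matrix(runif(d_in * 4) + 0.05, d_in, 4)
  B <- matrix(runif(d_in * 4) + 0.05, d_in, 4)
  MA <- matrix(rpois(8, 50), 2, 4)
  MB <- matrix(rpois(8, 50), 2, 4)
  y <- c(1, 0, 1, 0)
  loss_of <- function(p) {
    fwd <- zdsurf:::nn_forward_batch(A, B, MA, MB, p)
    pr <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fwd <- zdsurf:::nn_forward_batch(A, B, MA, MB, params)
  grads <- zdsurf:::nn_backward_batch(fwd, (fwd$p - y) / length(y), params)
  eps <- 1e-6
  for (grp in c("enc", "comp")) {
    for (i in seq_along(params[[grp]])) {
      W <- params[[grp]][[i]]$W
      for (idx in seq_len(min(6, length(W)))) {
        p2 <- params; p2[[grp]][[i]]$W[idx] <- W[idx] + eps
        p3 <- params; p3[[grp]][[i]]$W[idx] <- W[idx] - eps
        num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
        expect_equal(grads[[grp]][[i]]$W[idx], num, tolerance = 1e-4)
      }
      b <- params[[grp]][[i]]$b
      p2 <- params; p2[[grp]][[i]]$b[1] <- b[1] + eps
      p3 <- params; p3[[grp]][[i]]$b[1] <- b[1] - eps
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(grads[[grp]][[i]]$b[1], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss deterministically and learns separable pairs", {
  cl <- make_descriptor_clusters(2, 12, dim = 20, separation = 4,
                                 noise = 0.1, noise_spread = c(1, 1), seed = 9)
  idx <- seq_along(cl$labels)
  tr <- unlist(lapply(split(idx, cl$labels[idx]), head, 9))
  te <- setdiff(idx, tr)
  pairs_tr <- make_pair_table(tr, cl$labels, seed = 2)
  pairs_te <- make_pair_table(te, cl$labels, seed = 3)
  cfg <- list(encoder_widths = c(16, 12, 8), comparator_hidden = 16,
              epochs = 12, seed = 4)
  params <- train_network(cl$descriptors, pairs_tr, cfg)
  h <- attr(params, "history")
  expect_lt(h$loss[nrow(h)], h$loss[1])

  params_b <- train_network(cl$descriptors, pairs_tr, cfg)
  expect_identical(attr(params_b, "history")$loss, h$loss)  # bit-identical rerun

  acc <- mean(vapply(seq_len(nrow(pairs_te)), function(k)
    (nn_score(cl$descriptors[[pairs_te$i[k]]], cl$descriptors[[pairs_te$j[k]]],
              params)$value >= 0.5) == (pairs_te$label[k] == 1), logical(1)))
  expect_gt(acc, 0.95)

  single <- pairs_tr[pairs_tr$label == 1, ]
  expect_error(train_network(cl$descriptors, single, cfg), "positive and one negative")
})

test_that("training on shuffled labels stays at chance on held-out pairs", {
  # a single shuffle is volatile: the optimizer turns whatever chance
  # correlation the shuffle left into confident (possibly inverted)
  # predictions, so the null is assessed as the mean over several
  # independent shuffles
  cl <- make_descriptor_clusters(5, 15, dim = 20, separation = 4,
                                 noise = 0.1, noise_spread = c(1, 1), seed = 9)
  idx <- seq_along(cl$labels)
  tr <- unlist(lapply(split(idx, cl$labels[idx]), head, 10))
  te <- setdiff(idx, tr)
  pairs_tr <- make_pair_table(tr, cl$labels, seed = 2)
  pairs_te <- make_pair_table(te, cl$labels, seed = 3)
  accs <- vapply(1:6, function(sh) {
    set.seed(100 + sh)
    ptr <- pairs_tr
    ptr$label <- sample(ptr$label)
    params <- train_network(cl$descriptors, ptr,
                            list(encoder_widths = c(16, 12, 8),
                                 comparator_hidden = 16, epochs = 4, seed = 4))
    mean(vapply(seq_len(nrow(pairs_te)), function(k)
      (nn_score(cl$descriptors[[pairs_te$i[k]]], cl$descriptors[[pairs_te$j[k]]],
                params)$value >= 0.5) == (pairs_te$label[k] == 1), logical(1)))
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("parameter checkpoints round-trip through the JSON archive", {
  params <- nn_init_params(12, c(6, 5, 4), 3, seed = 13)
  a <- desc_from(runif(12), 5)
  b <- desc_from(runif(12), 5)
  f <- tempfile(fileext = ".ckpt")
  write_nn_params(params, f)
  params2 <- read_nn_params(f)
  expect_equal(nn_score(a, b, params2)$value, nn_score(a, b, params)$value)
  expect_equal(params2$config$encoder_widths, c(6, 5, 4))
})
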