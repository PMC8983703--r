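# Pair scoring: direct descriptor distance and a trainable siamese network
# that outputs the probability that two structures share a fold.
#
# Architecture: a shared three-layer ReLU encoder (default widths 250, 200,
# 150) maps each 121-component descriptor to a 600-component encoding (the
# concatenation of all three hidden layers).  The comparator input is
# [a, b, enc(a), enc(b), 4 metrics on raw descriptors, 4 metrics on the
# encodings, delta-vertices, delta-faces] = 2*121 + 2*600 + 2*4 + 2 = 1452
# features, passed through one ReLU hidden layer to a sigmoid output.
# The four comparison metrics are the Euclidean distance, the cosine
# distance, the Manhattan (summed absolute) distance and the dot product;
# each is a single scalar per representation, which is the only reduction
# consistent with the 2*4 term of the feature count.

#' Direct 3DZD similarity score
#'
#' `1 / (1 + d)` where `d` is the Euclidean distance between the two
#' descriptors; ranges over (0, 1] and equals 1 exactly for identical
#' descriptors. The default decision threshold for "same fold" is 0.1.
#'
#' @param a,b `zd_descriptor` objects of equal order.
#' @param threshold Binarization threshold (default 0.1).
#' @return A `zd_pair_score`: list with `value`, `method = "zdzd"`,
#'   `threshold`, `same_fold`.
#' @export
zdzd_score <- function(a, b, threshold = 0.1) {
  stopifnot(inherits(a, "zd_descriptor"), inherits(b, "zd_descriptor"))
  if (a$order != b$order)
    stop("descriptor orders differ (", a$order, " vs ", b$order, ")")
  value <- 1 / (1 + sqrt(sum((a$values - b$values)^2)))
  new_pair_score(value, "zdzd", threshold)
}

new_pair_score <- function(value, method, threshold) {
  structure(list(value = value, method = method, threshold = threshold,
                 same_fold = value >= threshold),
            class = "zd_pair_score")
}

#' @export
print.zd_pair_score <- function(x, ...) {
  cat("<zd_pair_score> ", x$method, ": ", signif(x$value, 4),
      " (threshold ", x$threshold, ", same fold: ", x$same_fold, ")\n",
      sep = "")
  invisible(x)
}

#' Initialize siamese network parameters
#'
#' He-normal weight initialization, deterministic given the seed.
#'
#' @param d_in Descriptor length (default 121).
#' @param encoder_widths Hidden widths of the shared encoder.
#' @param comparator_hidden Width of the comparator hidden layer.
#' @param seed Random seed.
#' @return A `zd_nn_params` list with `config` and weight matrices.
#' @export
nn_init_params <- function(d_in = 121, encoder_widths = c(250, 200, 150),
                           comparator_hidden = 128, seed = 1) {
  stopifnot(all(encoder_widths > 0), comparator_hidden > 0)
  n_feat <- pair_feature_length(d_in, encoder_widths)
  with_seed(seed, {
    he <- function(n_out, n_in)
      matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
    widths <- c(d_in, encoder_widths)
    enc <- lapply(seq_along(encoder_widths), function(i)
      list(W = he(widths[i + 1], widths[i]), b = numeric(widths[i + 1])))
    comp <- list(list(W = he(comparator_hidden, n_feat),
                      b = numeric(comparator_hidden)),
                 list(W = he(1, comparator_hidden), b = numeric(1)))
    structure(list(config = list(d_in = d_in,
                                 encoder_widths = encoder_widths,
                                 comparator_hidden = comparator_hidden,
                                 n_features = n_feat,
                                 activation = "relu", seed = seed),
                   enc = enc, comp = comp, trained = FALSE),
              class = "zd_nn_params")
  })
}

#' Length of the pair-comparison feature vector
#'
#' `2 D + 2 sum(widths) + 2 * 4 + 2`; with D = 121 and widths
#' (250, 200, 150) this is 1452.
#'
#' @param d_in Descriptor length.
#' @param encoder_widths Encoder hidden widths.
#' @return Integer feature count.
#' @export
pair_feature_length <- function(d_in = 121, encoder_widths = c(250, 200, 150)) {
  as.integer(2 * d_in + 2 * sum(encoder_widths) + 2 * 4 + 2)
}

relu <- function(x) pmax(x, 0)

#' Encode a descriptor through the shared encoder
#'
#' @param d A `zd_descriptor` or numeric vector of length `d_in`.
#' @param params A `zd_nn_params`.
#' @return List of the three hidden-layer activation vectors.
#' @export
nn_encode <- function(d, params) {
  x <- descriptor_values(d)
  if (length(x) != params$config$d_in)
    stop("descriptor length ", length(x), " does not match network input ",
         params$config$d_in)
  acts <- vector("list", length(params$enc))
  h <- x
  for (i in seq_along(params$enc)) {
    h <- relu(as.vector(params$enc[[i]]$W %*% h) + params$enc[[i]]$b)
    acts[[i]] <- h
  }
  acts
}

descriptor_values <- function(d) {
  if (inherits(d, "zd_descriptor")) unname(d$values) else as.numeric(d)
}

descriptor_mesh <- function(d) {
  if (inherits(d, "zd_descriptor")) c(d$mesh_vertices, d$mesh_faces)
  else c(0, 0)
}

# the four scalar comparison metrics between two vectors
pair_metrics <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  cosd <- if (nu == 0 && nv == 0) 0 else if (nu == 0 || nv == 0) 1
  else 1 - sum(u * v) / (nu * nv)
  c(euclidean = sqrt(sum((u - v)^2)),
    cosine = cosd,
    manhattan = sum(abs(u - v)),
    dot = sum(u * v))
}

#' Assemble the pair-comparison feature vector
#'
#' Concatenates both raw descriptors, both encodings (all encoder layers),
#' the four comparison metrics applied to the raw descriptors and to the
#' encodings, and the signed differences in surface-mesh vertex and face
#' counts.
#'
#' @param a,b `zd_descriptor`s (or numeric vectors).
#' @param enc_a,enc_b Encoder activations from [nn_encode()] computed with
#'   the same parameters.
#' @return Numeric feature vector (length 1452 under the default
#'   configuration).
#' @export
build_pair_features <- function(a, b, enc_a, enc_b) {
  va <- descriptor_values(a); vb <- descriptor_values(b)
  if (length(va) != length(vb)) stop("descriptor lengths differ")
  ea <- unlist(enc_a, use.names = FALSE)
  eb <- unlist(enc_b, use.names = FALSE)
  if (length(ea) != length(eb)) stop("encoding lengths differ")
  ma <- descriptor_mesh(a); mb <- descriptor_mesh(b)
  unname(c(va, vb, ea, eb, pair_metrics(va, vb), pair_metrics(ea, eb),
           ma[1] - mb[1], ma[2] - mb[2]))
}

# forward pass of the comparator on a feature vector; returns activations
comparator_forward <- function(feat, params) {
  z1 <- relu(as.vector(params$comp[[1]]$W %*% feat) + params$comp[[1]]$b)
  logit <- sum(params$comp[[2]]$W * z1) + params$comp[[2]]$b
  list(z1 = z1, logit = logit, p = 1 / (1 + exp(-logit)))
}

nn_forward_one <- function(a, b, params) {
  enc_a <- nn_encode(a, params)
  enc_b <- nn_encode(b, params)
  feat <- build_pair_features(a, b, enc_a, enc_b)
  comparator_forward(feat, params)$p
}

#' Same-fold probability from the siamese network
#'
#' The raw network is not exactly symmetric in its two arguments, so the
#' reported value is the mean of both orderings. The decision threshold
#' depends on the descriptor representation: 0.5 for full-atom surfaces,
#' 0.6 for main-chain surfaces (both tunable).
#'
#' @param a,b `zd_descriptor`s.
#' @param params Trained `zd_nn_params`.
#' @param threshold Override the mode-derived threshold.
#' @return A `zd_pair_score` with `method = "nn"`.
#' @export
nn_score <- function(a, b, params, threshold = NULL) {
  stopifnot(inherits(params, "zd_nn_params"))
  if (is.null(threshold)) {
    mode <- if (inherits(a, "zd_descriptor")) a$source_mode else NA
    threshold <- if (identical(mode, "main_chain")) 0.6 else 0.5
  }
  value <- (nn_forward_one(a, b, params) + nn_forward_one(b, a, params)) / 2
  new_pair_score(value, "nn", threshold)
}

# ---- batched training ------------------------------------------------------

# Forward pass for a batch of pairs.  A, B: d x m matrices of descriptor
# values; MA, MB: 2 x m mesh-count matrices.  Returns everything needed for
# the backward pass.
nn_forward_batch <- function(A, B, MA, MB, params) {
  enc_branch <- function(X) {
    Hs <- vector("list", length(params$enc))
    H <- X
    for (i in seq_along(params$enc)) {
      H <- params$enc[[i]]$W %*% H + params$enc[[i]]$b
      H[H < 0] <- 0
      Hs[[i]] <- H
    }
    Hs
  }
  Ha <- enc_branch(A); Hb <- enc_branch(B)
  Ea <- do.call(rbind, Ha); Eb <- do.call(rbind, Hb)
  m <- ncol(A)

  metr <- function(U, V) {
    nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(V^2))
    dotv <- colSums(U * V)
    eu <- sqrt(colSums((U - V)^2))
    cosd <- ifelse(nu == 0 & nv == 0, 0,
                   ifelse(nu == 0 | nv == 0, 1, 1 - dotv / (nu * nv)))
    man <- colSums(abs(U - V))
    rbind(euclidean = eu, cosine = cosd, manhattan = man, dot = dotv)
  }
  Mraw <- metr(A, B)
  Menc <- metr(Ea, Eb)
  Feat <- rbind(A, B, Ea, Eb, Mraw, Menc, MA[1, ] - MB[1, ], MA[2, ] - MB[2, ])

  Z1 <- params$comp[[1]]$W %*% Feat + params$comp[[1]]$b
  Z1[Z1 < 0] <- 0
  logit <- as.vector(params$comp[[2]]$W %*% Z1) + params$comp[[2]]$b
  p <- 1 / (1 + exp(-logit))
  list(Ha = Ha, Hb = Hb, Ea = Ea, Eb = Eb, Feat = Feat, Z1 = Z1, p = p,
       A = A, B = B)
}

# gradient of the four metrics w.r.t. U given upstream scalars g (4 x m)
metric_backward <- function(g, U, V) {
  nu <- sqrt(colSums(U^2)); nv <- sqrt(colSums(V^2))
  dotv <- colSums(U * V)
  diffUV <- U - V
  eu <- sqrt(colSums(diffUV^2))
  inv_eu <- ifelse(eu > 0, 1 / eu, 0)
  dU_eu <- sweep(diffUV, 2, g[1, ] * inv_eu, "*")
  ok <- nu > 0 & nv > 0
  ccoef <- ifelse(ok, 1 / (nu * nv), 0)
  scoef <- ifelse(ok, dotv / (nu^3 * nv), 0)
  dU_cos <- sweep(-V, 2, g[2, ] * ccoef, "*") + sweep(U, 2, g[2, ] * scoef, "*")
  dU_man <- sweep(sign(diffUV), 2, g[3, ], "*")
  dU_dot <- sweep(V, 2, g[4, ], "*")
  dU_eu + dU_cos + dU_man + dU_dot
}

# Full backward pass; `dp` is dLoss/dlogit (1 x m).  Returns gradients with
# the same shape as params$enc / params$comp.
nn_backward_batch <- function(fwd, dp, params) {
  d_in <- params$config$d_in
  widths <- params$config$encoder_widths
  Z1 <- fwd$Z1
  dW2 <- matrix(dp %*% t(Z1), nrow = 1)
  db2 <- sum(dp)
  dZ1 <- (t(params$comp[[2]]$W) %*% matrix(dp, nrow = 1)) * (Z1 > 0)
  dWc1 <- dZ1 %*% t(fwd$Feat)
  dbc1 <- rowSums(dZ1)
  dFeat <- t(params$comp[[1]]$W) %*% dZ1

  nE <- sum(widths)
  iA <- seq_len(d_in)
  iB <- d_in + iA
  iEa <- 2 * d_in + seq_len(nE)
  iEb <- 2 * d_in + nE + seq_len(nE)
  iMraw <- 2 * d_in + 2 * nE + 1:4
  iMenc <- 2 * d_in + 2 * nE + 4 + 1:4

  gEnc <- dFeat[iMenc, , drop = FALSE]
  dEa <- dFeat[iEa, , drop = FALSE] + metric_backward(gEnc, fwd$Ea, fwd$Eb)
  dEb <- dFeat[iEb, , drop = FALSE] + metric_backward(gEnc, fwd$Eb, fwd$Ea)

  enc_backward <- function(Hs, X, dE) {
    offs <- c(0, cumsum(widths))
    dHdirect <- lapply(seq_along(widths), function(i)
      dE[(offs[i] + 1):offs[i + 1], , drop = FALSE])
    g <- vector("list", length(widths))
    dH <- dHdirect[[length(widths)]]
    for (i in rev(seq_along(widths))) {
      if (i < length(widths)) dH <- dH + dHdirect[[i]]
      dPre <- dH * (Hs[[i]] > 0)
      Hin <- if (i == 1) X else Hs[[i - 1]]
      g[[i]] <- list(W = dPre %*% t(Hin), b = rowSums(dPre))
      if (i > 1) dH <- t(params$enc[[i]]$W) %*% dPre
    }
    g
  }
  gA <- enc_backward(fwd$Ha, fwd$A, dEa)
  gB <- enc_backward(fwd$Hb, fwd$B, dEb)
  genc <- lapply(seq_along(widths), function(i)
    list(W = gA[[i]]$W + gB[[i]]$W, b = gA[[i]]$b + gB[[i]]$b))
  list(enc = genc,
       comp = list(list(W = dWc1, b = dbc1), list(W = dW2, b = db2)))
}

#' Train the siamese fold network
#'
#' ADAM optimization of the binary cross-entropy over balanced mini-batches
#' (equal numbers of positive, same-fold, and negative pairs per batch,
#' sampled with replacement). Training is deterministic given the seed.
#' When validation pairs are supplied, the parameters with the best
#' validation loss are returned; otherwise the final parameters are.
#'
#' @param descriptors List of `zd_descriptor`s (or a d x n matrix).
#' @param pairs Data frame with columns `i`, `j` (1-based indices into
#'   `descriptors`) and `label` (1 = same fold, 0 = different fold).
#' @param config List overriding defaults: `encoder_widths` (250, 200,
#'   150), `comparator_hidden` (128), `learning_rate` (0.005),
#'   `batch_size` (64), `epochs` (30), `seed` (1), `val_frac` (0).
#' @return A trained `zd_nn_params` with a `history` attribute (data frame
#'   of per-epoch training loss, and validation loss when applicable).
#' @export
train_network <- function(descriptors, pairs, config = list()) {
  cfg <- modifyList(list(encoder_widths = c(250, 200, 150),
                         comparator_hidden = 128, learning_rate = 0.005,
                         batch_size = 64, epochs = 30, seed = 1,
                         val_frac = 0), config)
  stopifnot(all(c("i", "j", "label") %in% names(pairs)))
  if (length(unique(pairs$label)) < 2)
    stop("training needs at least one positive and one negative pair")
  if (is.list(descriptors)) {
    D <- vapply(descriptors, descriptor_values,
                numeric(length(descriptor_values(descriptors[[1]]))))
    M <- vapply(descriptors, descriptor_mesh, numeric(2))
  } else {
    D <- as.matrix(descriptors)
    M <- matrix(0, 2, ncol(D))
  }
  d_in <- nrow(D)
  params <- nn_init_params(d_in, cfg$encoder_widths, cfg$comparator_hidden,
                           seed = cfg$seed)

  with_seed(cfg$seed + 1L, {
    n <- nrow(pairs)
    if (cfg$val_frac > 0) {
      val_idx <- sample(n, max(2, round(cfg$val_frac * n)))
      val <- pairs[val_idx, ]
      train <- pairs[-val_idx, ]
      if (length(unique(train$label)) < 2) stop("validation split left a single class")
    } else {
      val <- NULL
      train <- pairs
    }
    pos <- which(train$label == 1)
    neg <- which(train$label == 0)
    half <- cfg$batch_size %/% 2
    steps <- max(1L, ceiling(nrow(train) / cfg$batch_size))

    adam <- adam_state(params)
    lr <- cfg$learning_rate
    hist <- data.frame(epoch = integer(), loss = numeric(), val_loss = numeric())
    best <- list(loss = Inf, params = params)
    t_step <- 0
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps)) {
        sel <- train[c(sample(pos, half, replace = TRUE),
                       sample(neg, half, replace = TRUE)), ]
        fwd <- nn_forward_batch(D[, sel$i, drop = FALSE],
                                D[, sel$j, drop = FALSE],
                                M[, sel$i, drop = FALSE],
                                M[, sel$j, drop = FALSE], params)
        y <- sel$label
        p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - mean(y * log(p) + (1 - y) * log(1 - p))
        dp <- (fwd$p - y) / length(y)
        grads <- nn_backward_batch(fwd, dp, params)
        t_step <- t_step + 1
        upd <- adam_update(params, grads, adam, lr, t_step)
        params <- upd$params
        adam <- upd$state
      }
      vloss <- NA_real_
      if (!is.null(val)) {
        vf <- nn_forward_batch(D[, val$i, drop = FALSE], D[, val$j, drop = FALSE],
                               M[, val$i, drop = FALSE], M[, val$j, drop = FALSE],
                               params)
        pv <- pmin(pmax(vf$p, 1e-12), 1 - 1e-12)
        vloss <- -mean(val$label * log(pv) + (1 - val$label) * log(1 - pv))
        if (vloss < best$loss) best <- list(loss = vloss, params = params)
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / steps,
                                     val_loss = vloss))
    }
    if (!is.null(val) && is.finite(best$loss)) params <- best$params
    params$trained <- TRUE
    attr(params, "history") <- hist
    params
  })
}

adam_state <- function(params) {
  zero_like <- function(g) lapply(g, function(layer)
    list(W = layer$W * 0, b = layer$b * 0))
  list(m_enc = zero_like(params$enc), v_enc = zero_like(params$enc),
       m_comp = zero_like(params$comp), v_comp = zero_like(params$comp))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd_group <- function(layers, g, m, v) {
    for (i in seq_along(layers)) {
      for (nm in c("W", "b")) {
        m[[i]][[nm]] <- beta1 * m[[i]][[nm]] + (1 - beta1) * g[[i]][[nm]]
        v[[i]][[nm]] <- beta2 * v[[i]][[nm]] + (1 - beta2) * g[[i]][[nm]]^2
        mhat <- m[[i]][[nm]] / (1 - beta1^t)
        vhat <- v[[i]][[nm]] / (1 - beta2^t)
        layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(layers = layers, m = m, v = v)
  }
  e <- upd_group(params$enc, grads$enc, state$m_enc, state$v_enc)
  c_ <- upd_group(params$comp, grads$comp, state$m_comp, state$v_comp)
  params$enc <- e$layers
  params$comp <- c_$layers
  list(params = params,
       state = list(m_enc = e$m, v_enc = e$v, m_comp = c_$m, v_comp = c_$v))
}

#' Save / load network parameters
#'
#' Single-file JSON checkpoint: config header plus flattened weight arrays
#' at full precision.
#'
#' @param params A `zd_nn_params`.
#' @param path Checkpoint file path.
#' @return `path` invisibly for the writer; a `zd_nn_params` for the
#'   reader.
#' @export
write_nn_params <- function(params, path) {
  stopifnot(inherits(params, "zd_nn_params"))
  flat <- function(layers) lapply(layers, function(l)
    list(W = as.numeric(l$W), dim = dim(l$W), b = as.numeric(l$b)))
  jsonlite::write_json(list(config = params$config, trained = params$trained,
                            enc = flat(params$enc), comp = flat(params$comp)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nn_params
#' @export
read_nn_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unflat <- function(layers) lapply(seq_len(nrow_list(layers)), function(i) {
    l <- pick_layer(layers, i)
    list(W = matrix(l$W, l$dim[1], l$dim[2]), b = as.numeric(l$b))
  })
  cfg <- x$config
  cfg$encoder_widths <- as.numeric(cfg$encoder_widths)
  structure(list(config = cfg, enc = unflat(x$enc), comp = unflat(x$comp),
                 trained = isTRUE(x$trained)),
            class = "zd_nn_params")
}

# jsonlite may simplify the layer list into a data frame; normalize access
nrow_list <- function(layers) if (is.data.frame(layers)) nrow(layers) else length(layers)
pick_layer <- function(layers, i) {
  if (is.data.frame(layers))
    list(W = layers$W[[i]], dim = layers$dim[[i]], b = layers$b[[i]])
  else layers[[i]]
}
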