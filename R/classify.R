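# Secondary-structure class assignment (alpha / beta / alphabeta / small)
# by expert rule cascades or a bagged SVM ensemble, SCOPe-style fold
# assignment via exemplar comparison, and the standard confusion-matrix
# performance metrics.

.class_levels <- c("alpha", "alphabeta", "beta", "small")

#' Assign a secondary-structure class by expert rules
#'
#' Two fixed threshold cascades over chain length and helix/sheet content;
#' the first matching condition wins.
#' \itemize{
#'   \item `original`: length < 50 aa -> small; else helix >= 60% -> alpha;
#'     else sheet >= 35% and helix < 20% -> beta; else -> alphabeta.
#'   \item `optimized`: length < 55 aa -> small; else helix >= 55% ->
#'     alpha; else sheet >= 25% and helix < 20% -> beta; else -> alphabeta.
#' }
#'
#' @param content List or data frame row with `length`, `helix_frac`,
#'   `sheet_frac` (fractions in \[0, 1\]).
#' @param rule `"original"` or `"optimized"`.
#' @return One of `"alpha"`, `"beta"`, `"alphabeta"`, `"small"`.
#' @export
assign_class_rule <- function(content, rule = c("original", "optimized")) {
  rule <- match.arg(rule)
  len <- content$length
  h <- content$helix_frac
  s <- content$sheet_frac
  stopifnot(h >= 0, s >= 0, h + s <= 1 + 1e-9)
  th <- if (rule == "original") c(len = 50, helix = 0.60, sheet = 0.35)
  else c(len = 55, helix = 0.55, sheet = 0.25)
  if (len < th[["len"]]) "small"
  else if (h >= th[["helix"]]) "alpha"
  else if (s >= th[["sheet"]] && h < 0.20) "beta"
  else "alphabeta"
}

#' Secondary-structure content from C-alpha geometry
#'
#' A lightweight geometric assigner over the C-alpha trace: a residue is
#' called helical when the i to i+3 and i to i+4 CA distances fall in
#' windows around the canonical 5.1 and 6.2 Angstrom of an alpha-helix,
#' and strand when its i to i+2 distance is extended (near 6.7 A) and a
#' residue of another extended stretch lies within 5.5 A (a paired
#' neighbouring strand). Precomputed fractions from any standard assigner
#' can be substituted wherever an `SSContent` is accepted.
#'
#' @param s A `zd_structure` with at least 5 CA-bearing residues.
#' @return List with `length`, `helix_frac`, `sheet_frac`.
#' @export
ss_content_from_structure <- function(s) {
  stopifnot(inherits(s, "zd_structure"))
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  n <- nrow(ca)
  if (n < 5) stop("need at least 5 residues with CA atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  dist_k <- function(k) {
    idx <- seq_len(n - k)
    sqrt(rowSums((xyz[idx + k, , drop = FALSE] - xyz[idx, , drop = FALSE])^2))
  }
  d2 <- dist_k(2); d3 <- dist_k(3); d4 <- dist_k(4)
  nw <- n - 4
  helix_window <- d3[seq_len(nw)] >= 4.6 & d3[seq_len(nw)] <= 5.6 &
    d4 >= 5.6 & d4 <= 6.8
  # demand two consecutive window hits: a lone hit (e.g. where the chain
  # folds back between strands) is not a helical turn
  core <- helix_window & c(helix_window[-1], FALSE) |
    helix_window & c(FALSE, helix_window[-nw])
  is_helix <- logical(n)
  for (i in which(core)) is_helix[i:min(n, i + 4)] <- TRUE

  extended <- c(d2 >= 6.2 & d2 <= 7.2, FALSE, FALSE)
  ext_res <- logical(n)
  for (i in which(extended)) ext_res[i:min(n, i + 2)] <- TRUE
  is_sheet <- logical(n)
  cand <- which(ext_res & !is_helix)
  if (length(cand) > 1) {
    for (i in cand) {
      others <- cand[abs(cand - i) > 2]
      if (length(others)) {
        dmin <- min(sqrt(colSums((t(xyz[others, , drop = FALSE]) - xyz[i, ])^2)))
        if (dmin <= 5.5) is_sheet[i] <- TRUE
      }
    }
  }
  list(length = n,
       helix_frac = mean(is_helix),
       sheet_frac = mean(is_sheet & !is_helix))
}

#' Train a bagged SVM ensemble for class assignment
#'
#' Twenty radial-basis-kernel SVMs, each trained on a bootstrap sample
#' (drawn with replacement) of 5% of the data; the ensemble predicts by
#' majority vote, with ties broken by the summed class probabilities
#' across members and then by lexicographic class order. Features
#' (`length`, `helix_frac`, `sheet_frac`) are standardized using training
#' statistics. A bootstrap sample containing fewer than two classes is
#' redrawn (up to 100 attempts).
#'
#' @param data Data frame with columns `length`, `helix_frac`,
#'   `sheet_frac`, `label`.
#' @param n_classifiers Ensemble size (default 20).
#' @param sample_frac Bootstrap sample size as a fraction of the data
#'   (default 0.05).
#' @param seed Random seed.
#' @param gamma,cost RBF kernel hyperparameters passed to the members.
#' @return A `zd_bagged_svm` model; use [predict_bagged_svm()].
#' @export
train_bagged_svm <- function(data, n_classifiers = 20, sample_frac = 0.05,
                             seed = 1, gamma = NULL, cost = 1) {
  stopifnot(all(c("length", "helix_frac", "sheet_frac", "label") %in% names(data)))
  if (length(unique(data$label)) < 4)
    stop("training data must contain all four classes")
  X <- as.matrix(data[, c("length", "helix_frac", "sheet_frac")])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  y <- factor(data$label, levels = sort(unique(data$label)))
  m <- max(2L, round(sample_frac * nrow(X)))
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  members <- with_seed(seed, lapply(seq_len(n_classifiers), function(b) {
    for (attempt in 1:100) {
      idx <- sample(nrow(Xs), m, replace = TRUE)
      if (length(unique(y[idx])) >= 2)
        return(e1071::svm(Xs[idx, , drop = FALSE], droplevels(y[idx]),
                          kernel = "radial", gamma = gamma, cost = cost,
                          probability = TRUE))
    }
    stop("could not draw a bootstrap sample with at least two classes")
  }))
  structure(list(members = members, center = mu, scale = sdv,
                 levels = levels(y), n_classifiers = n_classifiers,
                 sample_frac = sample_frac, gamma = gamma, cost = cost,
                 seed = seed),
            class = "zd_bagged_svm")
}

#' Predict classes with a bagged SVM ensemble
#'
#' @param model A `zd_bagged_svm`.
#' @param newdata Data frame with `length`, `helix_frac`, `sheet_frac`.
#' @return Character vector of class labels.
#' @export
predict_bagged_svm <- function(model, newdata) {
  stopifnot(inherits(model, "zd_bagged_svm"))
  X <- as.matrix(newdata[, c("length", "helix_frac", "sheet_frac")])
  Xs <- scale(X, center = model$center, scale = model$scale)
  votes <- matrix(0L, nrow(Xs), length(model$levels),
                  dimnames = list(NULL, model$levels))
  probsum <- matrix(0, nrow(Xs), length(model$levels),
                    dimnames = list(NULL, model$levels))
  for (mem in model$members) {
    pred <- predict(mem, Xs, probability = TRUE)
    pr <- attr(pred, "probabilities")
    for (lv in colnames(pr)) probsum[, lv] <- probsum[, lv] + pr[, lv]
    pc <- as.character(pred)
    for (i in seq_along(pc)) votes[i, pc[i]] <- votes[i, pc[i]] + 1L
  }
  vapply(seq_len(nrow(Xs)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) {  # tie: summed probability, then lexicographic
      p <- probsum[i, top]
      top <- top[which(p == max(p))]
    }
    model$levels[min(top)]
  }, character(1))
}

#' Assign a fold by comparison with catalogue exemplars
#'
#' For each fold in the catalogue, up to `k` exemplar descriptors are
#' sampled without replacement (seeded) and scored against the query; the
#' fold score aggregates exemplar scores by maximum (default) or mean, and
#' the best-scoring fold is returned. Ties are broken by lexicographic
#' fold id.
#'
#' @param query A `zd_descriptor`.
#' @param catalogue Named list: fold id -> list of exemplar
#'   `zd_descriptor`s.
#' @param k Exemplars sampled per fold (default 10).
#' @param scorer Function `(a, b) -> zd_pair_score` (e.g. a closure over
#'   [nn_score()] parameters, or [zdzd_score()]).
#' @param seed Seed for exemplar sampling.
#' @param aggregate `"max"` or `"mean"`.
#' @return List with `fold_id`, `score` and the per-fold score vector
#'   `fold_scores`.
#' @export
assign_fold <- function(query, catalogue, k = 10, scorer = zdzd_score,
                        seed = 1, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(catalogue) == 0L) stop("empty fold catalogue")
  if (is.null(names(catalogue)) || any(names(catalogue) == ""))
    stop("catalogue must be a named list of folds")
  fold_ids <- sort(names(catalogue))
  scores <- with_seed(seed, vapply(fold_ids, function(fid) {
    ex <- catalogue[[fid]]
    take <- if (length(ex) > k) sample(length(ex), k) else seq_along(ex)
    s <- vapply(take, function(t) scorer(query, ex[[t]])$value, numeric(1))
    if (aggregate == "max") max(s) else mean(s)
  }, numeric(1)))
  best <- fold_ids[which.max(scores)]  # which.max takes the first = lexicographic
  list(fold_id = best, score = unname(scores[best]), fold_scores = scores)
}

#' Classification performance metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F-measure `2PR/(P+R)`. A metric whose denominator is
#' zero is undefined and raises an error naming it; request a subset via
#' `measures` to avoid this.
#'
#' @param counts List or vector with `TP`, `FP`, `TN`, `FN` (non-negative).
#' @param measures Which metrics to compute.
#' @return Named numeric vector of the requested metrics.
#' @export
classification_metrics <- function(counts,
                                   measures = c("accuracy", "precision",
                                                "recall", "f_measure")) {
  measures <- match.arg(measures, several.ok = TRUE)
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  out <- numeric(0)
  need <- function(cond, name) if (!cond)
    stop("metric '", name, "' is undefined: zero denominator", call. = FALSE)
  for (m in measures) {
    val <- switch(m,
      accuracy = { need(tp + tn + fp + fn > 0, "accuracy")
        (tp + tn) / (tp + tn + fp + fn) },
      precision = { need(tp + fp > 0, "precision"); tp / (tp + fp) },
      recall = { need(tp + fn > 0, "recall"); tp / (tp + fn) },
      f_measure = {
        need(tp + fp > 0, "f_measure"); need(tp + fn > 0, "f_measure")
        p <- tp / (tp + fp); r <- tp / (tp + fn)
        need(p + r > 0, "f_measure")
        2 * p * r / (p + r)
      })
    out[m] <- val
  }
  out
}
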