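#' @name dnetpro-module
#' @title DNetPRO network-based feature-signature extraction
#'
#' @description
#' DNetPRO selects low-dimensional, interpretable feature signatures from
#' high-dimensional, highly redundant data (originally gene expression,
#' here radiomic + clinical variables).  Every unordered feature couple is
#' scored by the cross-validated performance of a linear support vector
#' machine fit on just those two features; the top-scoring couples form a
#' weighted graph whose connected components are candidate signatures;
#' each candidate is then evaluated with an L2-penalized logistic model
#' and the best component becomes the signature.  Two selection schemes
#' are provided: procedure A (selection and evaluation inside a
#' train/test cross-validation) and procedure B (a stratified three-way
#' hold-out where an intermediate validation part ranks the candidate
#' components, rotated so each part serves once in each role).
NULL

#' DNetPRO configuration
#'
#' @param keep_fraction fraction of top-scoring couples retained when
#'   building the couple network; default 0.05.
#' @param inner_folds stratified folds for couple scoring; default 5.
#' @param eval_folds stratified folds for component evaluation; default 5.
#' @param metric couple score: `"mcc"` (default) or `"accuracy"`.
#' @param penalty L2 penalty strength of the logistic model (total-loss
#'   scale; the per-observation ridge lambda is `penalty / n_train`).
#' @param cost SVM misclassification cost C; default 1.
#' @param outer_folds outer cross-validation folds for procedure A.
#' @param p_max refuse to score more than `choose(p_max, 2)` couples;
#'   guards the quadratic cost, pre-filter to one feature category first.
#' @param b_repartition if `TRUE`, procedure B draws three independent
#'   partitions instead of rotating one partition through the roles.
#' @return a `dnetpro_config` list.
#' @export
dnetpro_config <- function(keep_fraction = 0.05, inner_folds = 5,
                           eval_folds = 5, metric = c("mcc", "accuracy"),
                           penalty = 1, cost = 1, outer_folds = 10,
                           p_max = 2000, b_repartition = FALSE) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1, inner_folds >= 2,
            eval_folds >= 2, penalty > 0, cost > 0, outer_folds >= 2,
            p_max >= 2)
  structure(list(keep_fraction = keep_fraction, inner_folds = inner_folds,
                 eval_folds = eval_folds, metric = match.arg(metric),
                 penalty = penalty, cost = cost, outer_folds = outer_folds,
                 p_max = p_max, b_repartition = b_repartition),
            class = "dnetpro_config")
}

#' Fit the linear SVM used for couple scoring
#'
#' Deterministic dual coordinate-descent solver for the L2-regularised
#' hinge-loss linear SVM (fixed sweep order, regularised bias).  Exposed
#' so feature weights can be used for coefficient-based selection and so
#' tests can compare single fits against an independent SVM
#' implementation.
#'
#' @param X numeric matrix (standardized).
#' @param y binary labels (0/1 or two-level factor).
#' @param cost misclassification cost C.
#' @return list with `weights` (one per column of `X`) and `bias`.
#' @export
linsvm_fit <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y)) - 1L
  w <- .cpp_linsvm_fit(X, as.numeric(y), cost, 1e-5, 1000)
  list(weights = w[seq_len(ncol(X))], bias = w[ncol(X) + 1])
}

#' Score all feature couples with a linear SVM
#'
#' Fits the linear SVM on every unordered pair of feature columns within
#' one stratified fold assignment shared by all couples, and records the
#' mean out-of-fold score (MCC by default).  All `choose(p, 2)` couples
#' are scored; deterministic under `seed`.
#'
#' @param X standardized numeric matrix (patients x features).
#' @param y binary labels.
#' @param config a [dnetpro_config()].
#' @param seed integer seed for the fold assignment.
#' @return a `couple_scores` data.frame with columns `i`, `j` (1-based
#'   column indices, `i < j`), `score`; attribute `"features"` carries the
#'   column names.
#' @export
score_couples <- function(X, y, config = dnetpro_config(), seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("couple scoring needs at least 2 features")
  if (p > config$p_max)
    stop("refusing to score choose(", p, ", 2) couples; pre-filter the ",
         "table to one feature category (or raise p_max) first")
  y01 <- as.integer(as.factor(y)) - 1L
  folds <- make_stratified_folds(y01, config$inner_folds, seed)
  m <- .cpp_score_couples(X, as.numeric(y01), as.integer(folds),
                          config$cost, 1e-5, 1000, config$metric)
  res <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                    score = m[, 3])
  attr(res, "features") <- colnames(X) %||% paste0("f", seq_len(p))
  class(res) <- c("couple_scores", "data.frame")
  res
}

#' Build the couple network from scored couples
#'
#' Retains the top `ceiling(keep_fraction * n_couples)` couples by score
#' (ties broken by lower `i`, then lower `j`, for determinism); the
#' retained couples are the edges of a weighted graph whose connected
#' components are the candidate signatures.
#'
#' @param couples a `couple_scores` data.frame from [score_couples()].
#' @param keep_fraction fraction of couples to retain, in `(0, 1]`.
#' @return a `signature_network`: list with `nodes`, `edges` (data.frame
#'   `name_i`, `name_j`, `score`), `membership` (named integer vector,
#'   component id per node) and `graph` (an igraph object).
#' @export
build_network <- function(couples, keep_fraction = 0.05) {
  stopifnot(inherits(couples, "couple_scores"),
            keep_fraction > 0, keep_fraction <= 1)
  if (nrow(couples) == 0) stop("empty couple list")
  feats <- attr(couples, "features")
  ord <- order(-couples$score, couples$i, couples$j)
  n_keep <- ceiling(keep_fraction * nrow(couples))
  kept <- couples[ord[seq_len(n_keep)], , drop = FALSE]
  edges <- data.frame(name_i = feats[kept$i], name_j = feats[kept$j],
                      score = kept$score, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("name_i", "name_j")],
                                     directed = FALSE)
  igraph::E(g)$score <- edges$score
  comp <- igraph::components(g)
  membership <- comp$membership[igraph::V(g)$name]
  structure(list(nodes = igraph::V(g)$name, edges = edges,
                 membership = membership, graph = g),
            class = "signature_network")
}

#' @export
print.signature_network <- function(x, ...) {
  cat("<signature_network> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", max(x$membership), " component(s)\n",
      sep = "")
  invisible(x)
}

#' Component feature sets of a signature network
#'
#' @param network a `signature_network`.
#' @return list of character vectors (feature names), one per connected
#'   component, in component-id order.
#' @export
network_components <- function(network) {
  split(names(network$membership), network$membership)
}

# ---- penalized logistic model --------------------------------------------

# Newton/IRLS ridge-logistic used when glmnet refuses the fit (a class
# with a single observation in a tiny split); unpenalized intercept.
.irls_ridge <- function(X, y, lambda_total) {
  Xa <- cbind(1, X)
  b <- rep(0, ncol(Xa))
  P <- diag(c(0, rep(lambda_total, ncol(X))), ncol(Xa))
  for (it in 1:50) {
    eta <- drop(Xa %*% b)
    mu <- 1 / (1 + exp(-eta))
    wv <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(Xa, y - mu)) - drop(P %*% b)
    H <- crossprod(Xa, Xa * wv) + P
    d <- solve(H, g)
    b <- b + d
    if (max(abs(d)) < 1e-10) break
  }
  b
}

# glmnet requires >= 2 columns; single-feature models get a zero padding
# column whose coefficient is exactly zero under the L2 penalty.
ridge_fit <- function(X, y, penalty) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  pad <- ncol(X) == 1
  if (pad) X <- cbind(X, 0)
  if (min(table(y)) >= 2) {
    # tiny splits trip glmnet's small-class advisory; expected here
    m <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = penalty / nrow(X), standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than.*observations", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    structure(list(model = m, pad = pad, lambda = penalty / nrow(X)),
              class = "radsig_ridge")
  } else {
    structure(list(coef = .irls_ridge(X, y, penalty), pad = pad),
              class = "radsig_ridge")
  }
}

ridge_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (fit$pad) X <- cbind(X, 0)
  if (!is.null(fit$model))
    as.integer(predict(fit$model, newx = X, s = fit$lambda,
                       type = "response") > 0.5)
  else
    as.integer(drop(cbind(1, X) %*% fit$coef) > 0)
}

#' Cross-validated evaluation of a candidate signature
#'
#' Mean out-of-fold MCC of the L2-penalized logistic model on the
#' component's features under stratified cross-validation.  Folds whose
#' training part is single-class are skipped (and counted in the
#' `"skipped"` attribute).
#'
#' @param X_sub standardized matrix restricted to the component's features
#'   (>= 1 column).
#' @param y binary labels.
#' @param eval_folds number of stratified folds.
#' @param penalty L2 penalty strength.
#' @param seed integer seed for the folds.
#' @return mean out-of-fold MCC in `[-1, 1]`.
#' @export
evaluate_signature <- function(X_sub, y, eval_folds = 5, penalty = 1,
                               seed = 1) {
  X_sub <- as.matrix(X_sub)
  stopifnot(ncol(X_sub) >= 1)
  y01 <- as.integer(as.factor(y)) - 1L
  folds <- make_stratified_folds(y01, eval_folds, seed)
  scores <- c(); skipped <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2) { skipped <- skipped + 1L; next }
    fit <- ridge_fit(X_sub[tr, , drop = FALSE], y01[tr], penalty)
    pred <- ridge_predict(fit, X_sub[!tr, , drop = FALSE])
    scores <- c(scores, mcc_pred(y01[!tr], pred))
  }
  out <- if (length(scores)) mean(scores) else 0
  attr(out, "skipped") <- skipped
  out
}

# score and rank the components of a network on given data; returns a
# data.frame ordered best-first with a deterministic tie-break
.rank_components <- function(network, X, y, eval_folds, penalty, seed,
                             Xval = NULL, yval = NULL) {
  stopifnot(!is.null(colnames(X)))
  comps <- network_components(network)
  rows <- lapply(seq_along(comps), function(ci) {
    feats <- comps[[ci]]
    key <- paste(sort(feats), collapse = "|")
    sc <- if (is.null(Xval)) {
      as.numeric(evaluate_signature(X[, feats, drop = FALSE], y,
                                    eval_folds, penalty, seed))
    } else {
      fit <- ridge_fit(X[, feats, drop = FALSE], y, penalty)
      mcc_pred(yval, ridge_predict(fit, Xval[, feats, drop = FALSE]))
    }
    data.frame(component = ci, key = key, n_features = length(feats),
               eval_score = sc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(-res$eval_score, res$key), , drop = FALSE]
}

.make_signature <- function(features, network, eval_score, procedure) {
  keep_nodes <- intersect(network$nodes, features)
  sub <- igraph::induced_subgraph(network$graph, keep_nodes)
  edges <- network$edges[network$edges$name_i %in% keep_nodes &
                           network$edges$name_j %in% keep_nodes, ,
                         drop = FALSE]
  net <- structure(list(nodes = igraph::V(sub)$name, edges = edges,
                        membership = setNames(rep(1L,
                                                  length(igraph::V(sub))),
                                              igraph::V(sub)$name),
                        graph = sub),
                   class = "signature_network")
  structure(list(features = sort(features), network = net,
                 eval_score = eval_score, procedure = procedure),
            class = "dnetpro_signature")
}

#' @export
print.dnetpro_signature <- function(x, ...) {
  cat("<dnetpro_signature> procedure ", x$procedure, ", ",
      length(x$features), " feature(s), eval score ",
      format(x$eval_score, digits = 3), "\n", sep = "")
  cat("  ", paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' DNetPRO procedure A
#'
#' Outer stratified cross-validation.  Within each outer training split:
#' z-score standardization is fitted, all couples are scored, the couple
#' network is built, every connected component is evaluated by inner
#' cross-validation on the same training data, and the best component is
#' refit with the penalized logistic model and scored on the outer test
#' split.  The returned signature is the consensus winner: the component
#' (as a feature set) that wins the most outer splits, ties broken by
#' mean evaluation score; its network is taken from its best-scoring
#' winning split.
#'
#' @param X numeric matrix (patients x features, unstandardized; scaling
#'   is fitted inside each training split).
#' @param y binary labels.
#' @param config a [dnetpro_config()].
#' @param seed integer master seed.
#' @return list with `signature` (a `dnetpro_signature`), `cv` (a
#'   [cv_result()] of outer-test MCCs) and `splits` (per-split winners).
#' @export
procedure_A <- function(X, y, config = dnetpro_config(), seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y01 <- as.integer(as.factor(y)) - 1L
  folds <- make_stratified_folds(y01, config$outer_folds,
                                 derive_seed(seed, 1))
  split_rows <- list(); winners <- list(); outer_scores <- numeric()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    sc <- fit_scaler(X[tr, , drop = FALSE], "zscore")
    Ztr <- apply_scaler(sc, X[tr, , drop = FALSE])
    Zte <- apply_scaler(sc, X[!tr, , drop = FALSE])
    couples <- score_couples(Ztr, y01[tr], config, derive_seed(seed, 100 + f))
    net <- build_network(couples, config$keep_fraction)
    ranking <- .rank_components(net, Ztr, y01[tr], config$eval_folds,
                                config$penalty, derive_seed(seed, 200 + f))
    best <- ranking[1, ]
    feats <- strsplit(best$key, "|", fixed = TRUE)[[1]]
    fit <- ridge_fit(Ztr[, feats, drop = FALSE], y01[tr], config$penalty)
    test_mcc <- mcc_pred(y01[!tr],
                         ridge_predict(fit, Zte[, feats, drop = FALSE]))
    outer_scores <- c(outer_scores, test_mcc)
    winners[[as.character(f)]] <- list(key = best$key, feats = feats,
                                       eval = best$eval_score, net = net)
    split_rows[[as.character(f)]] <-
      data.frame(fold = f, key = best$key, n_features = best$n_features,
                 eval_score = best$eval_score, test_mcc = test_mcc,
                 stringsAsFactors = FALSE)
  }
  splits <- do.call(rbind, split_rows)
  agg <- aggregate(eval_score ~ key, splits, mean)
  agg$wins <- as.vector(table(splits$key)[agg$key])
  agg <- agg[order(-agg$wins, -agg$eval_score, agg$key), , drop = FALSE]
  best_key <- agg$key[1]
  cand <- Filter(function(w) w$key == best_key, winners)
  top <- cand[[which.max(vapply(cand, `[[`, 0, "eval"))]]
  signature <- .make_signature(top$feats, top$net,
                               mean(splits$eval_score[splits$key ==
                                                        best_key]), "A")
  list(signature = signature,
       cv = cv_result(outer_scores, n_repeats = 1,
                      n_folds = config$outer_folds,
                      pipeline_id = "dnetpro_A", seed = seed),
       splits = splits)
}

#' DNetPRO procedure B
#'
#' Stratified three-way hold-out: couples are scored and the network is
#' built on the training part, the candidate components are ranked on the
#' validation part, and the best component is scored on the test part.
#' The three parts rotate through the roles so each serves once in each
#' (or, with `b_repartition`, three independent partitions are drawn).
#' Returns the best signature across the three iterations and the three
#' test MCCs.
#'
#' @inheritParams procedure_A
#' @return list with `signature` (a `dnetpro_signature`), `cv` (a
#'   [cv_result()] with the 3 test MCCs) and `splits`.
#' @export
procedure_B <- function(X, y, config = dnetpro_config(), seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y01 <- as.integer(as.factor(y)) - 1L
  if (min(table(y01)) < 3)
    stop("procedure B needs at least 3 samples per class for a ",
         "stratified three-way partition")
  split_rows <- list(); iters <- list()
  for (t in 1:3) {
    parts <- if (config$b_repartition)
      stratified_partition(y01, 3, derive_seed(seed, 300 + t))
    else stratified_partition(y01, 3, derive_seed(seed, 300))
    roles <- ((0:2 + t - 1) %% 3) + 1 # train, validation, test part ids
    tr <- parts == roles[1]; va <- parts == roles[2]; te <- parts == roles[3]
    sc <- fit_scaler(X[tr, , drop = FALSE], "zscore")
    Ztr <- apply_scaler(sc, X[tr, , drop = FALSE])
    Zva <- apply_scaler(sc, X[va, , drop = FALSE])
    Zte <- apply_scaler(sc, X[te, , drop = FALSE])
    couples <- score_couples(Ztr, y01[tr], config, derive_seed(seed, 400 + t))
    net <- build_network(couples, config$keep_fraction)
    ranking <- .rank_components(net, Ztr, y01[tr], config$eval_folds,
                                config$penalty, derive_seed(seed, 500 + t),
                                Xval = Zva, yval = y01[va])
    best <- ranking[1, ]
    feats <- strsplit(best$key, "|", fixed = TRUE)[[1]]
    fit <- ridge_fit(Ztr[, feats, drop = FALSE], y01[tr], config$penalty)
    test_mcc <- mcc_pred(y01[te],
                         ridge_predict(fit, Zte[, feats, drop = FALSE]))
    iters[[t]] <- list(feats = feats, net = net, test_mcc = test_mcc,
                       val_mcc = best$eval_score)
    split_rows[[t]] <- data.frame(iteration = t, key = best$key,
                                  n_features = best$n_features,
                                  val_mcc = best$eval_score,
                                  test_mcc = test_mcc,
                                  stringsAsFactors = FALSE)
  }
  splits <- do.call(rbind, split_rows)
  best_t <- which.max(vapply(iters, `[[`, 0, "test_mcc"))
  top <- iters[[best_t]]
  signature <- .make_signature(top$feats, top$net, top$test_mcc, "B")
  list(signature = signature,
       cv = cv_result(vapply(iters, `[[`, 0, "test_mcc"), n_repeats = 3,
                      n_folds = 1, pipeline_id = "dnetpro_B", seed = seed),
       splits = splits)
}

#' Export a signature as a graph file plus node table
#'
#' Writes the signature network in GraphML and as an edge-list CSV, and a
#' node table with normalized degree centrality (`degree / (n - 1)`); the
#' hub(s) are the maximum-degree node(s).
#'
#' @param signature a `dnetpro_signature`.
#' @param path output path prefix; writes `<path>.graphml`,
#'   `<path>_edges.csv`, `<path>_nodes.csv`.
#' @return invisibly, the node table.
#' @export
export_signature <- function(signature, path) {
  g <- signature$network$graph
  n <- length(igraph::V(g))
  deg <- igraph::degree(g)
  centrality <- if (n > 1) deg / (n - 1) else setNames(0, names(deg))
  nodes <- data.frame(feature = names(deg), degree = as.integer(deg),
                      degree_centrality = as.numeric(centrality),
                      hub = deg == max(deg), stringsAsFactors = FALSE)
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  write.csv(signature$network$edges, paste0(path, "_edges.csv"),
            row.names = FALSE)
  write.csv(nodes, paste0(path, "_nodes.csv"), row.names = FALSE)
  invisible(nodes)
}
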