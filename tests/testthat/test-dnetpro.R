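test_that("all couples are scored, deterministically", {
  pm <- planted_matrix(60, 4, 1, seed = 1)
  cs <- score_couples(pm$X, pm$y, seed = 3)
  expect_equal(nrow(cs), choose(4, 2))
  expect_true(all(cs$i < cs$j))
  expect_true(all(cs$score >= -1 & cs$score <= 1))
  cs2 <- score_couples(pm$X, pm$y, seed = 3)
  expect_identical(cs, cs2)
  expect_error(score_couples(pm$X[, 1, drop = FALSE], pm$y), "at least 2")
  expect_error(score_couples(pm$X, pm$y,
                             dnetpro_config(p_max = 3)), "pre-filter")
})

test_that("couple scoring agrees exactly with a brute-force double-loop
           oracle", {
  pm <- planted_matrix(60, 10, 1.2, seed = 2)
  cfg <- dnetpro_config()
  cs <- score_couples(pm$X, pm$y, cfg, seed = 5)
  folds <- make_stratified_folds(pm$y, cfg$inner_folds, 5) # same folds
  row <- 1
  for (a in 1:9) for (b in (a + 1):10) {
    fold_scores <- c()
    for (f in 1:cfg$inner_folds) {
      tr <- folds != f
      fit <- linsvm_fit(pm$X[tr, c(a, b)], pm$y[tr], cost = cfg$cost)
      dec <- pm$X[!tr, c(a, b)] %*% fit$weights + fit$bias
      pred <- as.integer(dec > 0)
      fold_scores <- c(fold_scores, mcc_pred(pm$y[!tr], pred))
    }
    expect_equal(cs$score[row], mean(fold_scores), tolerance = 1e-12)
    expect_equal(c(cs$i[row], cs$j[row]), c(a, b))
    row <- row + 1
  }
})

test_that("the in-house SVM agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  pm <- planted_matrix(80, 2, 2.5, n_planted = 2, seed = 3)
  ours <- linsvm_fit(pm$X, pm$y)
  ref <- e1071::svm(pm$X, factor(pm$y), kernel = "linear", cost = 1,
                    scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  b_ref <- -ref$rho
  # e1071 labels the first level +1, flipping the sign convention
  sgn <- sign(sum(ours$weights * w_ref))
  expect_gt(abs(sum(ours$weights * w_ref)) /
              sqrt(sum(ours$weights^2) * sum(w_ref^2)), 0.99)
  pred_ours <- as.integer(pm$X %*% ours$weights + ours$bias > 0)
  pred_ref <- as.integer(as.character(predict(ref, pm$X)))
  expect_gt(mean(pred_ours == pred_ref), 0.97)
})

test_that("a strongly separated planted couple ranks first", {
  first <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(200 * 8), 200, 8)
      y <- rep(0:1, each = 100)
      X[y == 1, 1:2] <- X[y == 1, 1:2] + 3
    })
    cs <- score_couples(X, y, seed = s)
    top <- cs[which.max(cs$score), ]
    top$i == 1 && top$j == 2
  }, NA)
  expect_gte(mean(first), 0.95)
})

test_that("network construction keeps top couples and finds components
           matching a transitive-closure oracle", {
  # hand-built couple list: edges (a,b), (b,c), (d,e) survive
  cs <- data.frame(i = c(1L, 2L, 4L, 1L, 3L),
                   j = c(2L, 3L, 5L, 4L, 5L),
                   score = c(0.9, 0.8, 0.7, 0.1, 0.05))
  attr(cs, "features") <- letters[1:5]
  class(cs) <- c("couple_scores", "data.frame")
  net <- build_network(cs, keep_fraction = 0.6) # ceiling(3) edges
  comps <- network_components(net)
  expect_setequal(vapply(comps, paste, "", collapse = ""), c("abc", "de"))

  # keep_fraction = 1 on a complete scoring gives one component
  pm <- planted_matrix(40, 5, 0, seed = 4)
  full <- build_network(score_couples(pm$X, pm$y, seed = 1), 1)
  expect_equal(length(network_components(full)), 1)
  expect_setequal(full$nodes, paste0("f", 1:5))

  # random graphs vs brute-force transitive closure
  withr::with_seed(9, {
    for (rep in 1:10) {
      p <- sample(8:14, 1)
      ncpl <- choose(p, 2)
      cs <- data.frame(t(combn(p, 2)), score = runif(ncpl))
      names(cs) <- c("i", "j", "score")
      attr(cs, "features") <- paste0("n", seq_len(p))
      class(cs) <- c("couple_scores", "data.frame")
      net <- build_network(cs, keep_fraction = 0.2)
      oracle <- components_bruteforce(net$nodes, net$edges)
      got <- network_components(net)
      expect_setequal(
        unname(vapply(got, function(x) paste(sort(x), collapse = "|"), "")),
        unname(vapply(oracle, function(x) paste(sort(x), collapse = "|"),
                      "")))
    }
  })
})

test_that("increasing keep_fraction never drops a retained edge, and ties
           break deterministically by index", {
  pm <- planted_matrix(50, 8, 0.5, seed = 5)
  cs <- score_couples(pm$X, pm$y, seed = 2)
  prev <- NULL
  for (kf in c(0.05, 0.1, 0.3, 0.6, 1)) {
    net <- build_network(cs, kf)
    key <- paste(net$edges$name_i, net$edges$name_j)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
  cs$score <- rep(0.5, nrow(cs)) # all tied
  n1 <- build_network(cs, 0.2)
  n2 <- build_network(cs, 0.2)
  expect_identical(n1$edges, n2$edges)
  expect_equal(n1$edges$name_i[1], "f1") # lowest (i, j) wins ties
})

test_that("signature evaluation separates signal from noise", {
  pm <- planted_matrix(200, 5, 2, n_planted = 3, seed = 6)
  strong <- evaluate_signature(pm$X[, 1:3], pm$y, seed = 1)
  expect_gt(strong, 0.8)

  nulls <- vapply(1:100, function(s) {
    withr::with_seed(700 + s, {
      Xn <- matrix(rnorm(200 * 3), 200, 3)
      yn <- rep(0:1, each = 100)
    })
    as.numeric(evaluate_signature(Xn, yn, seed = s))
  }, 0)
  expect_lt(abs(mean(nulls)), 0.15)

  # single-feature component runs
  expect_no_error(evaluate_signature(pm$X[, 1, drop = FALSE], pm$y,
                                     seed = 1))
})

test_that("procedure A recovers a planted signature and is deterministic", {
  cfg <- dnetpro_config(outer_folds = 3, inner_folds = 3)
  hits <- vapply(1:10, function(s) {
    pm <- planted_matrix(150, 50, 1.5, n_planted = 3, seed = 4000 + s)
    res <- procedure_A(pm$X, pm$y, cfg, seed = s)
    sum(pm$planted %in% res$signature$features) >= 2
  }, NA)
  expect_gte(mean(hits), 0.9)

  pm <- planted_matrix(150, 20, 1.5, seed = 77)
  r1 <- procedure_A(pm$X, pm$y, cfg, seed = 9)
  r2 <- procedure_A(pm$X, pm$y, cfg, seed = 9)
  expect_identical(r1$signature$features, r2$signature$features)
  expect_identical(r1$cv$scores, r2$cv$scores)
})

test_that("procedure A on pure noise scores near zero", {
  cfg <- dnetpro_config(outer_folds = 3, inner_folds = 3)
  meds <- vapply(1:8, function(s) {
    pm <- planted_matrix(120, 20, 0, seed = 5000 + s)
    median(procedure_A(pm$X, pm$y, cfg, seed = s)$cv$scores)
  }, 0)
  expect_lt(abs(median(meds)), 0.15)
})

test_that("procedure B rotates a stratified three-way partition and
           enforces minimum sizes", {
  pm <- planted_matrix(9, 4, 1, seed = 8)
  res <- procedure_B(pm$X, pm$y, dnetpro_config(inner_folds = 2,
                                                eval_folds = 2), seed = 1)
  expect_equal(length(res$cv$scores), 3)
  expect_equal(nrow(res$splits), 3)

  pm5 <- planted_matrix(5, 4, 1, seed = 8)
  expect_error(procedure_B(pm5$X, pm5$y, dnetpro_config()), "3 samples")

  pm2 <- planted_matrix(60, 12, 1.5, seed = 9)
  b1 <- procedure_B(pm2$X, pm2$y, dnetpro_config(inner_folds = 3), seed = 4)
  b2 <- procedure_B(pm2$X, pm2$y, dnetpro_config(inner_folds = 3), seed = 4)
  expect_identical(b1$signature$features, b2$signature$features)
  expect_identical(b1$cv$scores, b2$cv$scores)
})

test_that("signature export writes degree centrality and round-trips", {
  # star: center c connected to 4 leaves
  cs <- data.frame(i = rep(1L, 4), j = 2:5,
                   score = c(0.9, 0.8, 0.7, 0.6))
  attr(cs, "features") <- c("c", "l1", "l2", "l3", "l4")
  class(cs) <- c("couple_scores", "data.frame")
  net <- build_network(cs, 1)
  sig <- radsig:::.make_signature(net$nodes, net, 0.5, "A")
  dir <- withr::local_tempdir()
  nodes <- export_signature(sig, file.path(dir, "sig"))
  expect_equal(nodes$degree_centrality[nodes$feature == "c"], 1)
  expect_true(all(nodes$degree_centrality[nodes$feature != "c"] == 0.25))
  expect_true(nodes$hub[nodes$feature == "c"])

  g2 <- igraph::read_graph(file.path(dir, "sig.graphml"),
                           format = "graphml")
  expect_true(igraph::isomorphic(g2, sig$network$graph))
  edges <- read.csv(file.path(dir, "sig_edges.csv"))
  expect_equal(sort(edges$score), sort(sig$network$edges$score))
})
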