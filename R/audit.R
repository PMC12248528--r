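#' @name embedding_audit-module
#' @title Unsupervised batch-effect and structure audit
#'
#' @description
#' Before any supervised modelling, the cohort is audited for acquisition
#' batch effects: features are robust-scaled (median / IQR), projected to
#' two dimensions, clustered with a density-based hierarchical method that
#' allows noise points, and every pair of clusters is tested for
#' enrichment in acquisition center and in tumor type with a two-sided
#' Fisher exact test (Benjamini-Hochberg adjusted across pairs).  A joint
#' center-by-tumor Fisher test on the full cohort checks whether the class
#' distribution differs between centers, which would confound any
#' center-linked structure with biology.
NULL

#' 2-D embedding of a feature table
#'
#' Deterministic projection of the (robust-standardized) feature table
#' onto two dimensions.  The default method is a principal-component
#' projection; the audit contract only requires a deterministic map to two
#' dimensions, so the stage is swappable.
#'
#' @param table a `feature_table`, robust-standardized (a warning is
#'   emitted otherwise).
#' @param seed integer seed (recorded; the default method is deterministic
#'   and does not consume randomness).
#' @param params list of method parameters; `method` is `"pca"`.
#' @return an `embedding_result`: list with `coords` (n x 2 matrix),
#'   `algorithm_params`, `seed`.
#' @export
embed_2d <- function(table, seed = 1, params = list(method = "pca")) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  if (n < 10)
    stop("embedding needs at least 10 patients (got ", n,
         "); the neighbourhood structure is meaningless below that")
  if (!identical(attr(table, "standardized"), "robust"))
    warning("feature table does not appear to be robust-standardized; ",
            "run standardize(table, 'robust') first")
  method <- params$method %||% "pca"
  coords <- with_seed(seed, {
    switch(method,
      pca = {
        pc <- prcomp(table$values, center = TRUE, scale. = FALSE,
                     rank. = 2)
        co <- pc$x[, 1:2, drop = FALSE]
        # fix the sign convention so the projection is reproducible across
        # LAPACK builds
        for (j in 1:2) {
          ld <- pc$rotation[, j]
          if (ld[which.max(abs(ld))] < 0) co[, j] <- -co[, j]
        }
        co
      },
      stop("unknown embedding method: ", method))
  })
  if (!all(is.finite(coords))) stop("embedding produced non-finite coordinates")
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- table$patient_ids
  structure(list(coords = coords,
                 algorithm_params = c(list(method = method),
                                      params[setdiff(names(params),
                                                     "method")]),
                 seed = as.integer(seed)),
            class = "embedding_result")
}

# ---- density-based hierarchical clustering --------------------------------

# Condensed-tree HDBSCAN on a distance matrix: core distances at
# k = min_cluster_size, mutual-reachability single-linkage hierarchy,
# erosion of sub-minimum side branches, excess-of-mass stability
# selection.  Selecting the root (a single cluster) is allowed, so a
# structureless cloud yields one cluster rather than an arbitrary split.
.hdbscan_labels <- function(coords, min_cluster_size) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  k <- min(min_cluster_size, n - 1)
  core <- apply(d, 1, function(r) sort(r)[k + 1]) # k-th nearest other point
  mrd <- pmax(d, outer(core, core, pmax))
  diag(mrd) <- 0
  hc <- hclust(as.dist(mrd), method = "single")

  # members of each merge-tree node (hclust convention: negatives = leaves)
  members <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    ch <- hc$merge[m, ]
    members[[m]] <- c(if (ch[1] < 0) -ch[1] else members[[ch[1]]],
                      if (ch[2] < 0) -ch[2] else members[[ch[2]]])
  }
  lam <- function(h) if (h <= 1e-12) 1e12 else 1 / h

  clusters <- list() # each: list(birth, stability, children ids, fallen pts)
  point_cluster <- integer(n)   # condensed cluster each point fell out of
  point_lambda <- numeric(n)

  pts_of <- function(c1) if (c1 < 0) -c1 else members[[c1]]
  build <- function(node, lambda_birth) {
    id <- length(clusters) + 1L
    clusters[[id]] <<- list() # reserve slot to keep ids topological
    fallen <- integer(); fallen_l <- numeric()
    children <- integer()
    stability <- 0
    cur <- node
    repeat {
      if (cur < 0) { # cluster reduced to one point; persists to max density
        fallen <- c(fallen, -cur); fallen_l <- c(fallen_l, 1e12)
        break
      }
      h <- hc$height[cur]; l <- lam(h)
      ch <- hc$merge[cur, ]
      sz <- vapply(ch, function(c1)
        if (c1 < 0) 1L else length(members[[c1]]), 1L)
      big <- sz >= min_cluster_size
      if (h > 1e-12 && all(big)) { # true split: two valid children
        children <- c(build(ch[1], l), build(ch[2], l))
        stability <- stability + sum(sz) * (l - lambda_birth)
        break
      }
      if (h > 1e-12 && !any(big)) { # cluster disperses entirely
        for (s in 1:2) {
          pts <- pts_of(ch[s])
          fallen <- c(fallen, pts)
          fallen_l <- c(fallen_l, rep(l, length(pts)))
        }
        break
      }
      # erosion (or a zero-height merge, where points are inseparable and
      # nothing truly splits): the off side falls out at this density,
      # the walk continues into the surviving branch
      into <- if (any(big)) which(big)[1] else which.max(sz)
      pts <- pts_of(ch[3 - into])
      fallen <- c(fallen, pts)
      fallen_l <- c(fallen_l, rep(l, length(pts)))
      cur <- ch[into]
    }
    stability <- stability + sum(fallen_l - lambda_birth)
    point_cluster[fallen] <<- id
    point_lambda[fallen] <<- fallen_l
    clusters[[id]] <<- list(birth = lambda_birth, stability = stability,
                            children = children)
    id
  }
  root <- build(nrow(hc$merge), 0)

  # excess-of-mass: keep a cluster if it is more stable than the sum of
  # its selected descendants
  selected <- logical(length(clusters))
  select <- function(id) { # returns total stability of the selection below
    cl <- clusters[[id]]
    if (length(cl$children) == 0) { selected[id] <<- TRUE; return(cl$stability) }
    child_total <- sum(vapply(cl$children, select, 0))
    if (cl$stability > child_total) {
      unselect <- function(j) {
        selected[j] <<- FALSE
        for (c1 in clusters[[j]]$children) unselect(c1)
      }
      for (c1 in cl$children) unselect(c1)
      selected[id] <<- TRUE
      cl$stability
    } else child_total
  }
  select(root)

  # map each point to its nearest selected ancestor-or-self
  parent <- integer(length(clusters))
  for (id in seq_along(clusters))
    for (c1 in clusters[[id]]$children) parent[c1] <- id
  labels <- integer(n)
  for (i in seq_len(n)) {
    id <- point_cluster[i]
    while (id != 0 && !selected[id]) id <- parent[id]
    labels[i] <- id # 0 = noise
  }
  # deterministic relabel 0..K-1 by smallest member index; noise = -1
  keep <- sort(unique(labels[labels != 0]))
  keep <- keep[order(vapply(keep, function(id) min(which(labels == id)), 1L))]
  out <- rep(-1L, n)
  for (j in seq_along(keep)) out[labels == keep[j]] <- j - 1L
  out
}

#' Density-based hierarchical clustering of a 2-D embedding
#'
#' Hierarchical density clustering in the style of HDBSCAN: mutual
#' reachability distances from k-nearest-neighbour core distances, a
#' single-linkage hierarchy, erosion of branches smaller than
#' `min_cluster_size`, and excess-of-mass stability selection of the flat
#' clustering.  Points that never join a stable cluster are labelled noise
#' (`-1`).
#'
#' @param embedding an `embedding_result` (or a bare n x 2 matrix).
#' @param min_cluster_size minimum cluster size (>= 2); default 5.
#' @return a `cluster_assignment`: list with `labels` (integer vector,
#'   `-1` noise, clusters `0..K-1`) and `n_clusters`.
#' @export
cluster_density <- function(embedding, min_cluster_size = 5) {
  coords <- if (inherits(embedding, "embedding_result"))
    embedding$coords else as.matrix(embedding)
  stopifnot(min_cluster_size >= 2)
  labels <- .hdbscan_labels(coords, min_cluster_size)
  structure(list(labels = labels,
                 n_clusters = length(unique(labels[labels >= 0]))),
            class = "cluster_assignment")
}

#' Pairwise Fisher enrichment of clusters in a binary category
#'
#' For every unordered pair of non-noise clusters, builds the 2 x 2 table
#' (cluster membership x category level) from the members of the two
#' clusters only and computes the two-sided Fisher exact p-value; p-values
#' are Benjamini-Hochberg adjusted across the pairs.
#'
#' @param assignment a `cluster_assignment`.
#' @param category binary vector (factor/character/0-1) aligned with the
#'   assignment; noise points are excluded.
#' @return data.frame with one row per cluster pair: `cluster_a`,
#'   `cluster_b`, the 2 x 2 counts, `p_value`, `p_adjusted`.  Zero rows
#'   (with a message) when fewer than two non-noise clusters exist.
#' @export
cluster_enrichment <- function(assignment, category) {
  labels <- assignment$labels
  stopifnot(length(category) == length(labels))
  category <- factor(category)
  if (nlevels(category) != 2)
    stop("category must have exactly two levels")
  cl <- sort(unique(labels[labels >= 0]))
  if (length(cl) < 2) {
    message("fewer than two non-noise clusters; no enrichment tests run")
    return(data.frame(cluster_a = integer(), cluster_b = integer(),
                      a1 = integer(), a2 = integer(), b1 = integer(),
                      b2 = integer(), p_value = numeric(),
                      p_adjusted = numeric()))
  }
  pairs <- utils::combn(cl, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    ca <- pairs[1, q]; cb <- pairs[2, q]
    ina <- labels == ca; inb <- labels == cb
    tab <- rbind(table(factor(category[ina], levels = levels(category))),
                 table(factor(category[inb], levels = levels(category))))
    data.frame(cluster_a = ca, cluster_b = cb,
               a1 = tab[1, 1], a2 = tab[1, 2],
               b1 = tab[2, 1], b2 = tab[2, 2],
               p_value = fisher.test(tab, alternative = "two.sided")$p.value)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}

#' Full batch-effect audit
#'
#' Runs robust scaling, 2-D embedding, density clustering, pairwise
#' cluster enrichment for both the acquisition center and the tumor label,
#' and the joint center x tumor Fisher test on the full cohort.
#'
#' @param table a raw (unstandardized) `feature_table`.
#' @param centers center factor (two levels) aligned with the table.
#' @param labels binary tumor labels aligned with the table.
#' @param seed integer seed for the embedding stage.
#' @param min_cluster_size passed to [cluster_density()].
#' @return an `audit_report`: list with `embedding`, `clusters`,
#'   `enrichment` (list with `center` and `tumor` data.frames),
#'   `joint_center_tumor_p`, `seed`.
#' @export
audit_report <- function(table, centers, labels, seed = 1,
                         min_cluster_size = 5) {
  stopifnot(length(centers) == nrow(table$values),
            length(labels) == nrow(table$values))
  scaled <- standardize(table, "robust")$table
  emb <- embed_2d(scaled, seed = seed)
  cls <- cluster_density(emb, min_cluster_size = min_cluster_size)
  enr <- list(center = cluster_enrichment(cls, centers),
              tumor = cluster_enrichment(cls, labels))
  joint <- fisher.test(table(factor(centers), factor(labels)),
                       alternative = "two.sided")$p.value
  structure(list(embedding = emb, clusters = cls, enrichment = enr,
                 joint_center_tumor_p = joint, seed = as.integer(seed)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report> ", nrow(x$embedding$coords), " patients, ",
      x$clusters$n_clusters, " cluster(s), ",
      sum(x$clusters$labels == -1L), " noise point(s)\n", sep = "")
  for (nm in names(x$enrichment)) {
    e <- x$enrichment[[nm]]
    if (nrow(e))
      cat("  ", nm, ": min adjusted p = ",
          format(min(e$p_adjusted), digits = 3), " over ", nrow(e),
          " cluster pair(s)\n", sep = "")
    else cat("  ", nm, ": no testable cluster pairs\n", sep = "")
  }
  cat("  joint center x tumor Fisher p = ",
      format(x$joint_center_tumor_p, digits = 3), "\n", sep = "")
  invisible(x)
}
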