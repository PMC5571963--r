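#' Log2 differential-expression ratio matrix
#'
#' Builds the gene x condition matrix of `log2(RPKM_condition /
#' RPKM_reference)` over the genes detected (RPKM >= `min_rpkm`) in
#' every listed library — the input to expression-ratio clustering.
#'
#' @param rpkm RPKM matrix (columns = libraries).
#' @param conditions Condition column names (each compared to the
#'   reference).
#' @param reference Reference column name (e.g. wild type).
#' @param min_rpkm Detection threshold applied to every listed column
#'   (default 1).
#' @return Numeric gene x condition matrix of log2 ratios.
#' @export
log2_ratio_matrix <- function(rpkm, conditions, reference, min_rpkm = 1) {
  cols <- c(reference, conditions)
  miss <- setdiff(cols, colnames(rpkm))
  if (length(miss)) {
    stop_param("log2_ratio_matrix: missing columns: %s",
               paste(miss, collapse = ", "))
  }
  keep <- rowSums(rpkm[, cols, drop = FALSE] >= min_rpkm) == length(cols)
  if (!any(keep)) {
    stop_param("log2_ratio_matrix: no gene detected in all libraries")
  }
  m <- log2(rpkm[keep, conditions, drop = FALSE] / rpkm[keep, reference])
  colnames(m) <- conditions
  m
}

#' K-means clustering of a ratio matrix
#'
#' Lloyd's algorithm under Euclidean dissimilarity with k-means++
#' initialization, run `n_restarts` times from seeded substreams; the
#' restart with the lowest within-cluster sum of squares (WCSS) wins.
#' WCSS is asserted non-increasing across Lloyd iterations. Results are
#' deterministic for a fixed `(seed, n_restarts)`.
#'
#' @param matrix Numeric gene x condition matrix (rownames = gene ids).
#' @param k Number of clusters (2 <= k <= rows).
#' @param seed Integer seed.
#' @param n_restarts Independent initializations (default 20).
#' @param max_iter Lloyd iteration cap (default 100).
#' @return Object of class `cluster_result`: `labels` (named integer
#'   vector in 1..k), `centroids` (k x conditions), `k`, `wcss`,
#'   `db_index`, `merge_log` (empty), `iterations`.
#' @export
kmeans_cluster <- function(matrix, k, seed = 1L, n_restarts = 20L,
                           max_iter = 100L) {
  if (!is.matrix(matrix) || is.null(rownames(matrix))) {
    stop_param("kmeans_cluster: 'matrix' must have gene rownames")
  }
  if (k < 2 || k > nrow(matrix)) {
    stop_param("kmeans_cluster: 'k' must lie in [2, %d]", nrow(matrix))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- local_seed(substream_seed(seed, r),
                      lloyd_once(matrix, k, max_iter))
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  labels <- stats::setNames(best$labels, rownames(matrix))
  db <- if (length(unique(labels)) >= 2) {
    davies_bouldin(matrix, labels)
  } else NA_real_
  structure(list(labels = labels, centroids = best$centroids, k = k,
                 wcss = best$wcss, db_index = db,
                 merge_log = character(0), iterations = best$iterations),
            class = "cluster_result")
}

# One Lloyd run from a k-means++ start. Empty clusters are re-seeded
# with the point farthest from its centroid.
lloyd_once <- function(x, k, max_iter) {
  centers <- x[kmeanspp_init(x, k), , drop = FALSE]
  wcss_prev <- Inf
  labels <- integer(nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- point_center_dist2(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        labels[far] <- j
      }
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    wcss <- sum((x - centers[labels, , drop = FALSE])^2)
    stopifnot(wcss <= wcss_prev + 1e-8)  # Lloyd monotonicity
    if (wcss_prev - wcss < 1e-12) break
    wcss_prev <- wcss
  }
  list(labels = labels, centroids = centers, wcss = wcss, iterations = it)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
  for (j in seq_len(k)[-1]) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
  }
  idx
}

point_center_dist2 <- function(x, centers) {
  cross <- x %*% t(centers)
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  pmax(outer(xs, cs, "+") - 2 * cross, 0)
}

#' Davies-Bouldin cluster-validity index
#'
#' `DB = (1/K) * sum_i max_{j != i} (S_i + S_j) / M_ij`, where `S_i` is
#' the mean Euclidean distance of cluster `i`'s members from their
#' centroid and `M_ij` the Euclidean distance between centroids `i` and
#' `j`. Lower is better; coincident centroids yield `Inf`.
#'
#' @param matrix Numeric data matrix.
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @return The index (scalar; `Inf` when two centroids coincide).
#' @export
davies_bouldin <- function(matrix, labels) {
  lv <- sort(unique(labels))
  if (length(lv) < 2) stop_param("davies_bouldin: need >= 2 clusters")
  cents <- t(vapply(lv, function(l) colMeans(matrix[labels == l, , drop = FALSE]),
                    numeric(ncol(matrix))))
  S <- vapply(seq_along(lv), function(i) {
    mem <- matrix[labels == lv[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2, cents[i, ], "-")^2)))
  }, numeric(1))
  K <- length(lv)
  ratios <- vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) {
      M <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      if (M == 0) Inf else (S[i] + S[j]) / M
    }, numeric(1)))
  }, numeric(1))
  mean(ratios)
}

#' Choose the number of clusters by the Davies-Bouldin profile
#'
#' Computes the DB index of [kmeans_cluster()] fits over `k_range` and
#' returns the local minimum of the profile with the lowest DB value
#' (smallest k on ties) — an automated surrogate for choosing K by
#' inspecting DB local minima for good separation. A monotone
#' decreasing profile returns the largest k in the range, flagged in
#' the log.
#'
#' @param matrix Numeric gene x condition matrix.
#' @param k_range Candidate k values (default 2:8).
#' @param seed Integer seed.
#' @param n_restarts Restarts per fit (default 20).
#' @return List: `k` (chosen), `profile` (data.frame `k`, `db`),
#'   `note` (character).
#' @export
select_k <- function(matrix, k_range = 2:8, seed = 1L, n_restarts = 20L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > nrow(matrix)) {
    stop_param("select_k: 'k_range' must lie in [2, %d]", nrow(matrix))
  }
  db <- vapply(k_range, function(k) {
    kmeans_cluster(matrix, k, seed = seed, n_restarts = n_restarts)$db_index
  }, numeric(1))
  pick <- db_profile_pick(db)
  list(k = k_range[pick$index], profile = data.frame(k = k_range, db = db),
       note = pick$note)
}

# Position of the chosen k in a DB profile: the local minimum with the
# lowest DB (smallest index on ties); endpoints count as minima against
# their single neighbour.
db_profile_pick <- function(db) {
  n <- length(db)
  is_min <- vapply(seq_len(n), function(i) {
    (i == 1 || db[i] < db[i - 1]) && (i == n || db[i] < db[i + 1])
  }, logical(1))
  note <- ""
  if (any(is_min)) {
    cand <- which(is_min)
    index <- cand[which.min(db[cand])]
    if (index == n && n > 1 && all(diff(db) < 0)) {
      note <- "DB profile monotone decreasing; largest k in range chosen"
    }
  } else {
    index <- which.min(db)
    note <- "no strict local minimum; global minimum chosen"
  }
  list(index = index, note = note)
}

#' Merge single-gene clusters into their nearest neighbor
#'
#' Every cluster of size one is combined into the cluster whose centroid
#' is nearest (Euclidean) to the singleton gene; ties go to the
#' lower-numbered cluster and are logged. Centroids, WCSS and the DB
#' index are recomputed and labels renumbered 1..K.
#'
#' @param result A `cluster_result`.
#' @param matrix The data matrix the result was fit on.
#' @return A `cluster_result` with no singleton clusters and a
#'   `merge_log` describing each merge.
#' @export
merge_singletons <- function(result, matrix) {
  stopifnot(inherits(result, "cluster_result"))
  labels <- result$labels
  log <- result$merge_log
  repeat {
    sizes <- table(labels)
    singles <- as.integer(names(sizes)[sizes == 1])
    if (!length(singles)) break
    if (all(sizes == 1)) {
      stop_param("merge_singletons: all clusters are singletons; no merge target")
    }
    l <- singles[1]
    g <- names(labels)[labels == l]
    others <- setdiff(as.integer(names(sizes)), l)
    cents <- t(vapply(others, function(j) {
      colMeans(matrix[names(labels)[labels == j], , drop = FALSE])
    }, numeric(ncol(matrix))))
    d <- sqrt(rowSums(sweep(cents, 2, matrix[g, ], "-")^2))
    tied <- others[d <= min(d) + 1e-12]
    target <- min(tied)
    if (length(tied) > 1) {
      log <- c(log, sprintf("tie: singleton %s equidistant to clusters %s; merged into %d",
                            g, paste(tied, collapse = ","), target))
    }
    log <- c(log, sprintf("merged singleton cluster %d (gene %s) into cluster %d",
                          l, g, target))
    labels[labels == l] <- target
  }
  lv <- sort(unique(labels))
  relab <- stats::setNames(seq_along(lv), lv)
  labels <- stats::setNames(relab[as.character(labels)], names(result$labels))
  k <- length(lv)
  cents <- t(vapply(seq_len(k), function(j) {
    colMeans(matrix[names(labels)[labels == j], , drop = FALSE])
  }, numeric(ncol(matrix))))
  wcss <- sum((matrix[names(labels), , drop = FALSE] -
                 cents[labels, , drop = FALSE])^2)
  db <- if (k >= 2) davies_bouldin(matrix[names(labels), , drop = FALSE], labels) else NA_real_
  structure(list(labels = labels, centroids = cents, k = k, wcss = wcss,
                 db_index = db, merge_log = log,
                 iterations = result$iterations),
            class = "cluster_result")
}
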