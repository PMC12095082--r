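# Partitioning around medoids on a precomputed dissimilarity matrix,
# silhouette-based model selection, heatmap ordering, and agreement.

check_dissimilarity <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("dissimilarity matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("dissimilarity matrix must have zero diagonal")
  D
}

#' Partitioning around medoids (classic BUILD + SWAP)
#'
#' Deterministic k-medoids on a precomputed dissimilarity matrix: greedy
#' cost-minimizing seeding (BUILD), then repeated application of the best
#' strictly-improving medoid/non-medoid swap until none remains (SWAP).
#' All ties break toward the lowest index. Clusters are renumbered in
#' decreasing order of size (ties by medoid index), so cluster 1 is always
#' the largest.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A `pam_clustering`: list with `ids`, `labels` (named integer
#'   vector in `1..k`), `medoid_ids`, `medoid_idx`, `k`, `total_cost`,
#'   `avg_silhouette` and `silhouette` (per point).
#' @export
pam <- function(D, k) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD: start from the point with the least total dissimilarity, then
  # greedily add the point giving the largest cost reduction.
  medoids <- which.min(colSums(D))
  dnear <- D[, medoids]
  while (length(medoids) < k) {
    gains <- vapply(seq_len(n), function(c) {
      if (c %in% medoids) return(-Inf)
      sum(pmax(dnear - D[, c], 0))
    }, numeric(1))
    add <- which.max(gains)
    medoids <- c(medoids, add)
    dnear <- pmin(dnear, D[, add])
  }

  cost_of <- function(m) sum(apply(D[, m, drop = FALSE], 1, min))
  cost <- cost_of(medoids)

  # SWAP: apply the single best strictly-improving swap, repeat to fixpoint.
  repeat {
    best_delta <- -1e-12
    best_swap <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (h in nonmed) {
        cand <- medoids
        cand[mi] <- h
        delta <- cost_of(cand) - cost
        if (delta < best_delta) {
          best_delta <- delta
          best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    cost <- cost + best_delta
  }

  # Assign to the nearest medoid (ties to the lowest medoid index).
  assign_raw <- apply(D[, medoids, drop = FALSE], 1, which.min)
  # Renumber clusters by decreasing size; ties by medoid index.
  sizes <- tabulate(assign_raw, nbins = k)
  ord <- order(-sizes, medoids)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[assign_raw]
  medoid_idx <- unname(medoids[ord])
  labels[medoid_idx] <- seq_len(k)   # each medoid belongs to its own cluster

  sil <- silhouette_widths(D, labels)
  structure(list(ids = ids, labels = setNames(labels, ids),
                 medoid_ids = ids[medoid_idx], medoid_idx = medoid_idx,
                 k = k, total_cost = cost_of(medoid_idx),
                 avg_silhouette = sil$average,
                 silhouette = sil$widths),
            class = "pam_clustering")
}

#' @export
print.pam_clustering <- function(x, ...) {
  cat("PAM clustering: k =", x$k, "| sizes:",
      paste(tabulate(x$labels, x$k), collapse = "/"),
      "| total cost:", signif(x$total_cost, 5),
      "| avg silhouette:", signif(x$avg_silhouette, 3), "\n")
  invisible(x)
}

#' Silhouette widths
#'
#' `a(i)` is the mean dissimilarity to the own cluster (excluding self),
#' `b(i)` the smallest mean dissimilarity to another cluster, and
#' `s(i) = (b - a) / max(a, b)`; members of singleton clusters get
#' `s(i) = 0` by convention. The average is the unweighted mean.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param labels Integer cluster labels (all clusters non-empty).
#' @return List with `widths` (per point) and `average`.
#' @export
silhouette_widths <- function(D, labels) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs at least two clusters")
  sizes <- table(factor(labels, levels = ks))
  if (any(sizes == 0)) stop("empty cluster")
  widths <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1) {
      widths[i] <- 0
      next
    }
    a <- mean(D[i, labels == own & seq_len(n) != i])
    b <- min(vapply(ks[ks != own], function(cl) mean(D[i, labels == cl]),
                    numeric(1)))
    widths[i] <- (b - a) / max(a, b)
  }
  list(widths = widths, average = mean(widths))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam()] for each `k` in `kmin..kmax` and picks the `k` with the
#' largest average silhouette width (ties toward smaller `k`). `k_override`
#' replaces the silhouette choice while keeping the full table — the
#' judgment call used when a neighbouring `k` is preferred for
#' comparability between strata.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param kmin,kmax Range of `k` (default 2..10; capped at `n - 1`).
#' @param k_override Optional integer forcing the returned `k`.
#' @return List with `k`, `assignment` (the `pam_clustering` at `k`) and
#'   `table` (data.frame of k vs avg_silhouette).
#' @export
select_k <- function(D, kmin = 2, kmax = 10, k_override = NULL) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  kmax <- min(kmax, n - 1)
  if (kmin > kmax) stop("kmin exceeds the feasible kmax")
  fits <- lapply(kmin:kmax, function(k) pam(D, k))
  tab <- data.frame(k = kmin:kmax,
                    avg_silhouette = vapply(fits, `[[`, numeric(1),
                                            "avg_silhouette"))
  k_star <- tab$k[which.max(tab$avg_silhouette)]
  if (!is.null(k_override)) {
    if (k_override < kmin || k_override > kmax) {
      stop("k_override outside the evaluated range")
    }
    k_star <- as.integer(k_override)
  }
  list(k = k_star, assignment = fits[[k_star - kmin + 1]], table = tab)
}

#' Order trajectories for a cluster-wise distance heatmap
#'
#' Groups ids by cluster (cluster 1 first) and, within each cluster, sorts
#' ascending by dissimilarity to the own medoid, so each medoid leads its
#' block and blocks appear dark in a distance heatmap.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param assignment A `pam_clustering`.
#' @return Integer permutation of `1..n`.
#' @export
order_for_heatmap <- function(D, assignment) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  labels <- assignment$labels
  d_own <- D[cbind(seq_len(n), assignment$medoid_idx[labels])]
  order(labels, d_own, seq_len(n))
}

# Adjusted Rand index between two labelings (standard contingency formula).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Agreement between two clusterings
#'
#' Maximizes the share of co-assigned points over all bijections between
#' cluster labels (exhaustive search over label permutations of the smaller
#' side; supported up to 8 clusters) and reports the adjusted Rand index
#' alongside.
#'
#' @param labels_a,labels_b Cluster labels over the same ids; when named,
#'   names are matched.
#' @return List with `agreement` (percent in `[0, 100]`), `table` (the
#'   contingency table) and `ari`.
#' @export
cluster_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop("labelings cover different id sets")
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("labelings cover different id sets")
  }
  tab <- table(labels_a, labels_b)
  ka <- nrow(tab); kb <- ncol(tab)
  if (min(ka, kb) > 8) stop("agreement matching supported up to 8 clusters")
  # Exhaustive optimal one-to-one matching of the smaller side.
  if (ka <= kb) {
    perms <- perm_rows(kb, ka)
    matched <- max(apply(perms, 1, function(p) sum(tab[cbind(seq_len(ka), p)])))
  } else {
    perms <- perm_rows(ka, kb)
    matched <- max(apply(perms, 1, function(p) sum(tab[cbind(p, seq_len(kb))])))
  }
  list(agreement = 100 * matched / length(labels_a),
       table = tab,
       ari = adjusted_rand_index(labels_a, labels_b))
}

# All ordered selections of `r` distinct values from 1..n, one per row.
perm_rows <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perm_rows(n, r - 1)
    sub <- sub[apply(sub != i, 1, all), , drop = FALSE]
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}
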