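# Kolmogorov distance between normalized cumulative profiles, the
# all-pairs distance matrix, k-medoids (PAM, deterministic BUILD + SWAP)
# and semantic labeling of the three clusters by where their mean profile
# puts its signal mass.

#' Kolmogorov distance between two cumulative profiles
#'
#' The maximum absolute difference between two cumulative distributions —
#' the Kolmogorov-Smirnov statistic evaluated on the shared bin grid. For
#' normalized profiles it lies in \[0, 1\] and measures how differently
#' the two underlying signals are shaped, regardless of amplitude.
#'
#' @param a,b numeric vectors of equal length (cumulative profiles).
#' @return the distance, `max(abs(a - b))`.
#' @export
kolmogorov_distance <- function(a, b) {
  if (length(a) != length(b))
    abort("kolmogorov_distance: profiles have %d vs %d bins",
          length(a), length(b))
  max(abs(a - b))
}

#' All-pairs Kolmogorov distance matrix
#'
#' @param profiles a `cumulative_profiles` matrix (rows = promoters,
#'   rownames = unique ids) from [cumulative_normalize()].
#' @return symmetric `dist_matrix` with zero diagonal, dimnames = ids.
#' @export
build_distance_matrix <- function(profiles) {
  n <- nrow(profiles)
  if (n < 2L) abort("build_distance_matrix: need at least 2 profiles")
  ids <- rownames(profiles)
  if (is.null(ids) || anyDuplicated(ids))
    abort("build_distance_matrix: profiles need unique rownames")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(ncol(profiles))) {
    cj <- profiles[, j]
    d <- pmax(d, abs(outer(cj, cj, `-`)))
  }
  structure(d, class = c("dist_matrix", "matrix", "array"))
}

#' k-medoids clustering (PAM: BUILD + SWAP) on a distance matrix
#'
#' Deterministic partitioning around medoids. BUILD seeds greedily: the
#' first medoid minimizes total distance to all points; each subsequent
#' medoid maximizes the total decrease in nearest-medoid distance. SWAP
#' then repeatedly applies the best strictly-improving exchange of a
#' medoid with a non-medoid until no exchange lowers the objective (total
#' distance of every point to its nearest medoid). All ties break toward
#' the lowest point index, so the result is reproducible without
#' randomness.
#'
#' @param dm a square symmetric distance matrix (a `dist_matrix` or plain
#'   matrix) with dimnames.
#' @param k number of clusters (default 3).
#' @return a `cluster_result`: list with `k`, `medoid_ids`, `assignment`
#'   (named integer vector, id -> cluster index; clusters numbered by
#'   ascending medoid index), `objective`, and `labels = NULL` until
#'   [label_clusters()] is applied.
#' @export
k_medoids <- function(dm, k = 3) {
  dm <- unclass(dm)
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- as.character(seq_len(n))
  if (k > n) abort("k_medoids: k = %d exceeds n = %d", k, n)
  if (k < 1L) abort("k_medoids: k must be >= 1")
  # BUILD
  medoids <- integer(0)
  nearest <- rep(Inf, n)
  for (step in seq_len(k)) {
    if (step == 1L) {
      tot <- colSums(dm)
      cand <- which(tot == min(tot))[1]
    } else {
      gain <- vapply(seq_len(n), function(c) {
        if (c %in% medoids) return(-Inf)
        sum(pmax(0, nearest - dm[, c]))
      }, numeric(1))
      cand <- which(gain == max(gain))[1]
    }
    medoids <- c(medoids, cand)
    nearest <- pmin(nearest, dm[, cand])
  }
  medoids <- sort(medoids)
  objective <- function(med) sum(do.call(pmin, asplit(dm[, med, drop = FALSE], 2L)))
  obj <- objective(medoids)
  # SWAP: best strictly-improving exchange, repeat to convergence.
  # Iteration order (ascending medoid, then ascending candidate) plus the
  # strict comparison makes tie handling deterministic.
  repeat {
    best_obj <- obj
    best_med <- NULL
    for (m in medoids) {
      for (h in setdiff(seq_len(n), medoids)) {
        med2 <- sort(c(setdiff(medoids, m), h))
        o2 <- objective(med2)
        if (o2 < best_obj - 1e-12) {
          best_obj <- o2
          best_med <- med2
        }
      }
    }
    if (is.null(best_med)) break
    medoids <- best_med
    obj <- best_obj
  }
  assignment <- apply(dm[, medoids, drop = FALSE], 1L, which.min)
  names(assignment) <- rownames(dm)
  structure(list(k = k, medoid_ids = rownames(dm)[medoids],
                 assignment = assignment, objective = obj, labels = NULL),
            class = "cluster_result")
}

#' Label three clusters upstream / centered / downstream
#'
#' Computes each cluster's mean strand-oriented binned profile and its
#' center of mass over bin indices, `c = sum(i * s_i) / sum(s_i)`.
#' Clusters ranked by center of mass get the labels upstream (smallest c:
#' signal mass 5' of the TSS), centered, downstream (largest c). Ties in
#' the center of mass are broken toward the lower cluster index and
#' flagged in the returned object (`label_ties`).
#'
#' @param result a `cluster_result` with `k = 3`.
#' @param profiles the `binned_profiles` matrix the clustering was built
#'   from (row ids must cover the assignment).
#' @return the `cluster_result` with `labels` (cluster index -> label) and
#'   a `labelled_assignment` (id -> label) filled in.
#' @export
label_clusters <- function(result, profiles) {
  if (result$k != 3L) {
    result$labels <- NULL
    return(result)
  }
  ids <- names(result$assignment)
  if (!all(ids %in% rownames(profiles)))
    abort("label_clusters: profiles missing some clustered promoters")
  com <- vapply(seq_len(result$k), function(cl) {
    rows <- profiles[ids[result$assignment == cl], , drop = FALSE]
    s <- colMeans(rows)
    if (sum(s) == 0) return((ncol(profiles) + 1) / 2)
    sum(seq_along(s) * s) / sum(s)
  }, numeric(1))
  ord <- order(com, seq_len(result$k))    # ties -> lower cluster index first
  labels <- character(result$k)
  labels[ord] <- c("upstream", "centered", "downstream")
  result$labels <- labels
  result$label_ties <- anyDuplicated(com) > 0L
  result$labelled_assignment <- setNames(labels[result$assignment], ids)
  result
}

#' Cross-tabulate two clusterings of the same promoters
#'
#' Builds the concordance table between, e.g., the acetylation-based and
#' the polymerase-based clusterings: cell (i, j) counts promoters with
#' label i in the first and label j in the second.
#'
#' @param a,b `cluster_result`s over the same promoter universe (labelled
#'   results use label order upstream/centered/downstream; unlabelled use
#'   cluster indices).
#' @return integer matrix of counts.
#' @export
cross_tabulate_clusterings <- function(a, b) {
  ga <- cluster_groups(a)
  gb <- cluster_groups(b)
  if (!setequal(names(ga), names(gb)))
    abort("cross_tabulate_clusterings: promoter universes differ")
  gb <- gb[names(ga)]
  lev_a <- cluster_levels(a)
  lev_b <- cluster_levels(b)
  tab <- table(factor(ga, levels = lev_a), factor(gb, levels = lev_b))
  m <- matrix(as.integer(tab), nrow = length(lev_a),
              dimnames = list(lev_a, lev_b))
  m
}

#' @noRd
cluster_groups <- function(x) {
  if (!is.null(x$labels)) x$labelled_assignment
  else setNames(as.character(x$assignment), names(x$assignment))
}

#' @noRd
cluster_levels <- function(x) {
  if (!is.null(x$labels)) c("upstream", "centered", "downstream")
  else as.character(seq_len(x$k))
}

#' Cluster sizes by label (or index)
#' @param x a `cluster_result`.
#' @return named integer vector of cluster sizes.
#' @export
cluster_sizes <- function(x) {
  g <- cluster_groups(x)
  tab <- table(factor(g, levels = cluster_levels(x)))
  setNames(as.integer(tab), names(tab))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, objective = %.4f\n", x$k, x$objective))
  print(cluster_sizes(x))
  invisible(x)
}
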