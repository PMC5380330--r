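# Agglomerative average-linkage (UPGMA) ordering of DEM expression
# profiles on correlation distance, as used for heatmap row ordering.
# Implemented directly (O(n^3)) so the tie-break is fully deterministic:
# among equally close pairs the pair whose member probe ids sort first
# lexicographically is merged, and on merging the lexicographically
# smaller branch is placed on the left.

#' Correlation distance between probe profiles
#'
#' `1 - Pearson correlation` across samples.  Probes with zero variance
#' have undefined correlation; their distance to every other probe is
#' defined as 1 (no evidence of co-expression), and 0 to themselves.
#'
#' @param log2_values probe x sample matrix (probes are profiled rows).
#' @return symmetric distance matrix.
#' @export
correlation_distance <- function(log2_values) {
  m <- as.matrix(log2_values)
  d <- 1 - suppressWarnings(cor(t(m)))
  d[is.na(d)] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Hierarchical ordering of expression profiles
#'
#' Average-linkage agglomerative clustering on the correlation distance
#' of probe profiles, with a deterministic lexicographic tie-break, as
#' used to order heatmap rows of differentially expressed miRNAs.
#'
#' @param log2_values probe x sample matrix with >= 2 rows and rownames.
#' @param distance optional precomputed symmetric distance matrix; by
#'   default [correlation_distance()] of `log2_values`.
#' @return an object of class `hclust` (fields `merge`, `height`,
#'   `order`, `labels`); `labels[order]` is the leaf order.
#' @export
hierarchical_order <- function(log2_values, distance = NULL) {
  m <- as.matrix(log2_values)
  n <- nrow(m)
  if (n < 2) contract_error("hierarchical ordering needs >= 2 probes")
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("probe_%d", seq_len(n))
  d <- if (is.null(distance)) correlation_distance(m) else as.matrix(distance)
  stopifnot(identical(dim(d), c(n, n)))

  # active cluster state
  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust merge codes
  key <- labels                  # lexicographically smallest member id
  ord <- as.list(seq_len(n))     # leaf order within each cluster
  active <- rep(TRUE, n)
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL; bestd <- Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        if (dij < bestd - 1e-12) {
          bestd <- dij; best <- c(i, j)
        } else if (abs(dij - bestd) <= 1e-12) {
          # tie: prefer the pair whose sorted key pair sorts first
          cand <- sort(c(key[i], key[j]))
          cur <- sort(c(key[best[1]], key[best[2]]))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
            best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    # left branch = lexicographically smaller key
    lr <- if (key[i] <= key[j]) c(i, j) else c(j, i)
    merge[step, ] <- c(code[lr[1]], code[lr[2]])
    height[step] <- max(bestd, 0)
    # UPGMA update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    ord[[i]] <- c(ord[[lr[1]]], ord[[lr[2]]])
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    code[i] <- step
    active[j] <- FALSE
  }

  structure(list(merge = merge, height = height,
                 order = ord[[which(active)]], labels = labels,
                 method = "average", dist.method = "1 - pearson",
                 call = match.call()),
            class = "hclust")
}
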