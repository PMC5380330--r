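# Genomic clustering of miRNA loci: single-linkage grouping of features
# on one chromosome whose inter-locus gap is at most a threshold
# (5000 bp by default), as used to detect co-transcribed miRNA clusters
# among co-downregulated miRNAs.

#' Normalize printed coordinates to an oriented interval
#'
#' Coordinate tables of miRNA loci print minus-strand rows with
#' start > end.  This maps any (start, end) pair to `low = min`,
#' `high = max` with strand `-` iff start > end, `+` iff start < end,
#' and `unknown` for a 1 bp locus (start == end).
#'
#' @param start,end positive integer vectors (1-based inclusive).
#' @return data.frame with columns `low`, `high`, `strand`.
#' @export
#' @examples
#' normalize_coordinates(207975861, 207975841)  # minus strand
normalize_coordinates <- function(start, end) {
  if (any(start <= 0) || any(end <= 0))
    input_error("coordinates must be positive")
  data.frame(low = pmin(start, end),
             high = pmax(start, end),
             strand = ifelse(start > end, "-",
                             ifelse(start < end, "+", "unknown")),
             stringsAsFactors = FALSE)
}

#' Distance between two genomic features
#'
#' `Inf` for features on different chromosomes; 0 for overlapping or
#' touching intervals; otherwise the gap `(later low) - (earlier high)`
#' in bp.
#'
#' @param f1,f2 single-row data.frames (or lists) with `chromosome`,
#'   `low`, `high`.
#' @return non-negative numeric distance in bp, possibly `Inf`.
#' @export
interval_distance <- function(f1, f2) {
  if (tolower(sub("^chr", "", tolower(f1$chromosome))) !=
      tolower(sub("^chr", "", tolower(f2$chromosome)))) return(Inf)
  gap <- max(f1$low, f2$low) - min(f1$high, f2$high)
  max(gap, 0)
}

#' Detect genomic miRNA clusters
#'
#' Single-linkage transitive closure of the relation
#' `interval_distance <= max_gap` (inclusive: a gap of exactly 5000 bp
#' clusters, reading "no longer than 5000 bp" as <=).  Groups smaller
#' than `min_size` are discarded — published cluster tables report only
#' multi-member clusters.  Clusters are ordered by chromosome (autosomes
#' numerically, then X, Y) and lowest coordinate, and labelled C1..Cn.
#' The output is invariant under any permutation of the input rows.
#' Exact duplicate (name, coordinate) records are dropped with a
#' message.
#'
#' @param features data.frame of normalized features (columns `name`,
#'   `chromosome`, `low`, `high`; e.g. from [read_coordinates()]).
#' @param max_gap inclusive gap threshold in bp (default 5000).
#' @param min_size minimum cluster size to report (default 2).
#' @return data.frame with one row per reported member: `cluster_id`,
#'   `name`, `chromosome`, `low`, `high`, plus per-cluster attributes in
#'   the `summary` attribute (cluster_id, chromosome, span_low,
#'   span_high, n_members, max_internal_gap).
#' @export
cluster_features <- function(features, max_gap = 5000, min_size = 2) {
  stopifnot(max_gap >= 0, min_size >= 1)
  f <- as.data.frame(features)
  if (!nrow(f)) {
    out <- f[, intersect(c("name", "chromosome", "low", "high"), names(f)),
             drop = FALSE]
    out$cluster_id <- character(0)
    attr(out, "summary") <- data.frame()
    return(out)
  }
  stopifnot(all(c("name", "chromosome", "low", "high") %in% names(f)),
            all(f$low <= f$high))
  dup <- duplicated(f[, c("name", "chromosome", "low", "high")])
  if (any(dup)) {
    message(sum(dup), " duplicate feature record(s) removed")
    f <- f[!dup, , drop = FALSE]
  }
  # canonical order: chromosome rank, then low coordinate, then name
  f <- f[order(chrom_rank(f$chromosome), f$low, f$high, f$name), ,
         drop = FALSE]
  rownames(f) <- NULL

  # sweep per chromosome: maintain running max high; a new feature joins
  # the open group iff its low is within max_gap of that max (this
  # equals the single-linkage closure of pairwise interval distances)
  grp <- integer(nrow(f))
  gid <- 0L
  last_chrom <- ""
  run_high <- -Inf
  for (i in seq_len(nrow(f))) {
    ck <- chrom_rank(f$chromosome[i])
    if (i == 1 || ck != last_chrom ||
        (f$low[i] - run_high) > max_gap) {
      gid <- gid + 1L
      run_high <- f$high[i]
    } else {
      run_high <- max(run_high, f$high[i])
    }
    grp[i] <- gid
    last_chrom <- ck
  }
  keep_gid <- as.integer(names(which(table(grp) >= min_size)))
  keep <- grp %in% keep_gid
  f <- f[keep, , drop = FALSE]
  grp <- grp[keep]
  if (!nrow(f)) {
    f$cluster_id <- character(0)
    attr(f, "summary") <- data.frame()
    return(f)
  }
  # relabel in encounter order (input already canonically sorted)
  relab <- match(grp, unique(grp))
  f$cluster_id <- sprintf("C%d", relab)
  summ <- do.call(rbind, lapply(split(f, relab), function(g) {
    gaps <- if (nrow(g) > 1)
      vapply(seq_len(nrow(g) - 1), function(k)
        max(g$low[k + 1] - max(g$high[seq_len(k)]), 0), numeric(1))
    else 0
    data.frame(cluster_id = g$cluster_id[1],
               chromosome = g$chromosome[1],
               span_low = min(g$low), span_high = max(g$high),
               n_members = nrow(g),
               max_internal_gap = max(gaps),
               members = paste(g$name, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  rownames(f) <- NULL
  attr(f, "summary") <- summ
  f
}
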