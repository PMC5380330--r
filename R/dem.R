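# Differential expression screening for one group-vs-group contrast:
# detection-flag consistency, pooled-variance (Student) t test on log2
# values, fold change on linear values, and the combined DEM call
# (FC > 2 or FC < 0.5, P < 0.05, consistent flags).  Also the
# cross-contrast set comparison with truncated two-decimal percentages.

group_columns <- function(dataset, group) {
  idx <- which(dataset$groups == group)
  if (!length(idx))
    contract_error(sprintf("group '%s' absent from dataset", group))
  if (length(idx) < 2)
    contract_error(sprintf("group '%s' has < 2 replicates", group))
  idx
}

#' Detection-flag consistency filter
#'
#' A probe passes for a contrast iff, within each of the two compared
#' groups, all replicate flags are identical, and at least one group's
#' common flag is Present.  Probes Absent in every replicate of both
#' groups are treated as unmeasured and fail the filter.
#'
#' @param dataset an [expression_dataset()].
#' @param contrast character vector `c(test, reference)` of group labels.
#' @return named logical vector over probes.
#' @export
flag_consistency_filter <- function(dataset, contrast) {
  stopifnot(inherits(dataset, "ExpressionDataset"), length(contrast) == 2)
  ia <- group_columns(dataset, contrast[1])
  ib <- group_columns(dataset, contrast[2])
  fl <- dataset$flags == "Present"
  consistent <- function(idx) {
    s <- rowSums(fl[, idx, drop = FALSE])
    s == 0 | s == length(idx)
  }
  any_present <- rowSums(fl[, c(ia, ib), drop = FALSE]) > 0
  out <- consistent(ia) & consistent(ib) & any_present
  names(out) <- dataset$probe_ids
  out
}

#' Row-wise two-sample Student t test
#'
#' Unpaired pooled-variance (equal-variance) t test per probe on log2
#' values, two-sided p from the t distribution with `nA + nB - 2`
#' degrees of freedom.  The t statistic is oriented test minus
#' reference.  Degenerate probes (zero pooled variance) get `t = 0,
#' p = 1` when the group means are equal, and `p = 0` with a degenerate
#' flag when they differ.
#'
#' @param log2_values numeric probe x sample matrix.
#' @param idx_test,idx_ref column indices of the two groups (each >= 2).
#' @return data.frame with columns `t_stat`, `p_value`, `degenerate`.
#' @export
student_t_test <- function(log2_values, idx_test, idx_ref) {
  if (length(idx_test) < 2 || length(idx_ref) < 2)
    contract_error("t test needs >= 2 replicates per group")
  a <- log2_values[, idx_test, drop = FALSE]
  b <- log2_values[, idx_ref, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(tt), df)
  degen <- se == 0
  eq <- degen & (ma == mb)
  ne <- degen & (ma != mb)
  tt[eq] <- 0; p[eq] <- 1
  tt[ne] <- sign(ma - mb)[ne] * Inf; p[ne] <- 0
  data.frame(t_stat = tt, p_value = p, degenerate = ne,
             row.names = rownames(log2_values))
}

#' Row-wise fold change (ratio of group means, linear scale)
#'
#' `fc = mean(test) / mean(reference)` computed on linear normalized
#' intensities.  Probes whose reference mean is zero get `NA` and are
#' excluded from DEM calling with a message.
#'
#' @param linear_values numeric probe x sample matrix (linear scale).
#' @param idx_test,idx_ref column indices of the two groups.
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(linear_values, idx_test, idx_ref) {
  mt <- rowMeans(linear_values[, idx_test, drop = FALSE])
  mr <- rowMeans(linear_values[, idx_ref, drop = FALSE])
  fc <- mt / mr
  bad <- mr == 0
  if (any(bad)) {
    message(sum(bad), " probe(s) with zero reference mean excluded from FC")
    fc[bad] <- NA_real_
  }
  names(fc) <- rownames(linear_values)
  fc
}

#' Call differentially expressed miRNAs
#'
#' Applies the screening rule to a contrast result: `up` iff
#' `fc > fc_up` and `p < alpha` and flags consistent; `down` iff
#' `fc < fc_down` and `p < alpha` and flags consistent; otherwise
#' `none`.  All inequalities are strict (fold change "more than 2.0"
#' excludes exactly 2.0).  Probes with undefined FC are `none`.
#'
#' @param result a `ContrastResult` from [run_contrast()] or a
#'   data.frame with columns `fc_linear`, `p_value`, `flag_ok`.
#' @param alpha p-value cutoff (default 0.05).
#' @param fc_up,fc_down linear fold-change thresholds (default 2.0 and
#'   0.5).
#' @return the input with a `call` column (factor up/down/none).
#' @export
call_dems <- function(result, alpha = 0.05, fc_up = 2.0, fc_down = 0.5) {
  tab <- as.data.frame(result)
  ok <- tab$flag_ok & !is.na(tab$fc_linear) & tab$p_value < alpha
  call <- rep("none", nrow(tab))
  call[ok & tab$fc_linear > fc_up] <- "up"
  call[ok & tab$fc_linear < fc_down] <- "down"
  result$call <- factor(call, levels = c("up", "down", "none"))
  result
}

#' Run one differential expression contrast
#'
#' Computes, per probe: linear fold change (test over reference group
#' means on the linear normalized scale), pooled-variance t test on log2
#' values, flag consistency, and the DEM call.
#'
#' @param dataset an [expression_dataset()] holding **normalized linear**
#'   intensities.
#' @param contrast `c(test, reference)` group labels.
#' @param alpha,fc_up,fc_down thresholds passed to [call_dems()].
#' @param log2_offset offset for [log2_transform()].
#' @return a `ContrastResult`: data.frame with columns `probe`,
#'   `fc_linear`, `log2fc`, `t_stat`, `p_value`, `degenerate`,
#'   `flag_ok`, `call`; attribute `contrast`.
#' @export
run_contrast <- function(dataset, contrast, alpha = 0.05, fc_up = 2.0,
                         fc_down = 0.5, log2_offset = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"), length(contrast) == 2)
  it <- group_columns(dataset, contrast[1])
  ir <- group_columns(dataset, contrast[2])
  lin <- dataset$intensities
  lg <- log2_transform(lin, offset = log2_offset)
  fc <- fold_change(lin, it, ir)
  tt <- student_t_test(lg, it, ir)
  flag_ok <- flag_consistency_filter(dataset, contrast)
  res <- data.frame(probe = dataset$probe_ids,
                    fc_linear = unname(fc),
                    log2fc = log2(unname(fc)),
                    t_stat = tt$t_stat,
                    p_value = tt$p_value,
                    degenerate = tt$degenerate,
                    flag_ok = unname(flag_ok),
                    stringsAsFactors = FALSE)
  res <- call_dems(res, alpha = alpha, fc_up = fc_up, fc_down = fc_down)
  attr(res, "contrast") <- contrast
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Extract DEM probe ids from a contrast result
#' @param result a `ContrastResult`.
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return character vector of probe ids.
#' @export
dem_probes <- function(result, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") result$call != "none"
          else result$call == direction
  result$probe[keep]
}

#' Compare DEM sets of two contrasts
#'
#' Intersects and differences the up- and down-regulated probe sets of
#' two contrasts over the same probe universe, and expresses the shared
#' counts as percentages of each contrast's totals, truncated (floored)
#' to two decimals — 130 shared of 150 and 140 upregulated prints as
#' 86.66 and 92.85.
#'
#' @param result_a,result_b `ContrastResult` objects over the same probe
#'   universe.
#' @return a `ContrastComparison`: list with probe-id sets `shared_up`,
#'   `shared_down`, `specific_up_a`, `specific_up_b`, `specific_down_a`,
#'   `specific_down_b`, and a `percentages` data.frame (direction,
#'   shared, total_a, total_b, pct_a, pct_b).
#' @export
compare_contrasts <- function(result_a, result_b) {
  if (!setequal(result_a$probe, result_b$probe))
    contract_error("contrasts must share one probe universe")
  up_a <- dem_probes(result_a, "up");   up_b <- dem_probes(result_b, "up")
  dn_a <- dem_probes(result_a, "down"); dn_b <- dem_probes(result_b, "down")
  shared_up <- sort(intersect(up_a, up_b))
  shared_dn <- sort(intersect(dn_a, dn_b))
  pct <- function(k, n) if (n > 0) truncated_percent(k, n) else 0
  percentages <- data.frame(
    direction = c("up", "down"),
    shared = c(length(shared_up), length(shared_dn)),
    total_a = c(length(up_a), length(dn_a)),
    total_b = c(length(up_b), length(dn_b)),
    pct_a = c(pct(length(shared_up), length(up_a)),
              pct(length(shared_dn), length(dn_a))),
    pct_b = c(pct(length(shared_up), length(up_b)),
              pct(length(shared_dn), length(dn_b))),
    stringsAsFactors = FALSE)
  structure(list(shared_up = shared_up,
                 shared_down = shared_dn,
                 specific_up_a = sort(setdiff(up_a, up_b)),
                 specific_up_b = sort(setdiff(up_b, up_a)),
                 specific_down_a = sort(setdiff(dn_a, dn_b)),
                 specific_down_b = sort(setdiff(dn_b, dn_a)),
                 percentages = percentages),
            class = "ContrastComparison")
}

#' @export
print.ContrastComparison <- function(x, ...) {
  cat("ContrastComparison\n")
  print(x$percentages)
  invisible(x)
}
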