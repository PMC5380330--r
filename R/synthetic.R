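# Synthetic-data generators.  Each generator states the statistical
# world the analysis assumes -- a 2,006-probe miRNA array measured over
# 3 conditions x 3 replicates with planted differential expression and
# detection-flag dropout; chromosome geometries with planted clusters;
# a target database with planted gene-set enrichment -- and returns a
# first-class truth table so recovery is scored against the plan, never
# re-derived from the data.  All generators are seed-deterministic.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic expression dataset
#'
#' Defaults state the emulated world: 2,006 probes (the human miRNA
#' array used), three groups (PBMC, CIK_IL2, CIK_IL15) of 3 replicates,
#' 5% planted up- and 5% planted down-regulated probes per CIK-vs-PBMC
#' contrast with 90% of planted DEMs shared between the two CIK
#' contrasts (matching the >90% observed co-regulation), a mean planted
#' |log2 FC| of 2, replicate noise SD 0.25 on the log2 scale, and a 5%
#' chance that a bottom-decile measurement loses its detection flag.
#'
#' @param n_probes number of probes (>= 1).
#' @param groups named integer vector of replicate counts per group; the
#'   first group is the reference (PBMC).
#' @param de_fraction_up,de_fraction_down planted DEM fractions per
#'   contrast, in `[0, 1]`.
#' @param effect_log2 planted |log2 fold change|.
#' @param noise_sd_log2 replicate noise SD (log2 scale).
#' @param baseline_mean_log2,baseline_sd_log2 probe baseline
#'   distribution (log2 scale).
#' @param flag_dropout probability that a low-intensity measurement is
#'   flagged Absent.
#' @param low_quantile measurements below this quantile of all values
#'   are dropout-eligible (default bottom decile).
#' @param shared_fraction fraction of planted DEMs common to all test
#'   groups.
#' @param seed integer RNG seed.
#' @return a `DESpec` list.
#' @export
de_spec <- function(n_probes = 2006,
                    groups = c(PBMC = 3, CIK_IL2 = 3, CIK_IL15 = 3),
                    de_fraction_up = 0.05, de_fraction_down = 0.05,
                    effect_log2 = 2, noise_sd_log2 = 0.25,
                    baseline_mean_log2 = 8, baseline_sd_log2 = 2,
                    flag_dropout = 0.05, low_quantile = 0.1,
                    shared_fraction = 0.9, seed = 1) {
  spec <- list(n_probes = n_probes, groups = groups,
               de_fraction_up = de_fraction_up,
               de_fraction_down = de_fraction_down,
               effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
               baseline_mean_log2 = baseline_mean_log2,
               baseline_sd_log2 = baseline_sd_log2,
               flag_dropout = flag_dropout, low_quantile = low_quantile,
               shared_fraction = shared_fraction, seed = seed)
  frac <- c(de_fraction_up, de_fraction_down, shared_fraction,
            flag_dropout, low_quantile)
  if (any(frac < 0 | frac > 1))
    contract_error("fractions and probabilities must lie in [0, 1]")
  if (n_probes < 1) contract_error("n_probes must be >= 1")
  if (is.null(names(groups)) || length(groups) < 2)
    contract_error("groups must be a named vector with >= 2 groups")
  if (any(groups < 2)) contract_error("every group needs >= 2 replicates")
  class(spec) <- "DESpec"
  spec
}

#' Generate a synthetic expression dataset with planted DEMs
#'
#' Probe baselines are drawn on the log2 scale from
#' N(`baseline_mean_log2`, `baseline_sd_log2`); planted DEMs shift the
#' test-group mean by +/- `effect_log2`; replicates add
#' N(0, `noise_sd_log2`); intensities are exported on the linear scale
#' (`2^log2`).  Per contrast (each non-reference group vs the first
#' group), `de_fraction_up` and `de_fraction_down` of probes are planted
#' up / down, with `shared_fraction` of each planted set common to all
#' test groups.  Detection flags are Absent with probability
#' `flag_dropout` for measurements below the `low_quantile` quantile of
#' all values.  Identical seeds give identical output.
#'
#' @param spec a [de_spec()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`,
#'   a data.frame (`probe`, `contrast` = test group, `status` in
#'   up/down/none) covering every probe x test-group pair.
#' @export
generate_expression_dataset <- function(spec = de_spec()) {
  stopifnot(inherits(spec, "DESpec"))
  with_seed(spec$seed, {
    np <- spec$n_probes
    probes <- sprintf("mir_probe_%04d", seq_len(np))
    gnames <- names(spec$groups)
    ref <- gnames[1]
    tests <- gnames[-1]
    n_up <- round(spec$de_fraction_up * np)
    n_dn <- round(spec$de_fraction_down * np)
    n_shared_up <- round(spec$shared_fraction * n_up)
    n_shared_dn <- round(spec$shared_fraction * n_dn)

    # disjoint pools: shared up, shared down, then per-test-group
    # specific sets
    need <- n_shared_up + n_shared_dn +
      length(tests) * ((n_up - n_shared_up) + (n_dn - n_shared_dn))
    if (need > np)
      contract_error("DE fractions too large for n_probes")
    pool <- sample(probes, need)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    shared_up <- take(n_shared_up)
    shared_dn <- take(n_shared_dn)
    up_sets <- list(); dn_sets <- list()
    for (g in tests) {
      up_sets[[g]] <- c(shared_up, take(n_up - n_shared_up))
      dn_sets[[g]] <- c(shared_dn, take(n_dn - n_shared_dn))
    }

    base <- rnorm(np, spec$baseline_mean_log2, spec$baseline_sd_log2)
    names(base) <- probes
    cols <- list(); samples <- character(0); groups <- character(0)
    for (g in gnames) {
      shift <- numeric(np); names(shift) <- probes
      if (g != ref) {
        shift[up_sets[[g]]] <- spec$effect_log2
        shift[dn_sets[[g]]] <- -spec$effect_log2
      }
      for (r in seq_len(spec$groups[[g]])) {
        sid <- sprintf("%s_r%d", g, r)
        cols[[sid]] <- base + shift + rnorm(np, 0, spec$noise_sd_log2)
        samples <- c(samples, sid)
        groups <- c(groups, g)
      }
    }
    lg <- do.call(cbind, cols)
    rownames(lg) <- probes
    lin <- 2^lg
    thr <- stats::quantile(lg, spec$low_quantile)
    dropout <- matrix(runif(length(lg)) < spec$flag_dropout & lg < thr,
                      nrow(lg), ncol(lg))
    flags <- matrix(ifelse(dropout, "Absent", "Present"),
                    nrow(lg), ncol(lg), dimnames = dimnames(lg))
    ds <- expression_dataset(lin, flags, setNames(groups, samples))
    truth <- do.call(rbind, lapply(tests, function(g) {
      status <- rep("none", np)
      names(status) <- probes
      status[up_sets[[g]]] <- "up"
      status[dn_sets[[g]]] <- "down"
      data.frame(probe = probes, contrast = g, status = unname(status),
                 stringsAsFactors = FALSE)
    }))
    list(dataset = ds, truth = truth)
  })
}

#' Specification of a synthetic chromosome geometry
#'
#' @param n_clusters number of planted clusters.
#' @param sizes integer vector (recycled) of members per cluster, all
#'   >= 2.
#' @param intra_gap_bp maximum planted gap between consecutive cluster
#'   members (should be below the detection threshold).
#' @param n_singletons isolated features planted far from everything.
#' @param min_inter_cluster_gap_bp minimum separation between planted
#'   entities (must exceed `intra_gap_bp`).
#' @param chromosomes chromosome label pool.
#' @param feature_bp mature miRNA locus length range in bp.
#' @param seed integer RNG seed.
#' @return a `ClusterSpec` list.
#' @export
cluster_spec <- function(n_clusters = 5, sizes = 2, intra_gap_bp = 3000,
                         n_singletons = 10,
                         min_inter_cluster_gap_bp = 1e6,
                         chromosomes = paste0("Chr", c(1:22, "X")),
                         feature_bp = c(18, 23), seed = 1) {
  if (intra_gap_bp >= min_inter_cluster_gap_bp)
    contract_error("intra_gap_bp must be < min_inter_cluster_gap_bp")
  sizes <- rep_len(as.integer(sizes), max(n_clusters, 1))
  if (n_clusters > 0 && any(sizes < 2))
    contract_error("cluster sizes must be >= 2")
  structure(list(n_clusters = n_clusters, sizes = sizes,
                 intra_gap_bp = intra_gap_bp, n_singletons = n_singletons,
                 min_inter_cluster_gap_bp = min_inter_cluster_gap_bp,
                 chromosomes = chromosomes, feature_bp = feature_bp,
                 seed = seed),
            class = "ClusterSpec")
}

#' Generate synthetic miRNA genomic annotation with planted clusters
#'
#' Plants exactly `n_clusters` groups whose consecutive-member gaps are
#' at most `intra_gap_bp`, plus `n_singletons` isolated features at
#' least `min_inter_cluster_gap_bp` away from everything else on the
#' same chromosome.  Roughly half of the rows are emitted in the
#' minus-strand dialect (start > end) to exercise coordinate
#' normalization.
#'
#' @param spec a [cluster_spec()].
#' @return data.frame with raw `start`/`end` columns (the printable
#'   dialect), normalized `low`/`high`/`strand`, `name`, `accession`,
#'   `chromosome`, and a `truth_cluster` column (planted cluster label
#'   or `NA` for singletons).
#' @export
generate_annotation <- function(spec = cluster_spec()) {
  stopifnot(inherits(spec, "ClusterSpec"))
  with_seed(spec$seed, {
    entities <- c(if (spec$n_clusters > 0)
                    sprintf("cluster_%02d", seq_len(spec$n_clusters)),
                  if (spec$n_singletons > 0)
                    sprintf("singleton_%02d", seq_len(spec$n_singletons)))
    if (!length(entities))
      return(data.frame(name = character(0), accession = character(0),
                        chromosome = character(0), start = numeric(0),
                        end = numeric(0), low = numeric(0),
                        high = numeric(0), strand = character(0),
                        truth_cluster = character(0)))
    chrom <- sample(spec$chromosomes, length(entities), replace = TRUE)
    cursor <- setNames(rep(1e6, length(spec$chromosomes)),
                       spec$chromosomes)
    rows <- list()
    k <- 0
    for (e in seq_along(entities)) {
      ch <- chrom[e]
      pos <- cursor[[ch]] +
        spec$min_inter_cluster_gap_bp + sample.int(1e5, 1)
      n_mem <- if (startsWith(entities[e], "cluster"))
        spec$sizes[as.integer(sub("cluster_", "", entities[e]))] else 1L
      for (m in seq_len(n_mem)) {
        len <- sample(seq(spec$feature_bp[1], spec$feature_bp[2]), 1)
        lo <- pos; hi <- pos + len - 1
        k <- k + 1
        minus <- runif(1) < 0.5
        rows[[k]] <- data.frame(
          name = sprintf("syn-mir-%03d", k),
          accession = sprintf("SYNMAT%07d", k),
          chromosome = ch,
          start = if (minus) hi else lo,
          end = if (minus) lo else hi,
          low = lo, high = hi,
          strand = if (minus) "-" else "+",
          truth_cluster = if (n_mem > 1) entities[e] else NA_character_,
          stringsAsFactors = FALSE)
        # next member within the planted gap
        pos <- hi + if (n_mem > 1) sample.int(spec$intra_gap_bp, 1) else 0
      }
      cursor[[ch]] <- max(cursor[[ch]], rows[[k]]$high)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic miRNA-target database with planted enrichment
#'
#' Builds `n_genes` genes, `n_sets` gene sets, and a target table wiring
#' each miRNA to `edges_per_mirna` genes sampled without replacement.
#' A designated miRNA subset (`selected_mirnas`) samples genes belonging
#' to designated "enriched" sets with probability weight `multiplier`
#' (weight 1 elsewhere); `multiplier = 1` is the null.  The truth lists
#' which terms are planted enriched for the selected subset.
#'
#' @param mirnas character vector of miRNA ids (may be empty).
#' @param n_genes size of the gene universe.
#' @param n_sets number of gene sets.
#' @param set_size length-2 integer range of set sizes.
#' @param n_enriched number of planted enriched sets.
#' @param selected_mirnas subset of `mirnas` wired preferentially;
#'   defaults to the first half.
#' @param multiplier sampling odds multiplier for enriched-set genes
#'   (>= 1; 1 = null).
#' @param edges_per_mirna targets sampled per miRNA.
#' @param seed integer RNG seed.
#' @return list with `mti` (an `MTITable`), `collection`
#'   (a `GeneSetCollection`), `genes` (the full gene universe), and
#'   `truth` (list: `selected_mirnas`, `enriched_terms`).
#' @export
generate_target_db <- function(mirnas, n_genes = 4000, n_sets = 50,
                               set_size = c(150, 250), n_enriched = 3,
                               selected_mirnas = NULL, multiplier = 1,
                               edges_per_mirna = 40, seed = 1) {
  stopifnot(multiplier >= 1, n_genes >= max(set_size),
            edges_per_mirna <= n_genes)
  with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    sets <- lapply(seq_len(n_sets), function(i)
      sample(genes, sample(seq(set_size[1], set_size[2]), 1)))
    names(sets) <- sprintf("TERM%04d", seq_len(n_sets))
    n_enriched <- min(n_enriched, n_sets)
    enriched_terms <- names(sets)[seq_len(n_enriched)]
    if (is.null(selected_mirnas) && length(mirnas))
      selected_mirnas <- mirnas[seq_len(ceiling(length(mirnas) / 2))]
    enriched_genes <- unique(unlist(sets[enriched_terms],
                                    use.names = FALSE))
    w_enriched <- rep(1, n_genes)
    w_enriched[genes %in% enriched_genes] <- multiplier
    edges <- NULL
    if (length(mirnas)) {
      edges <- do.call(rbind, lapply(mirnas, function(m) {
        w <- if (m %in% selected_mirnas) w_enriched else rep(1, n_genes)
        data.frame(mirna = m,
                   gene = sample(genes, edges_per_mirna, prob = w),
                   stringsAsFactors = FALSE)
      }))
    }
    mti <- if (is.null(edges))
      mti_table(character(0), character(0))
    else mti_table(edges$mirna, edges$gene, "synthetic")
    list(mti = mti,
         collection = gene_set_collection(
           sets, setNames(rep("synthetic set", n_sets), names(sets))),
         genes = genes,
         truth = list(selected_mirnas = selected_mirnas,
                      enriched_terms = enriched_terms))
  })
}

#' Score planted-DEM recovery
#'
#' Compares DEM calls of one contrast against the generator's truth
#' table: sensitivity = recovered planted DEMs (matching direction) over
#' planted DEMs; false-call rate = called probes that were not planted
#' over non-planted probes.
#'
#' @param result a `ContrastResult`.
#' @param truth the truth data.frame from
#'   [generate_expression_dataset()].
#' @param contrast_group test-group label selecting truth rows.
#' @return list with `sensitivity`, `false_call_rate`, `n_planted`,
#'   `n_called`.
#' @export
score_dem_recovery <- function(result, truth, contrast_group) {
  tr <- truth[truth$contrast == contrast_group, ]
  tr <- tr[match(result$probe, tr$probe), ]
  planted <- tr$status != "none"
  called <- as.character(result$call)
  hit <- planted & called == tr$status
  list(sensitivity = sum(hit) / sum(planted),
       false_call_rate = sum(!planted & called != "none") / sum(!planted),
       n_planted = sum(planted),
       n_called = sum(called != "none"))
}
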