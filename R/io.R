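# I/O for every external representation the pipeline touches: expression
# TSV + detection flags + group map, genomic coordinate tables (BED or
# the published start/end dialect where minus-strand rows run start >
# end), GMT gene-set collections, miRNA-target edge lists, and result
# tables.  All readers validate and all writers round-trip bit-stably.

#' Construct an expression dataset
#'
#' Bundles a probe x sample intensity matrix (linear fluorescence scale),
#' a parallel matrix of detection flags (`"Present"` / `"Absent"`), and a
#' sample -> group map.  Any flag token other than `"Present"`
#' (case-insensitive; `"P"` accepted) is collapsed to `"Absent"`,
#' following the binary detected/not-detected semantics of array feature
#' extraction.
#'
#' @param intensities numeric matrix, probes x samples, non-negative,
#'   with rownames (probe ids) and colnames (sample ids).
#' @param flags character matrix of the same shape, or `NULL` for all
#'   `"Present"`.
#' @param groups named character vector mapping every sample id to a
#'   group label.
#' @return an object of class `ExpressionDataset`: a list with elements
#'   `intensities`, `flags`, `groups`, `probe_ids`, `sample_ids`.
#' @export
expression_dataset <- function(intensities, flags = NULL, groups) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    format_error("intensity matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    format_error("duplicate probe id in expression table")
  if (anyDuplicated(colnames(intensities)))
    format_error("duplicate sample id in expression table")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    format_error("intensities must be finite and non-negative")
  if (is.null(flags)) {
    flags <- matrix("Present", nrow(intensities), ncol(intensities),
                    dimnames = dimnames(intensities))
  }
  flags <- as.matrix(flags)
  if (!identical(dim(flags), dim(intensities)))
    format_error(sprintf(
      "flag matrix shape (%d x %d) does not match intensities (%d x %d)",
      nrow(flags), ncol(flags), nrow(intensities), ncol(intensities)))
  flags <- matrix(ifelse(toupper(flags) %in% c("PRESENT", "P"),
                         "Present", "Absent"),
                  nrow(flags), ncol(flags), dimnames = dimnames(intensities))
  groups <- setNames(as.character(groups), names(groups))
  missing <- setdiff(colnames(intensities), names(groups))
  if (length(missing))
    format_error(paste("samples without a group label:",
                       paste(missing, collapse = ", ")))
  groups <- groups[colnames(intensities)]
  structure(list(intensities = intensities,
                 flags       = flags,
                 groups      = groups,
                 probe_ids   = rownames(intensities),
                 sample_ids  = colnames(intensities)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d probes x %d samples\n",
              length(x$probe_ids), length(x$sample_ids)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read an expression table with detection flags
#'
#' Reads a TSV whose first column holds probe ids and whose header row
#' holds sample ids.  Detection flags come either from a parallel file of
#' identical layout (`flags`), or from interleaved columns in the main
#' file named `<sample>_flag`.  The sample -> group map is a two-column
#' TSV (sample, group) given as `group_path`.
#'
#' @param path expression TSV.
#' @param flags optional parallel flag TSV; if `NULL`, `_flag` suffix
#'   columns in `path` are used, and if none exist all flags are Present.
#' @param group_path two-column TSV mapping sample id to group label.
#' @return an [expression_dataset()].
#' @export
read_expression_table <- function(path, flags = NULL, group_path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]
  flag_cols <- grep("_flag$", colnames(tab))
  fl <- NULL
  if (!is.null(flags)) {
    ftab <- read.delim(flags, check.names = FALSE, stringsAsFactors = FALSE)
    fprobes <- as.character(ftab[[1]])
    fl <- as.matrix(ftab[, -1, drop = FALSE])
    if (nrow(fl) != length(probe_ids) || !identical(fprobes, probe_ids))
      format_error("flag file rows do not match expression table probes")
    rownames(fl) <- probe_ids
  } else if (length(flag_cols)) {
    fl <- as.matrix(tab[, flag_cols, drop = FALSE])
    colnames(fl) <- sub("_flag$", "", colnames(fl))
    rownames(fl) <- probe_ids
    tab <- tab[, -flag_cols, drop = FALSE]
    fl <- fl[, colnames(tab), drop = FALSE]
  }
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) format_error("non-numeric intensity value")
  rownames(mat) <- probe_ids
  gtab <- read.delim(group_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(gtab) < 2) format_error("group map must have two columns")
  # tolerate an optional header line
  if (identical(tolower(gtab[1, 1]), "sample")) gtab <- gtab[-1, , drop = FALSE]
  groups <- setNames(as.character(gtab[[2]]), as.character(gtab[[1]]))
  expression_dataset(mat, fl, groups)
}

#' Write an expression dataset as TSV files
#'
#' Inverse of [read_expression_table()]: writes the intensity table, a
#' parallel flag table, and the two-column group map.  Values are written
#' with full precision (`format(..., digits = 17)`) so a write/read
#' round-trip reproduces every stored value exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param path,flag_path,group_path output TSV paths.
#' @return invisibly, the three paths.
#' @export
write_expression_table <- function(dataset, path, flag_path, group_path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  m <- dataset$intensities
  out <- data.frame(probe = rownames(m),
                    apply(m, 2, function(x) format(x, digits = 17, trim = TRUE,
                                                   scientific = FALSE)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fout <- data.frame(probe = rownames(m), dataset$flags,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write.table(fout, flag_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(dataset$groups), unname(dataset$groups)),
              group_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(path, flag_path, group_path))
}

#' Read genomic coordinates of miRNA loci
#'
#' Two dialects are supported.  `"table1"` is the published coordinate
#' table dialect: columns name, accession, chromosome, start, end;
#' 1-based inclusive; minus-strand rows are printed with start > end.
#' `"bed"` is standard BED (chrom, start, end, name, \[score, strand\]),
#' 0-based half-open, converted on read to the same internal 1-based
#' inclusive convention.  All rows are normalized via
#' [normalize_coordinates()] so `low <= high` always holds, with strand
#' inferred from coordinate order in the table1 dialect.
#'
#' @param path coordinate file.
#' @param dialect `"table1"` or `"bed"`.
#' @return a data.frame of genomic features with columns `name`,
#'   `accession`, `chromosome`, `low`, `high`, `strand`.
#' @export
read_coordinates <- function(path, dialect = c("table1", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "table1") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    need <- c("name", "accession", "chromosome", "start", "end")
    if (!all(need %in% names(tab)))
      format_error(paste("coordinate table must have columns:",
                         paste(need, collapse = ", ")))
    start <- suppressWarnings(as.numeric(tab$start))
    end <- suppressWarnings(as.numeric(tab$end))
    if (any(is.na(start)) || any(is.na(end)))
      format_error("non-numeric coordinate in table")
    nc <- normalize_coordinates(start, end)
    data.frame(name = as.character(tab$name),
               accession = as.character(tab$accession),
               chromosome = as.character(tab$chromosome),
               low = nc$low, high = nc$high, strand = nc$strand,
               stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#")
    if (ncol(tab) < 4) format_error("BED input needs chrom,start,end,name")
    start <- suppressWarnings(as.numeric(tab[[2]]))
    end <- suppressWarnings(as.numeric(tab[[3]]))
    if (any(is.na(start)) || any(is.na(end)))
      format_error("non-numeric coordinate in BED")
    if (any(start < 0) || any(end <= start))
      input_error("BED intervals must satisfy 0 <= start < end")
    strand <- if (ncol(tab) >= 6) as.character(tab[[6]]) else
      rep("unknown", nrow(tab))
    strand[!strand %in% c("+", "-")] <- "unknown"
    data.frame(name = as.character(tab[[4]]),
               accession = NA_character_,
               chromosome = as.character(tab[[1]]),
               low = start + 1, high = end, strand = strand,
               stringsAsFactors = FALSE)
  }
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `term_id`,
#' `description`, then member gene symbols.  Members are normalized with
#' [normalize_symbols()] and deduplicated.
#'
#' @param path GMT file.
#' @return a `GeneSetCollection`: list with `sets` (named list of symbol
#'   vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      format_error(sprintf("GMT set '%s' is empty", parts[1]))
    members <- unique(normalize_symbols(parts[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      format_error(sprintf("GMT set '%s' is empty", parts[1]))
    sets[[parts[1]]] <- members
    desc[parts[1]] <- parts[2]
  }
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets named list of gene symbol vectors.
#' @param descriptions optional named character of term descriptions.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)))
    format_error("gene-set collection needs named, non-empty sets")
  if (any(!lengths(sets)))
    format_error("gene-set collection contains an empty set")
  sets <- lapply(sets, function(g) unique(normalize_symbols(g)))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#' @param collection a `GeneSetCollection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns `mirna`, `gene`, and optionally `evidence`.  Gene
#' symbols are normalized with [normalize_symbols()]; duplicated
#' (miRNA, gene) pairs after normalization are collapsed to one edge
#' with a message stating how many were dropped.
#'
#' @param path TSV edge list.
#' @return data.frame with columns `mirna`, `gene`, `evidence`.
#' @export
read_mti <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("mirna", "gene") %in% names(tab)))
    format_error("MTI table must have columns mirna, gene")
  mti_table(tab$mirna, tab$gene,
            if ("evidence" %in% names(tab)) tab$evidence else NA_character_)
}

#' @rdname read_mti
#' @param mirna,gene,evidence parallel vectors defining edges.
#' @export
mti_table <- function(mirna, gene, evidence = NA_character_) {
  evidence <- rep_len(evidence, length(mirna))
  edges <- data.frame(mirna = as.character(mirna),
                      gene = normalize_symbols(gene),
                      evidence = as.character(evidence),
                      stringsAsFactors = FALSE)
  key <- paste(edges$mirna, edges$gene, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate miRNA-target edge(s) removed")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  class(edges) <- c("MTITable", "data.frame")
  edges
}

# columns formatted to 6 significant digits when writing result tables
.PVALUE_COLS <- c("p_value", "p", "p_fisher", "p_chi2", "q_bh", "q", "fdr")

#' Write result tables
#'
#' Writes each data.frame in `tables` to `<outdir>/<name>.tsv` with a
#' stable column order (as given) and fixed decimal formatting: p- and
#' q-value columns are rendered with 6 significant digits, everything
#' else with full precision.  Empty tables yield headers-only files.
#'
#' @param tables named list of data.frames.
#' @param outdir output directory, created if needed.
#' @return invisibly, the written paths.
#' @export
write_results <- function(tables, outdir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (col in intersect(names(tab), .PVALUE_COLS))
      tab[[col]] <- signif(tab[[col]], 6)
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
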