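# Small shared helpers: symbol normalization, percent truncation,
# chromosome ordering, seeded substreams.

# Protein-style synonyms that appear in curated miRNA-target tables.
.SYMBOL_ALIASES <- c(
  "FASL"      = "FASLG",
  "FAS LIGAND" = "FASLG",
  "TRAIL"     = "TNFSF10",
  "CD94"      = "KLRD1",
  "TNF-A"     = "TNF",
  "TNFA"      = "TNF",
  "CD40L"     = "CD40LG"
)

#' Normalize gene symbols
#'
#' Uppercases symbols, trims whitespace, and maps a small set of
#' protein-name synonyms (e.g. `FasL` -> `FASLG`, `Trail` -> `TNFSF10`,
#' `CD94` -> `KLRD1`, `TNF-alpha` -> `TNF`) onto HGNC gene symbols, so
#' that interaction tables and gene-set collections that mix protein and
#' gene names count the same entity once.
#'
#' @param symbols character vector of gene symbols or protein names.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbols(c("FasL", "Trail", "prf1"))
normalize_symbols <- function(symbols) {
  s <- toupper(trimws(as.character(symbols)))
  s <- sub("^TNF[-_]?(α|Α|ALPHA)$", "TNF", s)  # Greek alpha spellings
  hit <- s %in% names(.SYMBOL_ALIASES)
  s[hit] <- .SYMBOL_ALIASES[s[hit]]
  s
}

#' Percentage truncated to two decimals
#'
#' Computes `100 * num / den` truncated (floored) to two decimal places.
#' Truncation, not rounding, is used throughout the package when shared
#' DEM counts are expressed as percentages of per-contrast totals: 130
#' shared of 150 prints as 86.66, not 86.67.  The computation uses
#' integer arithmetic so boundary cases are exact.
#'
#' @param num,den non-negative integer counts; `den > 0`.
#' @return numeric percentage in `[0, 100]` with at most two decimals.
#' @export
#' @examples
#' truncated_percent(130, 150)  # 86.66
truncated_percent <- function(num, den) {
  stopifnot(length(num) == length(den), all(den > 0), all(num >= 0))
  num <- as.numeric(num)
  den <- as.numeric(den)
  # floor(10000 * num / den) / 100 without float division error
  (10000 * num - (10000 * num) %% den) / den / 100
}

# Canonical chromosome order: autosomes numerically, then X, Y, then any
# other label alphabetically.  Labels are matched case-insensitively with
# or without a "chr" prefix.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", tolower(trimws(chrom)))
  n <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(n), n,
                 ifelse(core == "x", 1000L,
                        ifelse(core == "y", 1001L, NA_integer_)))
  other <- is.na(rank)
  if (any(other)) {
    lev <- sort(unique(core[other]))
    rank[other] <- 2000L + match(core[other], lev)
  }
  rank
}

# Deterministic per-stage seed substream derived from one base seed.
# Keeps results < 2^31 so they remain valid R integer seeds.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Consistent stop() with a class so callers/tests can distinguish
# contract violations from format errors.
cik_error <- function(msg, class) {
  stop(structure(class = c(class, "cikmir_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

format_error   <- function(msg) cik_error(msg, "cikmir_format_error")
contract_error <- function(msg) cik_error(msg, "cikmir_contract_error")
input_error    <- function(msg) cik_error(msg, "cikmir_input_error")
usage_error    <- function(msg) cik_error(msg, "cikmir_usage_error")
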