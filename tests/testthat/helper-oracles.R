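# Independent oracles used by the property and acceptance tests.  These
# deliberately avoid the code paths they check: clustering is re-derived
# with all-pairs union-find, the hypergeometric tail with explicit
# binomial-coefficient sums, and BH with the textbook step-up recursion.

# --- all-pairs union-find genomic clustering -------------------------
brute_force_clusters <- function(features, max_gap = 5000, min_size = 2) {
  n <- nrow(features)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      same <- tolower(sub("^chr", "", tolower(features$chromosome[i]))) ==
        tolower(sub("^chr", "", tolower(features$chromosome[j])))
      if (!same) next
      gap <- max(features$low[i], features$low[j]) -
        min(features$high[i], features$high[j])
      if (max(gap, 0) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(features$name, roots)
  groups <- groups[lengths(groups) >= min_size]
  unname(lapply(groups, sort))
}

# --- exhaustive hypergeometric upper tail ----------------------------
hyper_tail_oracle <- function(a, b, cc, d) {
  N <- a + b + cc + d; K <- a + cc; n <- a + b
  ks <- seq(a, min(K, n))
  if (a > min(K, n)) return(0)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# --- textbook BH step-up recursion -----------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  q[m] <- min(ps[m] * m / m, 1)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(ps[i] * m / i, q[i + 1])
  out <- numeric(m)
  out[o] <- q
  out
}

# classic BH step-up rejection set at level alpha
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= alpha * seq_len(m) / m)
  if (!length(below)) return(integer(0))
  sort(o[seq_len(max(below))])
}

# --- tiny deterministic expression fixture ---------------------------
tiny_dataset <- function() {
  m <- matrix(c(100, 200, 300, 110, 210, 310,
                400, 150, 250, 420, 160, 260),
              nrow = 3,
              dimnames = list(c("mirA", "mirB", "mirC"),
                              c("g1_r1", "g1_r2", "g2_r1", "g2_r2")))
  expression_dataset(m, groups = c(g1_r1 = "G1", g1_r2 = "G1",
                                   g2_r1 = "G2", g2_r2 = "G2"))
}

# random normalized feature table on a few chromosomes
random_features <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c("Chr1", "Chr2", "ChrX"), n, replace = TRUE)
  lo <- sample.int(2e5, n, replace = TRUE)
  len <- sample(18:23, n, replace = TRUE)
  data.frame(name = sprintf("f%03d", seq_len(n)),
             chromosome = chrom, low = lo, high = lo + len,
             stringsAsFactors = FALSE)
}

cluster_membership <- function(clustered) {
  s <- split(clustered$name, clustered$cluster_id)
  unname(lapply(s[order(names(s))], sort))
}

set_equal_groups <- function(a, b) {
  key <- function(g) paste(sort(vapply(g, paste, "", collapse = ",")),
                           collapse = ";")
  identical(key(a), key(b))
}
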