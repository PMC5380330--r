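# Packaged fixtures: the published coordinate table of the 37
# co-downregulated miRNAs that form genomic clusters, and a small
# partly-synthetic miRNA -> cytotoxic-gene interaction table used for
# network contract tests.

#' Published coordinates of clustered co-downregulated miRNAs
#'
#' The 37 miRNA coordinate records reported as chromosome clusters of
#' miRNAs co-downregulated in CIK cells relative to PBMC, transcribed
#' verbatim: name, miRBase accession, chromosome, start, end (1-based
#' inclusive; minus-strand rows were printed with start > end and are
#' normalized here).  The `published_cluster` column carries the cluster
#' label (C1..C17) each record was reported under, so exact cluster
#' recovery can be asserted.
#'
#' @return data.frame with columns `name`, `accession`, `chromosome`,
#'   `low`, `high`, `strand`, `published_cluster`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "codown_mirna_coordinates.tsv",
                      package = "cikmir", mustWork = TRUE)
  feats <- read_coordinates(path, dialect = "table1")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  feats$published_cluster <- tab$cluster
  feats
}

#' Cytotoxicity-pathway miRNA-target fixture (partly synthetic)
#'
#' A small interaction table over anti-tumor effector genes expressed by
#' cytotoxic lymphocytes.  Edges marked `reported` encode relations
#' stated for this system (let-7c targeting FASLG, TNFSF10 and OSM;
#' miR-199a/b-5p targeting GZMB); edges marked `synthetic` are invented
#' complements chosen so the fixture exhibits the reported regulator
#' classes: PRF1, GZMB, TNFSF10 and FASLG targeted only by
#' co-downregulated miRNAs, and OSM, TNF and CD40LG by miRNAs of both
#' directions.  It is a contract-test fixture, not a claim about any
#' interaction database.
#'
#' @return list with `mti` (the edge table), `down_mirnas` and
#'   `up_mirnas` (the DEM status sets the fixture assumes).
#' @export
cytotox_fixture <- function() {
  path <- system.file("extdata", "cytotox_mti_synthetic.tsv",
                      package = "cikmir", mustWork = TRUE)
  list(mti = read_mti(path),
       down_mirnas = c("hsa-let-7c-5p", "hsa-miR-199a-5p",
                       "hsa-miR-199b-5p", "hsa-miR-28-5p",
                       "hsa-miR-23b-3p", "hsa-miR-30c-5p"),
       up_mirnas = c("hsa-miR-155-5p", "hsa-miR-21-5p",
                     "hsa-miR-146a-5p"))
}
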