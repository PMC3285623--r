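FIXTURE_MD5 <- c(
  table2_composition.tsv   = "47d805931d8995897291c144cd680e41",
  table3_flustra_genes.tsv = "43634cbdccc2905fc82083fcc1d2684b",
  table1_breakpoints.tsv   = "cb857abdd838ffd33c52412f4723ea10",
  recoding_partitions.tsv  = "e02fa261dc7c5f09d3febeb20c55a737")

#' Load the packaged reference tables
#'
#' Returns the genome-composition survey (50 metazoan mitogenomes with
#' phylum and superclade assignments), the per-gene composition of the
#' Flustra foliacea genome, the 10-taxon breakpoint distance matrix over
#' protein-coding plus rRNA gene orders, and the amino-acid recoding
#' partitions (Dayhoff groups and the 9- and 6-group minmax chi-squared
#' bins). The survey's \code{rounding_note} column flags derived cells
#' (AT\%, skews) that do not recompute exactly from the 3-decimal printed
#' proportions; such cells are within the propagation error of the inputs'
#' own rounding. File checksums are verified at load time.
#'
#' The two printed composition tables use different column orders (A,C,G,T
#' versus A,G,C,T); both are normalized to A,C,G,T here.
#'
#' @return list with \code{table2} (data frame), \code{table3} (data
#'   frame, columns reordered to A,C,G,T), \code{table1} (symmetric integer
#'   matrix), \code{dayhoff}, \code{minmax9}, \code{minmax6} (partition
#'   lists), \code{minmax_min_p} (named vector of the reported minimum
#'   p-values).
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "mitocomp")
  for (f in names(FIXTURE_MD5)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing fixture file: ", f)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, unname(FIXTURE_MD5[[f]])))
      stop("fixture checksum mismatch for ", f, ": ", md5)
  }
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, check.names = FALSE,
                                      stringsAsFactors = FALSE, quote = "",
                                      comment.char = "")
  table2 <- rd("table2_composition.tsv")
  table2$rounding_note[is.na(table2$rounding_note)] <- ""
  table3 <- rd("table3_flustra_genes.tsv")
  table3 <- table3[, c("unit", "A", "C", "G", "T",
                       "at_percent", "at_skew", "gc_skew")]
  t1 <- rd("table1_breakpoints.tsv")
  table1 <- as.matrix(t1[, -1L])
  rownames(table1) <- t1[[1L]]
  parts <- rd("recoding_partitions.tsv")
  getp <- function(nm) parse_partition(parts$partition[parts$name == nm])
  list(table2 = table2, table3 = table3, table1 = table1,
       dayhoff = getp("dayhoff"), minmax9 = getp("minmax9"),
       minmax6 = getp("minmax6"),
       minmax_min_p = stats::setNames(parts$min_p, parts$name))
}
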