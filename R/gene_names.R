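#' Normalize a gene name to the controlled vocabulary
#'
#' Maps the many GenBank spellings of mitochondrial gene names (COI, COX1,
#' CYTB, ND4L, 12S rRNA, ...) onto the controlled token set \code{atp6},
#' \code{atp8}, \code{cox1}-\code{cox3}, \code{cob}, \code{nad1}-\code{nad6},
#' \code{nad4L}, \code{rrnS}, \code{rrnL}, \code{MNCR} and single-letter tRNA
#' tokens. Leucine and serine tRNAs are ambiguous between two isoacceptor
#' families and are resolved with the anticodon: the anticodon is
#' reverse-complemented to its codon, and CUN codons give \code{L1}, UUR give
#' \code{L2}, AGN give \code{S1}, UCN give \code{S2}. The synonym table is
#' packaged as a tab-separated file and can be extended by the caller.
#'
#' @param raw gene name as found in a GenBank qualifier.
#' @param anticodon optional 3-letter anticodon (RNA or DNA spelling);
#'   required for leucine and serine tRNAs.
#' @param synonyms optional data frame with columns \code{raw} and
#'   \code{token}, merged over the packaged table.
#' @return a single token from the controlled vocabulary.
#' @export
normalize_gene_name <- function(raw, anticodon = NULL, synonyms = NULL) {
  if (is.null(raw) || is.na(raw) || !nzchar(trimws(raw)))
    stop("empty gene name")
  raw <- trimws(raw)
  if (grepl("^TRN", toupper(gsub("[^A-Za-z0-9]", "", raw))) ||
      grepl("transfer RNA", raw, ignore.case = TRUE))
    return(normalize_trna_name(raw, anticodon))
  key <- toupper(gsub("[^A-Za-z0-9]", "", raw))
  tab <- synonym_table(synonyms)
  hit <- tab$token[match(key, tab$raw)]
  if (!is.na(hit)) return(hit)
  stop("cannot normalize gene name '", raw, "'; vocabulary: ",
       paste(c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
               paste0("nad", 1:6), "nad4L", "rrnS", "rrnL", "MNCR",
               "trnX (single-letter tRNA tokens, L1/L2/S1/S2 for Leu/Ser)"),
             collapse = ", "))
}

synonym_table <- local({
  cache <- NULL
  function(extra = NULL) {
    if (is.null(cache)) {
      path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
      cache <<- utils::read.table(path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
    }
    tab <- cache
    if (!is.null(extra)) {
      extra$raw <- toupper(gsub("[^A-Za-z0-9]", "", extra$raw))
      tab <- rbind(extra[, c("raw", "token")], tab)
    }
    tab
  }
})

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

normalize_trna_name <- function(raw, anticodon) {
  up <- toupper(raw)
  # direct disambiguated tokens (trnL1, tRNA-Ser2, W2 ...)
  m <- regmatches(up, regexec("([LSW])[- ]?([12])", gsub("TRNA?|TRANSFER RNA", "", up)))[[1L]]
  if (length(m) == 3L && !grepl("\\(", up)) return(paste0(m[2L], m[3L]))
  # codon-family spelled in the name, e.g. tRNA-Leu(UUR)
  fam <- regmatches(up, regexec("\\((CUN|UUR|AGN|UCN)\\)", up))[[1L]]
  if (length(fam) == 2L)
    return(switch(fam[2L], CUN = "L1", UUR = "L2", AGN = "S1", UCN = "S2"))
  aa <- NA_character_
  m3 <- regmatches(up, regexec(paste0("(", paste(names(AA3TO1), collapse = "|"), ")"), up))[[1L]]
  if (length(m3) == 2L) aa <- AA3TO1[[m3[2L]]]
  if (is.na(aa)) {
    key <- gsub("[^A-Z0-9]", "", sub("TRANSFER RNA", "TRN", up))
    m1 <- regmatches(key, regexec("^TRNA?([A-Z])$", key))[[1L]]
    if (length(m1) == 2L) aa <- m1[2L]
  }
  if (is.na(aa)) stop("cannot parse tRNA name '", raw, "'")
  if (aa %in% c("L", "S")) {
    if (is.null(anticodon) || is.na(anticodon))
      stop("tRNA-", aa, " ('", raw, "') needs an anticodon to resolve ",
           aa, "1 vs ", aa, "2")
    codon <- revcomp(chartr("Uu", "Tt", toupper(anticodon)))
    fam2 <- substr(codon, 1L, 2L)
    if (aa == "L") {
      if (fam2 == "CT") return("L1")
      if (codon %in% c("TTA", "TTG")) return("L2")
    } else {
      if (fam2 == "AG") return("S1")
      if (fam2 == "TC") return("S2")
    }
    stop("anticodon '", anticodon, "' is not a ", aa, " isoacceptor")
  }
  aa
}

#' Reverse-complement a nucleotide string
#' @param x character string over A,C,G,T,N (case preserved).
#' @return the reverse complement.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
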