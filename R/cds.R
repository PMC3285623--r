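#' Extract the nucleotide sequence of a feature on its coding strand
#'
#' @param genome a \code{mito_genome}.
#' @param feature one row of \code{genome$features}.
#' @return nucleotide string, reverse-complemented for minus-strand features.
#' @export
feature_sequence <- function(genome, feature) {
  s <- if (feature$wraps_origin) {
    paste0(substr(genome$sequence, feature$start + 1L, genome$length),
           substr(genome$sequence, 1L, feature$end))
  } else {
    substr(genome$sequence, feature$start + 1L, feature$end)
  }
  if (feature$strand < 0L) revcomp(s) else s
}

genetic_code <- local({
  cache <- list()
  function(code = "5") {
    code <- as.character(code)
    if (is.null(cache[[code]]))
      cache[[code]] <<- Biostrings::getGeneticCode(code)
    cache[[code]]
  }
})

#' Extract in-frame codons and translation of a protein-coding gene
#'
#' Returns the codon triplets of a CDS read on its coding strand and the
#' conceptual translation under the invertebrate mitochondrial code by
#' default. A trailing incomplete termination codon (1-2 bases, flagged in
#' the feature table) is excluded from the codon list.
#'
#' @param genome a \code{mito_genome} from [read_genbank()].
#' @param token gene token naming a CDS feature (e.g. \code{"cox1"}).
#' @param code NCBI translation table id; default \code{"5"}
#'   (invertebrate mitochondrial).
#' @return list with \code{codons} (character vector of triplets),
#'   \code{translation} (amino-acid string, \code{*} for stops),
#'   \code{incomplete_stop} (the trailing bases, \code{""} if none).
#'   Internal stop codons trigger a warning, not an error.
#' @export
extract_cds <- function(genome, token, code = "5") {
  i <- which(genome$features$name == token & genome$features$kind == "cds")
  if (!length(i)) stop("no CDS feature named '", token, "'")
  f <- genome$features[i[1L], ]
  s <- feature_sequence(genome, f)
  isl <- f$incomplete_stop_len
  if ((nchar(s) - isl) %% 3L != 0L)
    stop("frame error in ", token, ": length ", nchar(s),
         " minus incomplete stop ", isl, " is not a multiple of 3")
  body <- substr(s, 1L, nchar(s) - isl)
  tail <- if (isl) substr(s, nchar(s) - isl + 1L, nchar(s)) else ""
  codons <- substring(body, seq(1L, nchar(body), 3L), seq(3L, nchar(body), 3L))
  translation <- translate_codons(codons, code)
  internal <- which(strsplit(translation, "")[[1L]] == "*")
  internal <- internal[internal < length(codons)]
  if (length(internal))
    warning("internal stop codon(s) in ", token, " at codon ",
            paste(internal, collapse = ", "))
  list(codons = codons, translation = translation, incomplete_stop = tail)
}

#' Translate codon triplets
#' @param codons character vector of triplets over A,C,G,T (N allowed,
#'   translated as X).
#' @param code NCBI translation table id.
#' @return amino-acid string.
#' @export
translate_codons <- function(codons, code = "5") {
  gc <- genetic_code(code)
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a (circular) signed gene order
#'
#' @param tokens character vector of gene tokens, unique.
#' @param signs integer vector of +1/-1; a single value is recycled.
#' @param taxon taxon label.
#' @param circular logical; circular orders compare equal under rotation.
#' @return object of class \code{gene_order}.
#' @export
gene_order <- function(tokens, signs = 1L, taxon = "", circular = TRUE) {
  signs <- rep_len(as.integer(signs), length(tokens))
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (anyDuplicated(tokens))
    stop("duplicate gene tokens in order: ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "))
  structure(list(taxon = taxon, tokens = as.character(tokens),
                 signs = signs, circular = isTRUE(circular)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s, %d genes): %s\n", x$taxon,
              if (x$circular) "circular" else "linear", length(x$tokens),
              paste(ifelse(x$signs < 0, paste0("-", x$tokens), x$tokens),
                    collapse = " ")))
  invisible(x)
}

#' Extract the gene order of a genome
#'
#' Genes of the requested feature kinds listed in genomic order starting from
#' the feature with the smallest start coordinate; each gene carries the sign
#' of its strand. tRNAs are excluded by default, giving the standard 15-token
#' order over the 13 protein-coding and 2 rRNA genes.
#'
#' @param genome a \code{mito_genome}.
#' @param include feature kinds to keep; default \code{c("cds", "rrna")}.
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(genome, include = c("cds", "rrna")) {
  f <- genome$features[genome$features$kind %in% include, , drop = FALSE]
  gene_order(f$name, f$strand, taxon = genome$taxon, circular = genome$circular)
}

#' Back-translate an amino-acid alignment to a codon alignment
#'
#' Uses the aligned amino-acid rows as a scaffold: each residue column
#' becomes the three nucleotide columns of the corresponding codon, each gap
#' becomes a triple gap. The supplied codons must match the ungapped residues
#' of each row in number and (up to a warning) in translation.
#'
#' @param aa_alignment an AA20 [mito_alignment()].
#' @param cds_by_taxon named list: taxon -> character vector of codons, in
#'   the order of that taxon's ungapped residues.
#' @param code NCBI translation table id used for the consistency check.
#' @return a DNA4 [mito_alignment()] with three times the columns.
#' @export
backtranslate_alignment <- function(aa_alignment, cds_by_taxon, code = "5") {
  gap <- attr(aa_alignment, "gap")
  out <- matrix(gap, nrow(aa_alignment), 3L * ncol(aa_alignment),
                dimnames = list(rownames(aa_alignment), NULL))
  for (tx in rownames(aa_alignment)) {
    row <- unclass(aa_alignment)[tx, ]
    res <- which(row != gap)
    codons <- cds_by_taxon[[tx]]
    if (is.null(codons)) stop("no codons supplied for taxon ", tx)
    if (length(codons) != length(res))
      stop("taxon ", tx, ": ", length(codons), " codons for ",
           length(res), " ungapped residues (first mismatch at alignment column ",
           if (length(res)) res[min(length(res), length(codons) + 1L)] else 1L, ")")
    aa <- strsplit(translate_codons(codons, code), "")[[1L]]
    diffs <- which(aa != row[res] & row[res] != "X")
    if (length(diffs))
      warning("taxon ", tx, ": codon translation disagrees with residue at ",
              length(diffs), " position(s), first at alignment column ", res[diffs[1L]])
    cols <- rbind(3L * (res - 1L) + 1L, 3L * (res - 1L) + 2L, 3L * res)
    out[tx, as.vector(cols)] <- unlist(strsplit(codons, ""), use.names = FALSE)
  }
  mito_alignment(out, alphabet = "DNA4", gap = gap)
}

#' Translate a codon alignment row-wise
#'
#' Inverse of [backtranslate_alignment()]: each non-gap codon column triple
#' becomes one residue, triple gaps become gaps.
#'
#' @param dna_alignment a DNA4 [mito_alignment()] with columns in codon
#'   triples.
#' @param code NCBI translation table id.
#' @return an AA20 [mito_alignment()] with a third of the columns.
#' @export
translate_alignment <- function(dna_alignment, code = "5") {
  if (ncol(dna_alignment) %% 3L != 0L)
    stop("column count is not a multiple of 3")
  gap <- attr(dna_alignment, "gap")
  L <- ncol(dna_alignment) / 3L
  gc <- genetic_code(code)
  out <- matrix(gap, nrow(dna_alignment), L,
                dimnames = list(rownames(dna_alignment), NULL))
  m <- unclass(dna_alignment)
  for (j in seq_len(L)) {
    cod <- paste0(m[, 3L * j - 2L], m[, 3L * j - 1L], m[, 3L * j])
    is_gap <- cod == strrep(gap, 3L)
    aa <- gc[cod]
    aa[is.na(aa) & !is_gap] <- "X"
    out[!is_gap, j] <- aa[!is_gap]
  }
  mito_alignment(out, alphabet = "AA20", gap = gap)
}
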