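#' Construct a multiple alignment
#'
#' A thin S3 container for a taxa x columns character matrix over a declared
#' alphabet. Rows are taxa, columns are alignment positions; the gap symbol is
#' carried as an attribute and is not part of the alphabet.
#'
#' @param mat character matrix with one row per taxon; rownames are taxon
#'   labels. A named character vector of equal-length sequences is also
#'   accepted.
#' @param alphabet one of \code{"DNA4"}, \code{"AA20"}, a \code{"RECODED-k"}
#'   label, or an explicit character vector of allowed states.
#' @param gap single gap character, default \code{"-"}.
#' @return an object of class \code{mito_alignment}: the character matrix with
#'   \code{alphabet} and \code{gap} attributes.
#' @export
mito_alignment <- function(mat, alphabet = "DNA4", gap = "-") {
  if (is.character(mat) && !is.matrix(mat)) {
    if (is.null(names(mat))) stop("sequence vector must be named by taxon")
    lens <- nchar(mat)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(toupper(mat), ""))
    rownames(mat) <- names(lens)
  }
  if (!is.matrix(mat) || !is.character(mat)) stop("mat must be a character matrix")
  if (is.null(rownames(mat))) stop("alignment rows must be named by taxon")
  states <- alignment_states(alphabet)
  label <- alphabet_label(alphabet)
  # N (DNA) and X/* (protein) are tolerated but never counted as states
  extras <- switch(label, DNA4 = "N", AA20 = c("X", "*"), character())
  bad <- setdiff(unique(as.vector(mat)), c(states, gap, extras))
  if (length(bad))
    stop("characters outside the ", label, " alphabet: ",
         paste(bad, collapse = " "))
  structure(mat, alphabet = label,
            states = states, gap = gap, class = "mito_alignment")
}

DNA_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

alignment_states <- function(alphabet) {
  if (is.character(alphabet) && length(alphabet) > 1L) return(alphabet)
  if (identical(alphabet, "DNA4")) return(DNA_STATES)
  if (identical(alphabet, "AA20")) return(AA_STATES)
  if (grepl("^RECODED-", alphabet))
    stop("RECODED alphabets need an explicit state set; use recode()")
  stop("unknown alphabet: ", alphabet)
}

alphabet_label <- function(alphabet) {
  if (is.character(alphabet) && length(alphabet) > 1L)
    return(paste0("RECODED-", length(alphabet)))
  alphabet
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("<mito_alignment> %d taxa x %d columns, alphabet %s\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  invisible(x)
}

#' @rdname mito_alignment
#' @param x a \code{mito_alignment}
#' @export
alignment_taxa <- function(x) rownames(x)

#' Read a FASTA alignment
#'
#' @param path FASTA file; all sequences must have equal length.
#' @param alphabet alphabet declaration passed to [mito_alignment()].
#' @param gap gap character.
#' @return a [mito_alignment()].
#' @export
read_alignment <- function(path, alphabet = "DNA4", gap = "-") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line is not a header): ", path)
  id <- cumsum(hdr)
  taxa <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(ss) paste(ss, collapse = ""), character(1))
  if (length(seqs) != length(taxa)) stop("FASTA record without sequence in ", path)
  names(seqs) <- taxa
  mito_alignment(seqs, alphabet = alphabet, gap = gap)
}

#' Write a FASTA alignment
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param x a [mito_alignment()] or named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_alignment <- function(x, path, width = 70L) {
  if (inherits(x, "mito_alignment")) {
    seqs <- apply(unclass(x), 1L, paste, collapse = "")
  } else seqs <- x
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a report table
#'
#' Tab-separated with a single header row; the dialect used by every report
#' in the package.
#'
#' @param df data frame.
#' @param path output file.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report table written by [write_table()]
#' @param path input file.
#' @export
read_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Count non-gap states per taxon
#'
#' Builds the taxa x states count matrix used by the compositional tests;
#' gaps and \code{N} are excluded.
#'
#' @param al a [mito_alignment()].
#' @return integer matrix, taxa x states.
#' @export
count_matrix <- function(al) {
  states <- attr(al, "states")
  m <- matrix(0L, nrow(al), length(states),
              dimnames = list(rownames(al), states))
  for (s in states) m[, s] <- rowSums(unclass(al) == s)
  if (any(rowSums(m) == 0L))
    stop("taxa with no countable characters: ",
         paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  m
}

#' Restrict an alignment to codon-position columns
#'
#' @param al a [mito_alignment()] whose columns are an in-frame codon
#'   alignment (length divisible by 3).
#' @param positions integer vector drawn from \code{1:3}, e.g. \code{c(1, 2)}
#'   for first plus second positions.
#' @return a [mito_alignment()] with the selected columns, order preserved.
#' @export
codon_position_columns <- function(al, positions) {
  if (ncol(al) %% 3L != 0L) stop("column count is not a multiple of 3")
  if (!all(positions %in% 1:3)) stop("positions must be within 1:3")
  keep <- which(((seq_len(ncol(al)) - 1L) %% 3L + 1L) %in% positions)
  sub_alignment(al, keep)
}

sub_alignment <- function(al, cols) {
  out <- unclass(al)[, cols, drop = FALSE]
  structure(out, alphabet = attr(al, "alphabet"), states = attr(al, "states"),
            gap = attr(al, "gap"), class = "mito_alignment")
}
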