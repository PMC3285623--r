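#' Read an annotated mitochondrial genome from a GenBank flat file
#'
#' Parses the LOCUS line, accession, organism, feature table and ORIGIN
#' sequence of a single-record GenBank flat file. GenBank 1-based inclusive
#' coordinates are converted to 0-based half-open internal coordinates at
#' this boundary; \code{join()} locations that span the origin of a circular
#' genome are resolved to a single feature with \code{wraps_origin = TRUE}.
#' Gene names are normalized to the controlled vocabulary via
#' [normalize_gene_name()]; duplicated tRNA isotypes receive ordinal
#' suffixes (W1, W2) in coordinate order.
#'
#' CDS features whose span is not a multiple of 3 are taken to end in an
#' incomplete termination codon (1 or 2 trailing bases, completed in vivo by
#' polyadenylation) and get \code{incomplete_stop_len} set accordingly.
#'
#' @param path GenBank flat file with at least one CDS or rRNA feature.
#' @param synonyms optional extra synonym table (data frame with columns
#'   \code{raw}, \code{token}) merged over the packaged one.
#' @return an object of class \code{mito_genome}: list with
#'   \code{accession}, \code{taxon}, \code{length}, \code{circular},
#'   \code{sequence} and a \code{features} data frame (\code{name},
#'   \code{start}, \code{end}, \code{strand}, \code{wraps_origin},
#'   \code{kind}, \code{incomplete_stop_len}), sorted by start.
#' @export
read_genbank <- function(path, synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("malformed GenBank record: no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1L]), "\\s+")[[1L]]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L][1L]))
  circular <- any(grepl("circular", locus[1L], ignore.case = TRUE))
  acc <- sub("^ACCESSION\\s+", "", grep("^ACCESSION", lines, value = TRUE)[1L])
  if (is.na(acc)) acc <- toks[2L]
  acc <- strsplit(trimws(acc), "\\s+")[[1L]][1L]
  org <- grep("^\\s*ORGANISM", lines, value = TRUE)[1L]
  taxon <- if (is.na(org)) acc else trimws(sub("^\\s*ORGANISM\\s+", "", org))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank record: missing ORIGIN/sequence in ", path)
  if (!length(fstart)) stop("malformed GenBank record: missing FEATURES table in ", path)
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[ 0-9/]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) stop("missing sequence in ", path)
  bad <- setdiff(unique(strsplit(sequence, "")[[1L]]), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("ambiguity characters other than N in sequence: ", paste(bad, collapse = " "))
  if (is.na(len)) len <- nchar(sequence)
  if (len != nchar(sequence))
    stop("LOCUS length ", len, " does not match sequence length ", nchar(sequence))

  feats <- parse_feature_table(lines[(fstart[1L] + 1L):(ostart[1L] - 1L)], path)
  rows <- lapply(feats, function(f) feature_row(f, len, circular, synonyms))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  features <- do.call(rbind, rows)
  if (is.null(features) || !any(features$kind %in% c("cds", "rrna")))
    stop("no CDS or rRNA feature found in ", path)
  features <- features[order(features$start, features$end), , drop = FALSE]
  features$name <- disambiguate_trna(features$name, features$kind)
  dup <- features$name[duplicated(features$name) & features$kind != "noncoding"]
  if (length(dup))
    stop("two features normalize to the same token (disambiguate them): ",
         paste(unique(dup), collapse = ", "))
  rownames(features) <- NULL
  structure(list(accession = acc, taxon = taxon, length = len,
                 circular = circular, sequence = sequence, features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %d bp, %s, %d features\n",
              x$taxon, x$accession, x$length,
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

# Split the feature table into per-feature blocks of (key, location, qualifiers).
parse_feature_table <- function(flines, path) {
  starts <- grep("^ {1,10}\\S", flines)
  if (!length(starts)) return(list())
  ends <- c(starts[-1L] - 1L, length(flines))
  lapply(seq_along(starts), function(i) {
    block <- flines[starts[i]:ends[i]]
    head <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    if (length(head) < 2L)
      stop("malformed feature line in ", path, ": '", block[1L], "'")
    rest <- trimws(block[-1L])
    # location may continue over lines until the first qualifier
    qual_at <- grep("^/", rest)
    loc_extra <- if (length(qual_at)) rest[seq_len(min(qual_at) - 1L)] else rest
    quals <- if (length(qual_at)) rest[min(qual_at):length(rest)] else character()
    list(key = head[1L],
         location = paste(c(head[2L], loc_extra), collapse = ""),
         qualifiers = paste(quals, collapse = " "))
  })
}

get_qualifier <- function(quals, name) {
  m <- regmatches(quals, regexec(paste0("/", name, '="([^"]*)"'), quals))[[1L]]
  if (length(m) == 2L) return(m[2L])
  m <- regmatches(quals, regexec(paste0("/", name, "=([^ /]+)"), quals))[[1L]]
  if (length(m) == 2L) return(m[2L])
  NA_character_
}

# Parse a GenBank location string into (start, end, strand, wraps) in
# 0-based half-open coordinates.
parse_location <- function(loc, genome_len, circular) {
  strand <- 1L
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  segs <- strsplit(loc, ",")[[1L]]
  parse_seg <- function(s) {
    s <- gsub("[<>]", "", s)
    n <- as.integer(strsplit(s, "\\.\\.")[[1L]])
    if (length(n) == 1L) n <- c(n, n)
    if (any(is.na(n))) stop("malformed location segment: '", s, "'")
    n
  }
  segs <- lapply(segs, parse_seg)
  if (length(segs) == 1L) {
    n <- segs[[1L]]
    return(list(start = n[1L] - 1L, end = n[2L], strand = strand, wraps = FALSE))
  }
  if (length(segs) == 2L && circular &&
      segs[[1L]][2L] == genome_len && segs[[2L]][1L] == 1L) {
    return(list(start = segs[[1L]][1L] - 1L, end = segs[[2L]][2L],
                strand = strand, wraps = TRUE))
  }
  stop("unsupported join() location: ", loc)
}

feature_row <- function(f, genome_len, circular, synonyms) {
  kind <- switch(f$key,
                 CDS = "cds", rRNA = "rrna", tRNA = "trna",
                 misc_feature = "noncoding", D_loop = "noncoding",
                 NULL)
  if (is.null(kind)) return(NULL)
  loc <- parse_location(f$location, genome_len, circular)
  raw <- get_qualifier(f$qualifiers, "gene")
  if (is.na(raw)) raw <- get_qualifier(f$qualifiers, "product")
  if (is.na(raw)) raw <- get_qualifier(f$qualifiers, "note")
  anticodon <- extract_anticodon(f$qualifiers, raw)
  name <- if (kind == "noncoding") "MNCR" else
    normalize_gene_name(raw, anticodon = anticodon, synonyms = synonyms)
  flen <- if (loc$wraps) (genome_len - loc$start) + loc$end else loc$end - loc$start
  isl <- if (kind == "cds") flen %% 3L else 0L
  data.frame(name = name, start = loc$start, end = loc$end,
             strand = loc$strand, wraps_origin = loc$wraps, kind = kind,
             incomplete_stop_len = isl, stringsAsFactors = FALSE)
}

extract_anticodon <- function(quals, raw) {
  m <- regmatches(quals, regexec("seq:([A-Za-z]{3})", quals))[[1L]]
  if (length(m) == 2L) return(toupper(m[2L]))
  if (!is.na(raw)) {
    m <- regmatches(raw, regexec("\\(([ACGUTacgut]{3})\\)", raw))[[1L]]
    if (length(m) == 2L) return(toupper(m[2L]))
  }
  NA_character_
}

disambiguate_trna <- function(names, kinds) {
  is_letter <- kinds == "trna" & names %in% setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  for (nm in unique(names[is_letter])) {
    idx <- which(names == nm & is_letter)
    if (length(idx) > 1L)
      names[idx] <- paste0(nm, seq_along(idx))
  }
  names
}
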