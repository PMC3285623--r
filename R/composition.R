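#' Perna-Kocher strand skews
#'
#' AT-skew = (A - T) / (A + T), GC-skew = (G - C) / (G + C), computed from
#' base proportions (or counts; only ratios matter). A zero denominator
#' yields \code{NaN} rather than an error, as an explicit undefined-skew
#' sentinel.
#'
#' @param p_A,p_C,p_G,p_T base proportions or counts.
#' @return named numeric vector \code{c(at_skew, gc_skew)}, each in
#'   \code{[-1, 1]} (or \code{NaN}).
#' @export
compute_skews <- function(p_A, p_C, p_G, p_T) {
  at <- if (p_A + p_T > 0) (p_A - p_T) / (p_A + p_T) else NaN
  gc <- if (p_G + p_C > 0) (p_G - p_C) / (p_G + p_C) else NaN
  c(at_skew = at, gc_skew = gc)
}

new_composition_profile <- function(unit, counts) {
  total <- sum(counts)
  if (total == 0) stop("no countable characters in unit '", unit, "'")
  p <- counts / total
  sk <- compute_skews(p[["A"]], p[["C"]], p[["G"]], p[["T"]])
  structure(list(unit = unit, counts = counts, proportions = p,
                 at_percent = 100 * (p[["A"]] + p[["T"]]),
                 at_skew = sk[["at_skew"]], gc_skew = sk[["gc_skew"]]),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: A=%.3f C=%.3f G=%.3f T=%.3f  AT%%=%.1f  AT-skew=%.3f GC-skew=%.3f\n",
              x$unit, x$proportions[["A"]], x$proportions[["C"]],
              x$proportions[["G"]], x$proportions[["T"]],
              x$at_percent, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Base composition of a nucleotide sequence
#'
#' Counts A, C, G, T (N and gaps excluded) and derives proportions, AT%
#' and the Perna-Kocher skews.
#'
#' @param seq nucleotide string, or character vector of strings pooled
#'   together.
#' @param unit label for the profiled unit.
#' @return a \code{composition_profile}: list with \code{unit},
#'   \code{counts}, \code{proportions}, \code{at_percent}, \code{at_skew},
#'   \code{gc_skew}.
#' @export
base_composition <- function(seq, unit = "sequence") {
  chars <- unlist(strsplit(toupper(paste(seq, collapse = "")), ""),
                  use.names = FALSE)
  counts <- vapply(DNA_STATES, function(s) sum(chars == s), numeric(1))
  new_composition_profile(unit, counts)
}

#' Per-codon-position composition of a set of coding sequences
#'
#' @param cds_set list of codon character vectors (complete triplets on the
#'   coding strand), e.g. the \code{codons} elements of [extract_cds()].
#' @return list of four \code{composition_profile}s: \code{pos1},
#'   \code{pos2}, \code{pos3} over all supplied genes, and \code{pooled}
#'   over all positions.
#' @export
codon_position_composition <- function(cds_set) {
  if (is.character(cds_set)) cds_set <- list(cds_set)
  codons <- unlist(cds_set, use.names = FALSE)
  if (!length(codons)) stop("empty codon set")
  pos <- lapply(1:3, function(i) {
    b <- substr(codons, i, i)
    new_composition_profile(paste0("codon position ", i),
                            vapply(DNA_STATES, function(s) sum(b == s), numeric(1)))
  })
  pooled <- new_composition_profile(
    "protein coding sequences",
    pos[[1L]]$counts + pos[[2L]]$counts + pos[[3L]]$counts)
  list(pos1 = pos[[1L]], pos2 = pos[[2L]], pos3 = pos[[3L]], pooled = pooled)
}

#' Codon usage and codon-family usage
#'
#' Counts all 64 codons over the supplied coding sequences and aggregates
#' them into codon families: one family per amino acid, except leucine and
#' serine which split into the two-tRNA families Leu1 (CUN), Leu2 (UUR),
#' Ser1 (AGN), Ser2 (UCN); termination codons form the Stop family. Complete
#' termination codons are counted; codons containing N are excluded from the
#' 64-codon table and tallied separately.
#'
#' @param cds_set list of codon character vectors.
#' @param code NCBI translation table id (default invertebrate
#'   mitochondrial), used to assign families.
#' @return a \code{codon_usage_table}: list with \code{counts} (named 64),
#'   \code{family_counts}, \code{family_fractions}, \code{total_codons},
#'   \code{n_excluded}.
#' @export
codon_usage <- function(cds_set, code = "5") {
  if (is.character(cds_set)) cds_set <- list(cds_set)
  codons <- toupper(unlist(cds_set, use.names = FALSE))
  gc <- genetic_code(code)
  all64 <- names(gc)
  ok <- codons %in% all64
  counts <- vapply(all64, function(cd) sum(codons == cd), numeric(1))
  fam <- codon_families(code)
  family_counts <- tapply(counts[all64], fam[all64], sum)
  family_counts <- family_counts[order(names(family_counts))]
  total <- sum(counts)
  structure(list(counts = counts, family_counts = c(family_counts),
                 family_fractions = c(family_counts) / total,
                 total_codons = total, n_excluded = sum(!ok)),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d codons (%d excluded), %d families\n",
              x$total_codons, x$n_excluded, length(x$family_counts)))
  top <- sort(x$counts, decreasing = TRUE)[1:5]
  cat("  top codons:", paste(sprintf("%s=%d", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Codon family labels for the 64 codons
#' @param code NCBI translation table id.
#' @return named character vector: codon -> family label (e.g. \code{Leu1},
#'   \code{Ser2}, \code{Phe}, \code{Stop}).
#' @export
codon_families <- function(code = "5") {
  gc <- genetic_code(code)
  aa3 <- stats::setNames(names(AA3TO1), AA3TO1)
  fam <- vapply(names(gc), function(cd) {
    a <- gc[[cd]]
    if (a == "*") return("Stop")
    if (a == "L") return(if (substr(cd, 1, 2) == "CT") "Leu1" else "Leu2")
    if (a == "S") return(if (substr(cd, 1, 2) == "AG") "Ser1" else "Ser2")
    nm <- aa3[[a]]
    paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 3)))
  }, character(1))
  fam
}

#' Uncorrected p-distance between two aligned rows
#'
#' Columns where either row carries a gap or N are skipped.
#'
#' @param row_a,row_b equal-length character vectors or strings.
#' @param gap gap character.
#' @return fraction of differing retained columns.
#' @export
p_distance <- function(row_a, row_b, gap = "-") {
  if (is.character(row_a) && length(row_a) == 1L) row_a <- strsplit(row_a, "")[[1L]]
  if (is.character(row_b) && length(row_b) == 1L) row_b <- strsplit(row_b, "")[[1L]]
  if (length(row_a) != length(row_b)) stop("rows differ in length")
  keep <- !(row_a %in% c(gap, "N")) & !(row_b %in% c(gap, "N"))
  if (!any(keep)) stop("no retained columns (all gap/N)")
  sum(row_a[keep] != row_b[keep]) / sum(keep)
}

#' Clade summaries of AT content
#'
#' Unweighted (per-genome) arithmetic means of AT% per clade, plus the
#' global mean, minimum and maximum with the taxa attaining them.
#'
#' @param profiles list of \code{composition_profile}s, or a data frame with
#'   columns \code{taxon} and \code{at_percent} (e.g. the packaged genome
#'   survey from [load_fixtures()]).
#' @param grouping named character vector or map: taxon -> clade.
#' @return list with \code{per_clade} (data frame: clade, n, mean, min, max)
#'   and \code{global} (mean, min, max, argmin, argmax).
#' @export
group_summary <- function(profiles, grouping) {
  if (is.data.frame(profiles)) {
    taxa <- profiles$taxon
    atp <- profiles$at_percent
  } else {
    taxa <- vapply(profiles, function(p) p$unit, character(1))
    atp <- vapply(profiles, function(p) p$at_percent, numeric(1))
  }
  clade <- grouping[taxa]
  if (any(is.na(clade)))
    stop("taxa without clade assignment: ",
         paste(taxa[is.na(clade)], collapse = ", "))
  empty <- setdiff(unique(grouping), clade)
  if (length(empty))
    warning("empty clade(s) omitted: ", paste(empty, collapse = ", "))
  per <- do.call(rbind, lapply(split(atp, clade), function(v)
    data.frame(n = length(v), mean = mean(v), min = min(v), max = max(v))))
  per <- data.frame(clade = rownames(per), per, row.names = NULL)
  list(per_clade = per,
       global = list(mean = mean(atp), min = min(atp), max = max(atp),
                     argmin = taxa[which.min(atp)],
                     argmax = taxa[which.max(atp)]))
}

#' Composition report rows for a profile
#'
#' Formats a profile the way the package's reports print them: proportions
#' and skews to 3 decimals, AT% to 1 decimal. Full precision is retained in
#' the profile object itself.
#'
#' @param profile a \code{composition_profile}.
#' @return one-row data frame.
#' @export
profile_row <- function(profile) {
  data.frame(unit = profile$unit,
             A = round(profile$proportions[["A"]], 3),
             C = round(profile$proportions[["C"]], 3),
             G = round(profile$proportions[["G"]], 3),
             T = round(profile$proportions[["T"]], 3),
             at_percent = round(profile$at_percent, 1),
             at_skew = round(profile$at_skew, 3),
             gc_skew = round(profile$gc_skew, 3),
             row.names = NULL)
}
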