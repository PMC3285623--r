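#' Parse and format state-group partitions
#'
#' Partitions are serialized as comma-separated residue groups, e.g.
#' \code{"AGPST,C,DENQ,FWY,HKR,ILMV"} for the Dayhoff groups.
#'
#' @param x partition string.
#' @return \code{parse_partition}: list of character vectors (one per
#'   group); \code{format_partition}: the canonical string (groups sorted
#'   internally and ordered by first member).
#' @export
parse_partition <- function(x) {
  canonical_partition(strsplit(strsplit(x, ",")[[1L]], ""))
}

#' @rdname parse_partition
#' @param groups list of character vectors.
#' @export
format_partition <- function(groups) {
  paste(vapply(canonical_partition(groups), paste, character(1), collapse = ""),
        collapse = ",")
}

canonical_partition <- function(groups) {
  groups <- lapply(groups, function(g) sort(unique(g)))
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

check_partition <- function(groups, states) {
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("partition groups overlap: ",
         paste(unique(flat[duplicated(flat)]), collapse = " "))
  miss <- setdiff(states, flat)
  if (length(miss))
    stop("partition does not cover the alphabet; missing: ",
         paste(miss, collapse = " "))
  if (any(lengths(groups) == 0L)) stop("empty group in partition")
  invisible(TRUE)
}

#' Recode an alignment into state groups
#'
#' Each residue is replaced by its group's symbol (the lexicographically
#' first member of the group, which is unique across groups); gaps are
#' preserved. Binned counts of the result equal the sums of the member
#' counts.
#'
#' @param al a [mito_alignment()].
#' @param partition list of disjoint character groups covering the
#'   alignment alphabet, a partition string, or a \code{bin_partition} from
#'   [find_minmax_bins()].
#' @return a [mito_alignment()] over the \code{RECODED-k} alphabet of group
#'   symbols.
#' @export
recode <- function(al, partition) {
  if (inherits(partition, "bin_partition")) partition <- partition$groups
  if (is.character(partition) && length(partition) == 1L)
    partition <- parse_partition(partition)
  groups <- canonical_partition(partition)
  states <- attr(al, "states")
  check_partition(groups, states)
  symbols <- vapply(groups, `[`, character(1), 1L)
  map <- stats::setNames(rep(symbols, lengths(groups)),
                         unlist(groups, use.names = FALSE))
  gap <- attr(al, "gap")
  m <- unclass(al)
  out <- m
  in_alpha <- m %in% names(map)
  bad <- setdiff(unique(as.vector(m)), c(names(map), gap, "X", "*", "N"))
  if (length(bad))
    stop("residues outside the partition: ", paste(bad, collapse = " "))
  out[in_alpha] <- map[m[in_alpha]]
  out[!in_alpha & m != gap] <- gap  # X/*/N carry no group; treat as missing
  mito_alignment(out, alphabet = symbols, gap = gap)
}

# Per-taxon binned chi-square statistics for a partition.
# Expected counts are row totals times pooled binned frequencies; the
# reported df is k - 1 (the convention is recorded in the output).
binned_taxon_stats <- function(cm, groups) {
  k <- length(groups)
  ind <- matrix(0, ncol(cm), k, dimnames = list(colnames(cm), NULL))
  for (g in seq_len(k)) ind[groups[[g]], g] <- 1
  B <- cm %*% ind
  q <- colSums(B) / sum(B)
  expd <- outer(rowSums(B), q)
  ok <- q > 0
  stats_ <- rowSums(((B - expd)^2 / ifelse(expd > 0, expd, 1))[, ok, drop = FALSE])
  stats_
}

partition_objective <- function(cm, groups) {
  max(binned_taxon_stats(cm, groups))
}

#' Minmax chi-squared bins
#'
#' Searches for a partition of the alphabet into \code{k} bins minimizing
#' the maximum over taxa of the per-taxon binned chi-square statistic
#' (taxon binned counts against pooled binned frequencies, df = k - 1).
#' The search is heuristic: steepest-descent single-residue moves from
#' random restarts, deterministic given the seed; ties are broken towards
#' the lexicographically smallest partition. For alphabets of up to 8
#' states the heuristic recovers the exhaustive optimum.
#'
#' @param al a [mito_alignment()] or a taxa x states count matrix.
#' @param k number of bins, between 2 and the alphabet size.
#' @param seed RNG seed for the restarts.
#' @param restarts number of random restarts (>= 50 recommended).
#' @return a \code{bin_partition}: list with \code{groups}, \code{k},
#'   \code{min_p} (minimum over taxa of the binned chi-square p-value at
#'   df = k - 1), \code{max_stat}, \code{df}.
#' @export
find_minmax_bins <- function(al, k, seed = 1L, restarts = 50L) {
  cm <- if (inherits(al, "mito_alignment")) count_matrix(al) else as.matrix(al)
  states <- colnames(cm)
  if (k < 2L || k > length(states))
    stop("k must be between 2 and the alphabet size (", length(states), ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(restarts)) {
    groups <- random_partition(states, k)
    res <- steepest_descent(cm, groups, k)
    if (is.null(best) || res$obj < best_obj - 1e-12 ||
        (abs(res$obj - best_obj) <= 1e-12 &&
         format_partition(res$groups) < format_partition(best))) {
      best <- res$groups
      best_obj <- res$obj
    }
  }
  df <- k - 1L
  min_p <- stats::pchisq(best_obj, df, lower.tail = FALSE)
  structure(list(groups = canonical_partition(best), k = k, min_p = min_p,
                 max_stat = best_obj, df = df),
            class = "bin_partition")
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("<bin_partition> k = %d: %s  (max chi-sq = %.3f, df = %d, min p = %.3g)\n",
              x$k, format_partition(x$groups), x$max_stat, x$df, x$min_p))
  invisible(x)
}

random_partition <- function(states, k) {
  seeds <- sample(states, k)
  rest <- setdiff(states, seeds)
  groups <- as.list(seeds)
  if (length(rest)) {
    asg <- sample.int(k, length(rest), replace = TRUE)
    for (i in seq_along(rest)) groups[[asg[i]]] <- c(groups[[asg[i]]], rest[i])
  }
  groups
}

steepest_descent <- function(cm, groups, k) {
  obj <- partition_objective(cm, groups)
  repeat {
    best_move <- NULL
    best_obj <- obj
    best_key <- format_partition(groups)
    for (g in seq_len(k)) {
      if (length(groups[[g]]) == 1L) next  # source group must stay non-empty
      for (s in groups[[g]]) {
        for (h in seq_len(k)[-g]) {
          cand <- groups
          cand[[g]] <- setdiff(cand[[g]], s)
          cand[[h]] <- c(cand[[h]], s)
          o <- partition_objective(cm, cand)
          key <- format_partition(cand)
          if (o < best_obj - 1e-12 ||
              (o <= best_obj + 1e-12 && o < obj - 1e-12 && key < best_key)) {
            best_move <- cand
            best_obj <- o
            best_key <- key
          }
        }
      }
    }
    if (is.null(best_move)) break
    groups <- best_move
    obj <- best_obj
  }
  list(groups = groups, obj = obj)
}

#' Choose the number of bins by the min-P rule
#'
#' Runs [find_minmax_bins()] for k from \code{k_max} down to 2 and returns
#' the largest k whose minimum p-value exceeds \code{alpha}, i.e. the
#' finest binning for which compositional homogeneity cannot be rejected
#' for any taxon. If no k qualifies, returns 1 with a warning.
#'
#' @param al alignment or count matrix.
#' @param k_max largest bin count to try.
#' @param alpha threshold on the minimum p-value (default 0.05).
#' @param seed,restarts passed to [find_minmax_bins()].
#' @return integer k*; the winning \code{bin_partition} (when k* > 1) is
#'   attached as attribute \code{"partition"}.
#' @export
select_bin_count <- function(al, k_max, alpha = 0.05, seed = 1L,
                             restarts = 50L) {
  for (k in seq(k_max, 2L)) {
    bp <- find_minmax_bins(al, k, seed = seed, restarts = restarts)
    if (bp$min_p > alpha)
      return(structure(k, partition = bp))
  }
  warning("no bin count from 2 to ", k_max, " has min p > ", alpha,
          "; returning 1")
  1L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
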