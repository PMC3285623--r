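new_test_result <- function(statistic, df, p_value, detail = NULL,
                            degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 detail = detail, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Chi-square test of compositional homogeneity across taxa
#'
#' Classical contingency-table test of whether all taxa share the pooled
#' state composition: expected cell counts are row totals times pooled state
#' frequencies, the statistic is the usual sum of (obs - exp)^2 / exp, and
#' df = (taxa - 1)(states - 1). States with pooled count zero are dropped
#' from the table (and the df) with a warning. The test treats rows as
#' independent multinomial samples; shared phylogenetic history makes it
#' anti-conservative on real alignments, which is why the matched-pairs
#' symmetry test is offered alongside.
#'
#' @param m taxa x states count matrix (see [count_matrix()]).
#' @return a \code{test_result} with a per-taxon detail table of each
#'   taxon's contribution to the statistic.
#' @export
chi2_homogeneity <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 taxa and >= 2 states")
  if (any(rowSums(m) == 0)) stop("taxa with zero counts")
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("dropping states with pooled count zero: ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
  }
  pooled <- colSums(m) / sum(m)
  expd <- outer(rowSums(m), pooled)
  contrib <- rowSums((m - expd)^2 / expd)
  stat <- sum(contrib)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  detail <- data.frame(taxon = rownames(m) %||% seq_len(nrow(m)),
                       contribution = contrib, row.names = NULL)
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE), detail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Matched-pairs test of symmetry (Bowker) for two aligned sequences
#'
#' Tests whether the divergence matrix N[i, j] (counts of columns where one
#' sequence shows state i and the other state j, over columns where both are
#' non-gap states) is symmetric. Asymmetry is the signature of
#' non-stationary evolution between the two lineages. The statistic is
#' S = sum over unordered state pairs of (N_ij - N_ji)^2 / (N_ij + N_ji),
#' taken over pairs with N_ij + N_ji > 0; df is the number of such pairs.
#'
#' @param row_a,row_b equal-length character vectors or strings.
#' @param states state alphabet; characters outside it (gaps, N) are
#'   skipped.
#' @return a \code{test_result}; a comparison with no off-diagonal pairs
#'   returns statistic 0, df 0, p 1 with \code{degenerate = TRUE}.
#' @export
matched_pairs_symmetry <- function(row_a, row_b, states = DNA_STATES) {
  if (is.character(row_a) && length(row_a) == 1L) row_a <- strsplit(row_a, "")[[1L]]
  if (is.character(row_b) && length(row_b) == 1L) row_b <- strsplit(row_b, "")[[1L]]
  if (length(row_a) != length(row_b)) stop("rows differ in length")
  keep <- row_a %in% states & row_b %in% states
  a <- factor(row_a[keep], levels = states)
  b <- factor(row_b[keep], levels = states)
  N <- table(a, b)
  stat <- 0
  df <- 0L
  cells <- list()
  for (i in seq_along(states)[-length(states)]) {
    for (j in (i + 1L):length(states)) {
      tot <- N[i, j] + N[j, i]
      if (tot > 0) {
        stat <- stat + (N[i, j] - N[j, i])^2 / tot
        df <- df + 1L
        cells[[length(cells) + 1L]] <-
          data.frame(pair = paste0(states[i], states[j]),
                     n_ij = N[i, j], n_ji = N[j, i])
      }
    }
  }
  if (df == 0L)
    return(new_test_result(0, 0L, 1, degenerate = TRUE))
  new_test_result(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
                  do.call(rbind, cells))
}

#' Fraction of significantly asymmetric sequence pairs in an alignment
#'
#' Applies [matched_pairs_symmetry()] to all unordered taxon pairs and
#' reports the fraction with p below the threshold. Degenerate pairs (no
#' off-diagonal counts) are counted as non-significant and flagged.
#'
#' @param al a [mito_alignment()].
#' @param alpha significance threshold (default 0.05).
#' @param positions optional codon positions (subset of 1:3) to restrict the
#'   columns to, assuming an in-frame codon alignment.
#' @return list with \code{fraction_significant}, \code{n_pairs} and a
#'   per-pair data frame \code{pairs} (taxa, statistic, df, p, degenerate).
#' @export
pairwise_symmetry_summary <- function(al, alpha = 0.05, positions = NULL) {
  if (!is.null(positions)) al <- codon_position_columns(al, positions)
  taxa <- rownames(al)
  if (length(taxa) < 2L) stop("need >= 2 taxa")
  states <- attr(al, "states")
  m <- unclass(al)
  rows <- list()
  for (i in seq_along(taxa)[-length(taxa)]) {
    for (j in (i + 1L):length(taxa)) {
      r <- matched_pairs_symmetry(m[i, ], m[j, ], states = states)
      rows[[length(rows) + 1L]] <-
        data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                   statistic = r$statistic, df = r$df, p_value = r$p_value,
                   degenerate = r$degenerate)
    }
  }
  pairs <- do.call(rbind, rows)
  sig <- pairs$p_value < alpha & !pairs$degenerate
  list(fraction_significant = mean(sig), n_pairs = nrow(pairs), pairs = pairs)
}

#' Compositional deviation of each taxon
#'
#' For each taxon, the sum over the alphabet of the absolute difference
#' between the taxon-specific and the global (pooled) empirical state
#' frequencies, computed on non-gap characters. Bounded above by 2.
#'
#' @param al a [mito_alignment()].
#' @return named numeric vector of per-taxon deviations.
#' @export
taxon_deviation <- function(al) {
  cm <- count_matrix(al)
  f_global <- colSums(cm) / sum(cm)
  f_taxon <- cm / rowSums(cm)
  rowSums(abs(sweep(f_taxon, 2L, f_global)))
}

#' Global compositional deviation of an alignment
#'
#' The maximum of [taxon_deviation()] across taxa.
#'
#' @param al a [mito_alignment()].
#' @return scalar deviation.
#' @export
global_deviation <- function(al) {
  max(taxon_deviation(al))
}

#' Posterior-predictive-style test of compositional homogeneity
#'
#' Compares the observed per-taxon and global deviation statistics with
#' their distribution over alignments simulated under a homogeneous
#' reference model (e.g. the stationary simulator on a fixed tree, standing
#' in for model-posterior draws). Z scores are (observed - replicate mean) /
#' replicate sd; one-sided p-values are the smoothed fraction
#' (r + 1) / (n + 1) of replicates at or above the observed value.
#'
#' @param al observed [mito_alignment()].
#' @param replicate_source function of one argument (the replicate index)
#'   returning a simulated [mito_alignment()] over the same taxa, or a list
#'   of such alignments.
#' @param n_reps number of replicates (>= 20; fewer give an unstable sd).
#' @param alpha flagging threshold for the per-taxon p-values.
#' @return a \code{deviation_report}: list with \code{per_taxon} data frame
#'   (observed, replicate mean/sd, z_score, p_value, deviating, degenerate),
#'   \code{global_z}, \code{global_p}, \code{n_deviating}, \code{n_reps},
#'   \code{alpha}.
#' @export
posterior_predictive <- function(al, replicate_source, n_reps = 100L,
                                 alpha = 0.05) {
  if (is.list(replicate_source) && !is.function(replicate_source)) {
    reps_list <- replicate_source
    n_reps <- length(reps_list)
    replicate_source <- function(i) reps_list[[i]]
  }
  if (n_reps < 20L) stop("n_reps < 20 gives an unstable replicate sd; refuse")
  obs <- taxon_deviation(al)
  taxa <- names(obs)
  rep_stats <- matrix(NA_real_, n_reps, length(taxa),
                      dimnames = list(NULL, taxa))
  rep_global <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- replicate_source(r)
    d <- taxon_deviation(sim)
    if (!all(taxa %in% names(d)))
      stop("replicate ", r, " is missing taxa: ",
           paste(setdiff(taxa, names(d)), collapse = ", "))
    rep_stats[r, ] <- d[taxa]
    rep_global[r] <- max(d)
  }
  mu <- colMeans(rep_stats)
  sd_ <- apply(rep_stats, 2L, stats::sd)
  degenerate <- sd_ == 0
  z <- ifelse(degenerate, NA_real_, (obs - mu) / sd_)
  p <- (colSums(rep_stats >= rep(obs, each = n_reps)) + 1) / (n_reps + 1)
  deviating <- !degenerate & p < alpha
  g_obs <- max(obs)
  g_sd <- stats::sd(rep_global)
  structure(list(
    per_taxon = data.frame(taxon = taxa, observed = obs, rep_mean = mu,
                           rep_sd = sd_, z_score = z, p_value = p,
                           deviating = deviating, degenerate = degenerate,
                           row.names = NULL),
    global_z = if (g_sd > 0) (g_obs - mean(rep_global)) / g_sd else NA_real_,
    global_p = (sum(rep_global >= g_obs) + 1) / (n_reps + 1),
    n_deviating = sum(deviating), n_reps = n_reps, alpha = alpha),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %d taxa, %d replicates: global Z = %.3f (p = %.3g), %d taxa deviating at alpha = %g\n",
              nrow(x$per_taxon), x$n_reps, x$global_z, x$global_p,
              x$n_deviating, x$alpha))
  invisible(x)
}
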