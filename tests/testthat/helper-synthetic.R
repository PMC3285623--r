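# Shared fixtures and independent oracles, all built in code.

# Write a minimal GenBank flat file; feats is a list of lists with
# key, loc and optional quals (character vector of qualifier lines).
synth_genbank <- function(seq, feats, path = tempfile(fileext = ".gb"),
                          circular = TRUE, accession = "SYN0001",
                          taxon = "Testus syntheticus") {
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     %s INV 01-JAN-2000",
            accession, n, if (circular) "circular" else "linear"),
    "DEFINITION  synthetic record.",
    paste0("ACCESSION   ", accession),
    paste0("  ORGANISM  ", taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n))
  for (f in feats) {
    lines <- c(lines, sprintf("     %-15s %s", f$key, f$loc))
    for (q in f$quals %||% character())
      lines <- c(lines, paste0("                     ", q))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, n, by = 60)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59, n))
    tens <- seq(1, nchar(chunk), by = 10)
    lines <- c(lines, sprintf("%9d %s", s,
      paste(substring(chunk, tens, pmin(tens + 9, nchar(chunk))), collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_signed_order <- function(n, taxon = "", circular = TRUE) {
  gene_order(sample(as.character(seq_len(n))),
             sample(c(-1L, 1L), n, TRUE), taxon = taxon, circular = circular)
}

# Brute-force breakpoint distance: for every consecutive pair of the first
# order, look for it in the second by explicit double loop, comparing both
# reading directions.
oracle_breakpoint <- function(a, b) {
  pairs_of <- function(o) {
    n <- length(o$tokens)
    st <- paste0(ifelse(o$signs < 0, "-", "+"), o$tokens)
    idx <- if (o$circular) cbind(1:n, c(2:n, 1)) else cbind(1:(n - 1), 2:n)
    cbind(st[idx[, 1]], st[idx[, 2]])
  }
  neg <- function(x) ifelse(substr(x, 1, 1) == "-",
                            paste0("+", substring(x, 2)),
                            paste0("-", substring(x, 2)))
  pa <- pairs_of(a)
  pb <- pairs_of(b)
  missing <- 0L
  for (i in seq_len(nrow(pa))) {
    found <- FALSE
    for (j in seq_len(nrow(pb))) {
      if ((pa[i, 1] == pb[j, 1] && pa[i, 2] == pb[j, 2]) ||
          (pa[i, 1] == neg(pb[j, 2]) && pa[i, 2] == neg(pb[j, 1]))) {
        found <- TRUE
        break
      }
    }
    if (!found) missing <- missing + 1L
  }
  missing
}

rotate_order <- function(o, k) {
  n <- length(o$tokens)
  k <- k %% n
  if (k == 0) return(o)
  idx <- c((k + 1):n, seq_len(k))
  gene_order(o$tokens[idx], o$signs[idx], taxon = o$taxon, circular = o$circular)
}

reverse_order <- function(o) {
  gene_order(rev(o$tokens), -rev(o$signs), taxon = o$taxon, circular = o$circular)
}

# Brute-force single-column likelihood by explicit summation over all
# ancestral state assignments; transition matrices via Matrix::expm, so the
# oracle shares no code path with the pruning implementation.
oracle_site_lik <- function(col, tree, model, rate) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  k <- length(model$states)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(model$Q * tree$edge.length[e] * rate)))
  obs <- match(col[tree$tip.label], model$states)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- grid[g, ]
    prob <- model$freqs[asg[1L]]  # root is node ntip + 1, first internal
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      sp <- asg[par - ntip]
      if (ch <= ntip) {
        if (is.na(obs[ch])) next  # missing tip: sums to 1 over states
        prob <- prob * P[[e]][sp, obs[ch]]
      } else {
        prob <- prob * P[[e]][sp, asg[ch - ntip]]
      }
      if (prob == 0) break
    }
    total <- total + prob
  }
  total
}

# All set partitions of `states` into exactly k non-empty blocks
# (restricted-growth enumeration).
all_partitions_k <- function(states, k) {
  n <- length(states)
  out <- list()
  recur <- function(i, asg, used) {
    if (i > n) {
      if (used == k) {
        groups <- split(states, asg)
        out[[length(out) + 1L]] <<- unname(groups)
      }
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k))) {
      asg[i] <- g
      recur(i + 1L, asg, max(used, g))
    }
  }
  recur(1L, integer(n), 0L)
  out
}

# Shift a composition by a given total-variation distance: mass tv moves
# onto the first state, taken proportionally from the others.
shift_composition <- function(freqs, tv) {
  p <- freqs
  p[-1] <- p[-1] * (1 - tv / sum(p[-1]))
  p[1] <- p[1] + tv
  p / sum(p)
}

random_alignment <- function(taxa, L, states = c("A", "C", "G", "T"),
                             alphabet = "DNA4", gap_frac = 0) {
  m <- matrix(sample(states, length(taxa) * L, TRUE), length(taxa), L,
              dimnames = list(taxa, NULL))
  if (gap_frac > 0) m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  mito_alignment(m, alphabet = alphabet)
}
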