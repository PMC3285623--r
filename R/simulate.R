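with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Randomly rearrange a gene order, logging the operations
#'
#' Applies \code{n_ops} random segment inversions and/or transpositions to
#' a gene order. Segments never span the full circle (an operation touches
#' at most \code{n - 1} genes), inversions flip segment signs, and the
#' returned log replays deterministically from the seed. Each operation
#' breaks at most 3 adjacencies, so the breakpoint distance to the source
#' is at most \code{3 * n_ops}.
#'
#' @param order a [gene_order()].
#' @param n_ops number of operations (>= 0).
#' @param op_mix probabilities of \code{c(inversion, transposition)}.
#' @param seed RNG seed.
#' @return a \code{scramble_log}: list with \code{seed}, \code{ops} (each a
#'   list with \code{type}, \code{start}, \code{len}, \code{dest}),
#'   \code{source} and \code{result} gene orders.
#' @export
scramble_gene_order <- function(order, n_ops, op_mix = c(0.5, 0.5),
                                seed = 1L) {
  stopifnot(n_ops >= 0)
  n <- length(order$tokens)
  ops <- vector("list", n_ops)
  cur <- order
  with_seed(seed, {
    for (i in seq_len(n_ops)) {
      type <- sample(c("inversion", "transposition"), 1L, prob = op_mix)
      len <- sample.int(max(n - 1L, 1L), 1L)
      start <- sample.int(n, 1L)
      dest <- if (type == "transposition") sample.int(n - len, 1L) else NA_integer_
      ops[[i]] <- list(type = type, start = start, len = len, dest = dest)
      cur <- apply_rearrangement(cur, ops[[i]])
    }
  })
  structure(list(seed = seed, ops = ops, source = order, result = cur),
            class = "scramble_log")
}

#' @export
print.scramble_log <- function(x, ...) {
  cat(sprintf("<scramble_log> %d operation(s), seed %d\n",
              length(x$ops), x$seed))
  invisible(x)
}

#' Replay a scramble log
#' @param log a \code{scramble_log}.
#' @return the resulting [gene_order()]; identical to \code{log$result}.
#' @export
replay_scramble <- function(log) {
  cur <- log$source
  for (op in log$ops) cur <- apply_rearrangement(cur, op)
  cur
}

apply_rearrangement <- function(order, op) {
  n <- length(order$tokens)
  idx <- ((op$start - 1L + seq_len(op$len) - 1L) %% n) + 1L
  toks <- order$tokens
  sgns <- order$signs
  if (op$type == "inversion") {
    toks[idx] <- rev(toks[idx])
    sgns[idx] <- -rev(sgns[idx])
  } else {
    seg_t <- toks[idx]
    seg_s <- sgns[idx]
    rest_t <- toks[-idx]
    rest_s <- sgns[-idx]
    at <- op$dest
    toks <- append(rest_t, seg_t, after = at)
    sgns <- append(rest_s, seg_s, after = at)
  }
  gene_order(toks, sgns, taxon = order$taxon, circular = order$circular)
}

#' Simulation configuration for tree-structured sequence evolution
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths.
#' @param states state alphabet (default DNA).
#' @param root_freqs composition at the root (simplex; default uniform).
#' @param exch symmetric exchangeability matrix or scalar (see
#'   [substitution_model()]).
#' @param shifts optional list of composition breakpoints, each a list with
#'   \code{node} (the child node of the branch: a tip label or node
#'   number), \code{position} (fraction along the branch from its parent)
#'   and \code{freqs} (the new composition, inherited by the whole
#'   descendant subtree). Multiple breakpoints on one branch are applied in
#'   position order.
#' @param n_sites number of sites.
#' @param gamma_shape optional gamma shape for continuous per-site rates.
#' @param rates optional explicit per-site rates (overrides
#'   \code{gamma_shape}).
#' @param seed RNG seed.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(tree, states = DNA_STATES, root_freqs = NULL,
                              exch = 1, shifts = NULL, n_sites = 1000L,
                              gamma_shape = NULL, rates = NULL, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (is.null(root_freqs)) root_freqs <- rep(1 / length(states), length(states))
  check_simplex(root_freqs, length(states))
  for (s in shifts) check_simplex(s$freqs, length(states))
  structure(list(tree = tree, states = states, root_freqs = root_freqs,
                 exch = exch, shifts = shifts, n_sites = as.integer(n_sites),
                 gamma_shape = gamma_shape, rates = rates, seed = seed),
            class = "simulation_config")
}

check_simplex <- function(p, k) {
  if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("composition must be a ", k, "-state simplex point")
  invisible(TRUE)
}

#' Simulate an alignment on a tree
#'
#' Root states are drawn from the root composition; along each branch sites
#' evolve under a reversible rate matrix rebuilt from the exchangeabilities
#' and the currently active composition (normalized to mean rate 1), with
#' exact matrix-exponential transition probabilities per branch segment.
#' Composition breakpoints switch the active composition part-way along a
#' branch; with an empty breakpoint list the process is stationary. Per-site
#' rates (all 1, drawn from a gamma, or supplied) multiply branch lengths
#' and are returned as the simulation truth.
#'
#' @param cfg a [simulation_config()].
#' @return list with \code{alignment} (a [mito_alignment()] over the tips)
#'   and \code{rates} (true per-site rates).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  tree <- stats::reorder(cfg$tree, "cladewise")
  states <- cfg$states
  k <- length(states)
  n <- cfg$n_sites
  ntip <- length(tree$tip.label)
  models <- new.env(parent = emptyenv())
  get_model <- function(freqs) {
    key <- paste(signif(freqs, 12), collapse = ",")
    if (is.null(models[[key]]))
      models[[key]] <- substitution_model(states, cfg$exch, freqs)
    models[[key]]
  }
  shift_node <- function(x) {
    if (is.character(x)) match(x, tree$tip.label) else as.integer(x)
  }
  shifts_by_child <- list()
  for (s in cfg$shifts) {
    ch <- as.character(shift_node(s$node))
    shifts_by_child[[ch]] <- append(shifts_by_child[[ch]], list(s))
  }
  with_seed(cfg$seed, {
    rates <- if (!is.null(cfg$rates)) {
      stopifnot(length(cfg$rates) == n)
      cfg$rates
    } else if (!is.null(cfg$gamma_shape)) {
      stats::rgamma(n, shape = cfg$gamma_shape, rate = cfg$gamma_shape)
    } else rep(1, n)
    node_states <- matrix(NA_integer_, ntip + tree$Nnode, n)
    node_freqs <- vector("list", ntip + tree$Nnode)
    root <- ntip + 1L
    node_states[root, ] <- sample.int(k, n, replace = TRUE,
                                      prob = cfg$root_freqs)
    node_freqs[[root]] <- cfg$root_freqs
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      t_e <- tree$edge.length[e]
      sh <- shifts_by_child[[as.character(child)]]
      segs <- branch_segments(node_freqs[[parent]], t_e, sh)
      node_states[child, ] <-
        propagate_states(node_states[parent, ], rates, segs, get_model, k)
      node_freqs[[child]] <- segs$freqs[[length(segs$freqs)]]
    }
    m <- matrix(states[node_states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip, dimnames = list(tree$tip.label, NULL))
    list(alignment = mito_alignment(m, alphabet = alphabet_for(states)),
         rates = rates)
  })
}

alphabet_for <- function(states) {
  if (identical(states, DNA_STATES)) return("DNA4")
  if (identical(states, AA_STATES)) return("AA20")
  states
}

branch_segments <- function(freqs0, t_e, shifts) {
  if (is.null(shifts) || !length(shifts))
    return(list(lens = t_e, freqs = list(freqs0)))
  pos <- vapply(shifts, function(s) s$position, numeric(1))
  o <- order(pos)
  pos <- pos[o]
  fr <- lapply(shifts[o], function(s) s$freqs)
  bounds <- c(0, pos, 1)
  list(lens = diff(bounds) * t_e, freqs = c(list(freqs0), fr))
}

# Vectorized propagation of parent states to child states across one branch
# made of piecewise-homogeneous segments; per-site rates scale all segment
# lengths. Uses the eigendecomposition rows, so cost is O(sites x states^2).
propagate_states <- function(parent_states, rates, segs, get_model, k) {
  n <- length(parent_states)
  V <- NULL
  for (i in seq_along(segs$lens)) {
    mod <- get_model(segs$freqs[[i]])
    t_seg <- segs$lens[i]
    E <- exp(outer(rates * t_seg, mod$eigen$lambda))
    A <- if (is.null(V)) mod$eigen$U1[parent_states, , drop = FALSE]
         else V %*% mod$eigen$U1
    V <- (A * E) %*% mod$eigen$U2
  }
  V[V < 0] <- 0
  tot <- rowSums(V)
  u <- stats::runif(n) * tot
  cs <- V
  for (j in seq_len(k)[-1L]) cs[, j] <- cs[, j - 1L] + V[, j]
  child <- 1L + rowSums(cs < u)
  pmin(as.integer(child), k)
}

#' Simulate a codon stream with prescribed usage
#'
#' Independent draws of codons from target usage fractions. By default
#' termination codons get zero mass, so the stream contains no in-frame
#' stops.
#'
#' @param usage a \code{codon_usage_table} (its counts define the target),
#'   or a named numeric vector of fractions over codons.
#' @param n_codons number of codons to draw (>= 1).
#' @param seed RNG seed.
#' @param allow_stops keep termination codons' mass?
#' @param code NCBI translation table id (identifies the stops).
#' @return character vector of codons.
#' @export
simulate_cds <- function(usage, n_codons, seed = 1L, allow_stops = FALSE,
                         code = "5") {
  if (inherits(usage, "codon_usage_table")) usage <- usage$counts
  if (is.null(names(usage))) stop("usage must be named by codon")
  if (!allow_stops) {
    gc <- genetic_code(code)
    usage[names(usage) %in% names(gc)[gc == "*"]] <- 0
  }
  if (sum(usage) <= 0) stop("zero-mass codon usage")
  if (n_codons < 1L) stop("n_codons must be >= 1")
  with_seed(seed, {
    sample(names(usage), n_codons, replace = TRUE, prob = usage)
  })
}
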