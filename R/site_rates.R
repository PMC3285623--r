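#' Construct a reversible substitution model with discrete-gamma rates
#'
#' Builds a general time-reversible rate matrix from a symmetric
#' exchangeability matrix and stationary frequencies, normalized to one
#' expected substitution per unit branch length, with among-site rate
#' variation modelled by \code{ncat} equiprobable discrete-gamma categories
#' whose rates are the category means (so the weighted mean rate is exactly
#' 1).
#'
#' @param states state alphabet (default DNA).
#' @param exch symmetric exchangeability matrix (diagonal ignored), or a
#'   single number for equal exchangeabilities (Jukes-Cantor-like). For DNA
#'   a length-6 vector gives the GTR rates in the order AC, AG, AT, CG, CT,
#'   GT.
#' @param freqs stationary frequencies (default uniform).
#' @param alpha gamma shape; \code{NULL} means no rate variation.
#' @param ncat number of gamma categories (default 8); forced to 1 when
#'   \code{alpha} is \code{NULL}.
#' @return object of class \code{substitution_model}: list with
#'   \code{states}, \code{freqs}, \code{Q}, an eigendecomposition for fast
#'   transition matrices, \code{alpha}, \code{cat_rates}, \code{cat_weights}.
#' @export
substitution_model <- function(states = DNA_STATES, exch = 1, freqs = NULL,
                               alpha = NULL, ncat = 8L) {
  n <- length(states)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  freqs <- freqs / sum(freqs)
  if (length(freqs) != n || any(freqs <= 0))
    stop("freqs must be ", n, " positive values")
  if (length(exch) == 1L) {
    exch <- matrix(exch, n, n)
  } else if (!is.matrix(exch) && n == 4L && length(exch) == 6L) {
    m <- matrix(0, 4, 4, dimnames = list(states, states))
    m["C", "A"] <- exch[1]; m["G", "A"] <- exch[2]; m["T", "A"] <- exch[3]
    m["G", "C"] <- exch[4]; m["T", "C"] <- exch[5]; m["T", "G"] <- exch[6]
    exch <- m + t(m)
  }
  if (!isTRUE(all.equal(exch, t(exch)))) stop("exchangeability matrix must be symmetric")
  Q <- exch %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix")
  Q <- Q / scale
  dimnames(Q) <- list(states, states)
  # symmetrized eigendecomposition for reversible Q
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  eig <- list(U1 = diag(1 / sq) %*% e$vectors,
              U2 = t(e$vectors) %*% diag(sq),
              lambda = e$values)
  if (is.null(alpha)) {
    ncat <- 1L
    cat_rates <- 1
  } else {
    cat_rates <- discrete_gamma_rates(alpha, ncat)
  }
  structure(list(states = states, freqs = freqs, exch = exch, Q = Q,
                 eigen = eig, alpha = alpha, ncat = as.integer(ncat),
                 cat_rates = cat_rates,
                 cat_weights = rep(1 / ncat, ncat)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("<substitution_model> %d states, alpha = %s, %d gamma categories\n",
              length(x$states),
              if (is.null(x$alpha)) "none" else format(x$alpha), x$ncat))
  invisible(x)
}

#' Mean rates of equiprobable discrete-gamma categories
#'
#' Category boundaries are the G-quantiles of a gamma(shape, rate = shape)
#' distribution; each category's rate is its conditional mean, so the
#' weighted mean over categories is exactly 1.
#'
#' @param alpha gamma shape.
#' @param ncat number of categories.
#' @return numeric vector of category rates.
#' @export
discrete_gamma_rates <- function(alpha, ncat) {
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha,
                     rate = alpha)
  ncat * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
}

transition_matrix <- function(model, t) {
  if (t < 0) stop("negative branch length")
  model$eigen$U1 %*% (exp(model$eigen$lambda * t) * model$eigen$U2)
}

#' Per-site per-category likelihoods on a fixed tree
#'
#' Felsenstein pruning over the tree for each discrete-gamma category,
#' log-space stable via per-node rescaling. Gaps and characters outside the
#' model alphabet contribute a flat likelihood vector (missing data).
#'
#' @param al a [mito_alignment()].
#' @param tree an \code{ape} \code{phylo} tree whose tip labels all occur in
#'   the alignment; branch lengths in expected substitutions per site.
#' @param model a [substitution_model()] over the alignment alphabet.
#' @return object of class \code{site_rate_profile}: list with
#'   \code{loglik} (sites x categories matrix of log-likelihoods),
#'   \code{cat_rates}, \code{cat_weights}, \code{all_gap} (logical per
#'   site), \code{n_sites}.
#' @export
site_likelihoods <- function(al, tree, model) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  miss <- setdiff(tree$tip.label, rownames(al))
  if (length(miss))
    stop("tree tips missing from alignment: ", paste(miss, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  states <- model$states
  L <- ncol(al)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  m <- unclass(al)[tr$tip.label, , drop = FALSE]
  # tip conditional likelihoods: indicator, or flat for gap/N/unknown
  tipcl <- lapply(seq_len(ntip), function(i) {
    x <- matrix(0, length(states), L)
    obs <- match(m[i, ], states)
    known <- !is.na(obs)
    x[cbind(obs[known], which(known))] <- 1
    x[, !known] <- 1
    x
  })
  all_gap <- colSums(matrix(m %in% states, nrow(m))) == 0
  G <- model$ncat
  loglik <- matrix(NA_real_, L, G)
  root <- ntip + 1L
  for (g in seq_len(G)) {
    r <- model$cat_rates[g]
    partial <- vector("list", nnode)
    logscale <- numeric(L)
    for (k in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[k, 1L]
      child <- tr$edge[k, 2L]
      P <- transition_matrix(model, tr$edge.length[k] * r)
      cl <- if (child <= ntip) tipcl[[child]] else partial[[child]]
      contrib <- P %*% cl
      if (is.null(partial[[parent]])) {
        partial[[parent]] <- contrib
      } else {
        partial[[parent]] <- partial[[parent]] * contrib
      }
      mx <- apply(partial[[parent]], 2L, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(partial[[parent]], 2L, mx, "/")
      logscale <- logscale + log(mx)
    }
    loglik[, g] <- log(colSums(model$freqs * partial[[root]])) + logscale
  }
  structure(list(loglik = loglik, cat_rates = model$cat_rates,
                 cat_weights = model$cat_weights, all_gap = all_gap,
                 n_sites = L),
            class = "site_rate_profile")
}

#' @export
print.site_rate_profile <- function(x, ...) {
  cat(sprintf("<site_rate_profile> %d sites, %d gamma categories\n",
              x$n_sites, length(x$cat_rates)))
  invisible(x)
}

#' Total log-likelihood of an alignment from a site-rate profile
#' @param profile a \code{site_rate_profile}.
#' @return scalar log-likelihood (sites summed, categories averaged with
#'   their weights).
#' @export
alignment_loglik <- function(profile) {
  mx <- apply(profile$loglik, 1L, max)
  sum(mx + log(rowSums(exp(profile$loglik - mx) *
                         rep(profile$cat_weights, each = profile$n_sites))))
}

#' Sitewise evolutionary rates
#'
#' Posterior-mean rate per site under the discrete-gamma model:
#' \eqn{\hat r_s = \sum_g r_g w_g L_{s,g} / \sum_g w_g L_{s,g}}, or the rate
#' of the maximum-posterior category in \code{"ml_category"} mode. All-gap
#' columns get \code{NA} (undefined; [remove_fast_sites()] treats them as
#' slowest).
#'
#' @param profile a \code{site_rate_profile} from [site_likelihoods()].
#' @param mode \code{"posterior_mean"} (default) or \code{"ml_category"}.
#' @return numeric vector of per-site rates.
#' @export
posterior_mean_rates <- function(profile, mode = c("posterior_mean",
                                                   "ml_category")) {
  mode <- match.arg(mode)
  ll <- profile$loglik
  w <- rep(profile$cat_weights, each = nrow(ll))
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx) * w
  post <- post / rowSums(post)
  rates <- if (mode == "posterior_mean") {
    as.vector(post %*% profile$cat_rates)
  } else {
    profile$cat_rates[max.col(post, ties.method = "first")]
  }
  rates[profile$all_gap] <- NA_real_
  rates
}

#' Remove the fastest-evolving fraction of sites
#'
#' Removes the \code{round(q * L)} highest-rate columns; among tied rates
#' the leftmost columns are kept. Undefined (\code{NA}) rates sort as
#' slowest. Survivor columns keep their original order.
#'
#' @param al a [mito_alignment()].
#' @param rates one rate per column (e.g. from [posterior_mean_rates()]).
#' @param q fraction to remove, in \code{[0, 1)}.
#' @return list with \code{alignment} (reduced) and \code{removed} (sorted
#'   indices of removed columns).
#' @export
remove_fast_sites <- function(al, rates, q) {
  L <- ncol(al)
  if (length(rates) != L) stop("need one rate per column")
  if (!is.numeric(q) || q < 0 || q >= 1) stop("q must be in [0, 1)")
  m <- round(q * L)
  if (m == 0) return(list(alignment = al, removed = integer()))
  r <- ifelse(is.na(rates), -Inf, rates)
  ord <- order(r, seq_along(r), decreasing = TRUE)
  removed <- sort(ord[seq_len(m)])
  list(alignment = sub_alignment(al, setdiff(seq_len(L), removed)),
       removed = removed)
}

#' Estimate the gamma shape on a fixed tree
#'
#' One-dimensional likelihood maximization of the discrete-gamma shape with
#' all other model parameters held fixed; a deliberately simple direct
#' search, since trees and substitution parameters are inputs here.
#'
#' @param al alignment; @param tree phylo; @param model substitution model
#'   (its \code{alpha} is ignored); @param interval search interval;
#'   @param ncat categories.
#' @return list with \code{alpha} and \code{loglik}.
#' @export
estimate_gamma_shape <- function(al, tree, model, interval = c(0.05, 20),
                                 ncat = 8L) {
  f <- function(a) {
    m2 <- substitution_model(model$states, model$exch, model$freqs,
                             alpha = a, ncat = ncat)
    -alignment_loglik(site_likelihoods(al, tree, m2))
  }
  opt <- stats::optimize(f, interval)
  list(alpha = opt$minimum, loglik = -opt$objective)
}

#' Read an empirical amino-acid exchangeability matrix (PAML format)
#'
#' Lower-triangle rows of the 20 x 20 exchangeability matrix followed
#' (optionally) by 20 stationary frequencies, whitespace-separated, in the
#' standard PAML amino-acid order ARNDCQEGHILKMFPSTWYV.
#'
#' @param path matrix file.
#' @return list with \code{exch} (symmetric 20 x 20 matrix) and
#'   \code{freqs} (or \code{NULL} if absent).
#' @export
read_exchangeability <- function(path) {
  nums <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(nums) < 190) stop("expected at least 190 exchangeability values")
  m <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  idx <- 1L
  for (i in 2:20) for (j in 1:(i - 1)) {
    m[i, j] <- m[j, i] <- nums[idx]
    idx <- idx + 1L
  }
  freqs <- NULL
  if (length(nums) >= 210) {
    freqs <- nums[191:210]
    names(freqs) <- AA_STATES
    freqs <- freqs / sum(freqs)
  }
  list(exch = m, freqs = freqs)
}
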