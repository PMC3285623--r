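signed_token <- function(tokens, signs) {
  paste0(ifelse(signs < 0L, "-", "+"), tokens)
}

negate_signed <- function(x) {
  ifelse(substr(x, 1L, 1L) == "-", paste0("+", substring(x, 2L)),
         paste0("-", substring(x, 2L)))
}

canonical_adjacency <- function(x, y) {
  a <- paste(x, y, sep = "\r")
  b <- paste(negate_signed(y), negate_signed(x), sep = "\r")
  ifelse(a <= b, a, b)
}

#' Oriented adjacency set of a gene order
#'
#' Consecutive signed gene pairs (including last-to-first for circular
#' orders), canonicalized under the reading-direction identification
#' (x, y) == (-y, -x), so that an order and its full reversal with flipped
#' signs yield the same set.
#'
#' @param order a [gene_order()].
#' @return character vector of canonical adjacency keys, with
#'   \code{circular} attribute; \code{n} adjacencies for a circular order of
#'   \code{n} genes, \code{n - 1} for a linear one.
#' @export
adjacency_set <- function(order) {
  if (anyDuplicated(order$tokens))
    stop("duplicate tokens in gene order")
  st <- signed_token(order$tokens, order$signs)
  n <- length(st)
  if (n < 2L) return(structure(character(), circular = order$circular))
  i <- if (order$circular) seq_len(n) else seq_len(n - 1L)
  j <- if (order$circular) c(seq_len(n)[-1L], 1L) else seq_len(n)[-1L]
  structure(canonical_adjacency(st[i], st[j]), circular = order$circular)
}

check_same_tokens <- function(a, b) {
  d1 <- setdiff(a$tokens, b$tokens)
  d2 <- setdiff(b$tokens, a$tokens)
  if (length(d1) || length(d2))
    stop("gene orders have different token sets; only in first: {",
         paste(d1, collapse = ", "), "}, only in second: {",
         paste(d2, collapse = ", "), "}")
}

#' Breakpoint distance between two gene orders
#'
#' Number of gene adjacencies of one order that are absent from the other,
#' on circular signed orders with identical token sets. Invariant under
#' rotation of either circular order and under global reversal with sign
#' flip.
#'
#' @param a,b [gene_order()] objects over the same tokens.
#' @return integer distance.
#' @export
breakpoint_distance <- function(a, b) {
  check_same_tokens(a, b)
  if (a$circular != b$circular) stop("cannot compare circular with linear order")
  aa <- adjacency_set(a)
  bb <- adjacency_set(b)
  length(aa) - length(intersect(aa, bb))
}

#' Pairwise breakpoint distance matrix
#'
#' @param orders list of [gene_order()]s with identical token sets.
#' @return symmetric integer matrix with zero diagonal, labelled by taxa.
#' @export
breakpoint_matrix <- function(orders) {
  if (length(orders) < 2L) stop("need at least two gene orders")
  taxa <- vapply(orders, function(o) o$taxon, character(1))
  if (any(!nzchar(taxa))) taxa[!nzchar(taxa)] <- paste0("order", which(!nzchar(taxa)))
  n <- length(orders)
  m <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  adj <- lapply(orders, adjacency_set)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    check_same_tokens(orders[[i]], orders[[j]])
    d <- length(adj[[i]]) - length(intersect(adj[[i]], adj[[j]]))
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Maximal conserved gene blocks shared by two orders
#'
#' Runs of consecutive genes that appear with identical relative order and
#' orientation (or fully reversed with flipped signs) in both orders,
#' reported in the coordinates of the first order.
#'
#' @param a,b [gene_order()]s over the same tokens.
#' @param min_len minimum run length, >= 2.
#' @return list of character vectors of signed tokens (as written in
#'   \code{a}); a single full-length block if the orders are equal.
#' @export
shared_blocks <- function(a, b, min_len = 2L) {
  check_same_tokens(a, b)
  if (min_len < 2L) stop("min_len must be >= 2")
  st <- signed_token(a$tokens, a$signs)
  n <- length(st)
  bb <- adjacency_set(b)
  # s[i]: adjacency between position i and its successor is shared with b
  if (a$circular) {
    s <- canonical_adjacency(st, st[c(2:n, 1L)]) %in% bb
    if (all(s)) return(list(st))
    # rotate so position 1 follows a broken adjacency; runs then never wrap
    f <- which(!s)[1L]
    idx <- c(seq_len(n)[-seq_len(f)], seq_len(f))
    sh <- s[idx][seq_len(n - 1L)]
  } else {
    if (n < 2L) return(list())
    idx <- seq_len(n)
    sh <- canonical_adjacency(st[-n], st[-1L]) %in% bb
  }
  blocks <- list()
  r <- rle(sh)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_len - 1L) {
      genes <- idx[pos[k]:(pos[k] + r$lengths[k])]
      blocks[[length(blocks) + 1L]] <- st[genes]
    }
  }
  blocks
}

#' Read gene orders from a plain-text file
#'
#' One line per taxon: taxon label then tab-separated signed tokens, a
#' leading \code{-} marking the opposite strand.
#'
#' @param path input file.
#' @param circular are the orders circular?
#' @return list of [gene_order()]s.
#' @export
read_gene_orders <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1L]]
    if (length(parts) < 2L) stop("malformed gene-order line: '", ln, "'")
    toks <- parts[-1L]
    signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
    gene_order(sub("^-", "", toks), signs, taxon = parts[1L],
               circular = circular)
  })
}

#' Write gene orders to a plain-text file
#' @param orders list of [gene_order()]s.
#' @param path output file.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- vapply(orders, function(o)
    paste(c(o$taxon, ifelse(o$signs < 0, paste0("-", o$tokens), o$tokens)),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
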