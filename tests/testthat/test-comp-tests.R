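test_that("chi-square homogeneity statistic, df and invariances", {
  # proportionally identical rows: statistic 0, p 1
  m <- rbind(a = c(10, 20, 30, 40), b = c(5, 10, 15, 20))
  r <- chi2_homogeneity(m)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand computation: rows (10,0) and (0,10), expected 5 per cell
  r <- chi2_homogeneity(rbind(a = c(10, 0), b = c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1L)
  # 49 taxa x 4 states gives df 144
  set.seed(20)
  m49 <- matrix(rpois(49 * 4, 50), 49, 4,
                dimnames = list(paste0("t", 1:49), c("A", "C", "G", "T")))
  expect_equal(chi2_homogeneity(m49)$df, 144L)
  # invariance under row and column permutation; linear scaling of counts
  r0 <- chi2_homogeneity(m49)
  expect_equal(chi2_homogeneity(m49[sample(49), sample(4)])$statistic,
               r0$statistic)
  expect_equal(chi2_homogeneity(3 * m49)$statistic, 3 * r0$statistic)
  # zero-count state dropped with warning
  m0 <- cbind(m49, X = 0)
  expect_warning(rz <- chi2_homogeneity(m0), "pooled count zero")
  expect_equal(rz$statistic, r0$statistic)
})

test_that("Bowker symmetry test matches the closed form", {
  # symmetric divergence: statistic 0
  r <- matched_pairs_symmetry(c("A", "C", "A", "C"), c("C", "A", "A", "C"))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # N_AB = 5, N_BA = 1: S = 16/6, df 1
  x <- c(rep("A", 5), "C", rep("G", 10))
  y <- c(rep("C", 5), "A", rep("G", 10))
  r <- matched_pairs_symmetry(x, y)
  expect_equal(r$statistic, 16 / 6)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(16 / 6, 1, lower.tail = FALSE))
  # swapping the sequences leaves the statistic unchanged
  r2 <- matched_pairs_symmetry(y, x)
  expect_equal(r2$statistic, r$statistic)
  # no off-diagonal pairs: degenerate
  r3 <- matched_pairs_symmetry("AAAA", "AAAA")
  expect_true(r3$degenerate)
  expect_equal(r3$df, 0L)
  expect_equal(r3$p_value, 1)
  # zero iff divergence matrix symmetric (random checks)
  set.seed(21)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "T"), 60, TRUE)
    r <- matched_pairs_symmetry(a, rev(a))
    # a vs rev(a) need not be symmetric; just check sign of statistic
    expect_gte(r$statistic, 0)
  }
})

test_that("pairwise symmetry summary counts significant fractions", {
  al <- mito_alignment(c(t1 = "ACGTACGT", t2 = "ACGTACGT", t3 = "ACGTACGT"))
  s <- pairwise_symmetry_summary(al)
  expect_equal(s$fraction_significant, 0)
  expect_equal(s$n_pairs, 3L)
  # one strongly asymmetric pair out of three
  n <- 300
  a <- strrep("A", n)
  b <- strrep("C", n)
  al <- mito_alignment(c(t1 = a, t2 = a, t3 = b))
  s <- pairwise_symmetry_summary(al, alpha = 0.05)
  expect_equal(s$n_pairs, 3L)
  expect_equal(sum(s$pairs$p_value < 0.05 & !s$pairs$degenerate), 2L)
  # codon-position restriction selects the right columns
  al2 <- mito_alignment(c(t1 = "AAATTT", t2 = "AAATTT"))
  s3 <- pairwise_symmetry_summary(al2, positions = 3)
  expect_equal(s3$n_pairs, 1L)
})

test_that("taxon deviation sums absolute frequency differences", {
  al <- mito_alignment(c(t1 = "ACGT", t2 = "ACGT"))
  expect_equal(unname(taxon_deviation(al)), c(0, 0))
  expect_equal(global_deviation(al), 0)
  # two-state toy: global (0.5, 0.5), taxa at (0.7, 0.3) and (0.3, 0.7)
  m <- rbind(t1 = c(rep("A", 7), rep("C", 3)),
             t2 = c(rep("A", 3), rep("C", 7)))
  al <- mito_alignment(m)
  expect_equal(unname(taxon_deviation(al)), c(0.4, 0.4))
  expect_equal(global_deviation(al), 0.4)
  # bound: deviation <= 2 on random alignments
  set.seed(22)
  for (i in 1:10) {
    al <- random_alignment(paste0("t", 1:5), 40, gap_frac = 0.2)
    expect_true(all(taxon_deviation(al) <= 2))
  }
  al_gap <- mito_alignment(rbind(t1 = c("A", "C"), t2 = c("-", "-")))
  expect_error(taxon_deviation(al_gap), "no countable")
})

test_that("deviation grows with the magnitude of a composition shift", {
  tree <- ape::read.tree(text = "((a:0.3,b:0.3):0.2,(c:0.3,d:0.3):0.2);")
  base <- c(0.3, 0.25, 0.2, 0.25)
  devs <- vapply(c(0.05, 0.15, 0.3), function(tv) {
    cfg <- simulation_config(tree, root_freqs = base, n_sites = 3000,
                             shifts = list(list(node = "a", position = 0,
                                                freqs = shift_composition(base, tv))),
                             seed = 23)
    sim <- simulate_alignment(cfg)
    taxon_deviation(sim$alignment)[["a"]]
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("posterior predictive flags a planted compositional outlier", {
  tree <- ape::rtree(8, br = function(n) rep(0.4, n))
  base <- c(0.35, 0.2, 0.15, 0.3)
  shifted <- shift_composition(base, 0.3)
  cfg0 <- function(seed, shifts = NULL)
    simulation_config(tree, root_freqs = base, n_sites = 400,
                      shifts = shifts, seed = seed)
  obs <- simulate_alignment(cfg0(900, shifts = list(
    list(node = tree$tip.label[1], position = 0, freqs = shifted))))$alignment
  rep_src <- function(i) simulate_alignment(cfg0(1000 + i))$alignment
  rep_out <- posterior_predictive(obs, rep_src, n_reps = 60, alpha = 0.05)
  pt <- rep_out$per_taxon
  expect_true(pt$deviating[pt$taxon == tree$tip.label[1]])
  expect_gt(pt$z_score[pt$taxon == tree$tip.label[1]], 3)
  expect_gt(rep_out$global_z, 2)
  # degenerate replicates (sd = 0) are flagged, not scored
  const <- mito_alignment(c(t1 = "AACC", t2 = "AACC"))
  rep_const <- function(i) const
  out <- posterior_predictive(const, rep_const, n_reps = 20)
  expect_true(all(out$per_taxon$degenerate))
  expect_true(all(is.na(out$per_taxon$z_score)))
  expect_error(posterior_predictive(const, rep_const, n_reps = 10), "n_reps")
  # a list of replicates is accepted in place of a generator
  out2 <- posterior_predictive(const, rep(list(const), 20))
  expect_equal(out2$n_reps, 20L)
})

test_that("recoding maps residues to groups and conserves counts", {
  fx <- load_fixtures()
  al <- mito_alignment(c(t1 = "ACDE", t2 = "GHKL"), alphabet = "AA20")
  rec <- recode(al, fx$dayhoff)
  # group symbols are each group's first member: AGPST->A, C->C, DENQ->D,
  # FWY->F, HKR->H, ILMV->I
  expect_equal(unname(unclass(rec)[1, ]), c("A", "C", "D", "D"))
  expect_equal(unname(unclass(rec)[2, ]), c("A", "H", "H", "I"))
  expect_equal(attr(rec, "alphabet"), "RECODED-6")
  expect_equal(ncol(rec), ncol(al))
  # identity partition changes nothing but the declared alphabet
  ident <- as.list(attr(al, "states"))
  rec20 <- recode(al, ident)
  expect_equal(unclass(rec20), unclass(al), ignore_attr = TRUE)
  # counts are conserved group-wise
  set.seed(24)
  big <- random_alignment(paste0("t", 1:4), 200, states = attr(al, "states"),
                          alphabet = "AA20", gap_frac = 0.1)
  rec2 <- recode(big, fx$dayhoff)
  cm <- count_matrix(big)
  cmr <- count_matrix(rec2)
  expect_equal(unname(rowSums(cmr)), unname(rowSums(cm)))
  for (g in fx$dayhoff)
    expect_equal(unname(cmr[, sort(g)[1]]), unname(rowSums(cm[, g, drop = FALSE])))
  # gaps preserved; partition strings parse both ways
  expect_equal(sum(unclass(rec2) == "-"), sum(unclass(big) == "-"))
  expect_equal(parse_partition(format_partition(fx$dayhoff)), fx$dayhoff)
  expect_error(recode(mito_alignment(c(t1 = "AC"), alphabet = "DNA4"),
                      list(c("A"))), "missing|cover")
})

test_that("minmax binning equals the exhaustive optimum on small alphabets", {
  set.seed(25)
  states <- LETTERS[1:6]
  cm <- matrix(rpois(5 * 6, 40), 5, 6,
               dimnames = list(paste0("t", 1:5), states))
  cm[1, 1] <- 90  # make one taxon clearly deviant
  for (k in c(2, 3, 4)) {
    exh <- min(vapply(all_partitions_k(states, k), function(p)
      max(mitocomp:::binned_taxon_stats(cm, p)), numeric(1)))
    heur <- find_minmax_bins(cm, k, seed = 1, restarts = 40)
    expect_equal(heur$max_stat, exh, tolerance = 1e-12)
    expect_equal(heur$df, k - 1L)
    expect_equal(heur$min_p,
                 pchisq(heur$max_stat, k - 1, lower.tail = FALSE))
  }
  # k = alphabet size: identity partition, statistics equal unbinned values
  full <- find_minmax_bins(cm, 6, seed = 1, restarts = 5)
  expect_equal(lengths(full$groups), rep(1L, 6))
  expect_equal(full$max_stat,
               max(mitocomp:::binned_taxon_stats(cm, as.list(states))))
  expect_error(find_minmax_bins(cm, 1), "between 2")
  expect_error(find_minmax_bins(cm, 7), "between 2")
  # determinism under a fixed seed
  expect_identical(find_minmax_bins(cm, 3, seed = 9, restarts = 10)$groups,
                   find_minmax_bins(cm, 3, seed = 9, restarts = 10)$groups)
})

test_that("bin-count selection follows the min-P rule", {
  # homogeneous counts: even the finest binning is acceptable
  set.seed(26)
  p <- c(0.3, 0.3, 0.2, 0.2)
  cm <- t(replicate(6, as.vector(rmultinom(1, 400, p))))
  colnames(cm) <- LETTERS[1:4]
  rownames(cm) <- paste0("t", 1:6)
  expect_equal(as.integer(select_bin_count(cm, k_max = 4, seed = 2)), 4L)
  # a two-regime matrix: heterogeneous within {A,B} and {C,D} but exactly
  # balanced across them, so only the 2-bin partition is homogeneous
  cm2 <- rbind(t1 = c(300, 100, 200, 200), t2 = c(100, 300, 200, 200),
               t3 = c(200, 200, 300, 100), t4 = c(200, 200, 100, 300))
  colnames(cm2) <- LETTERS[1:4]
  k2 <- select_bin_count(cm2, k_max = 4, seed = 2)
  expect_equal(as.integer(k2), 2L)
  expect_equal(attr(k2, "partition")$groups, list(c("A", "B"), c("C", "D")))
  expect_warning(k1 <- select_bin_count(cm2, k_max = 4, alpha = 1, seed = 2),
                 "returning 1")
  expect_equal(as.integer(k1), 1L)
})
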