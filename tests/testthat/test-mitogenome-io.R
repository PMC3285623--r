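make_demo_genome <- function() {
  seq <- paste(rep("ACGT", 25), collapse = "")  # 100 bp
  synth_genbank(seq, list(
    list(key = "CDS", loc = "1..9", quals = '/gene="cox1"'),
    list(key = "CDS", loc = "complement(10..19)", quals = '/gene="ND2"'),
    list(key = "rRNA", loc = "20..40", quals = '/product="12S ribosomal RNA"'),
    list(key = "rRNA", loc = "complement(81..94)", quals = '/product="16S rRNA"'),
    list(key = "tRNA", loc = "41..60",
         quals = c('/product="tRNA-Leu"',
                   '/anticodon="(pos:50..52,aa:Leu,seq:uag)"')),
    list(key = "tRNA", loc = "61..70", quals = '/product="tRNA-Trp"'),
    list(key = "tRNA", loc = "71..80", quals = '/product="tRNA-Trp"'),
    list(key = "CDS", loc = "join(95..100,1..10)", quals = '/gene="atp8"')))
}

test_that("GenBank coordinates, strands and origin wrap resolve correctly", {
  g <- read_genbank(make_demo_genome())
  expect_s3_class(g, "mito_genome")
  expect_equal(g$length, 100L)
  expect_true(g$circular)
  f <- g$features
  expect_equal(f$start, sort(f$start))

  cox1 <- f[f$name == "cox1", ]
  expect_equal(c(cox1$start, cox1$end, cox1$strand), c(0, 9, 1))
  nad2 <- f[f$name == "nad2", ]
  expect_equal(c(nad2$start, nad2$end, nad2$strand), c(9, 19, -1))

  atp8 <- f[f$name == "atp8", ]
  expect_true(atp8$wraps_origin)
  expect_equal(nchar(feature_sequence(g, atp8)), 16L)
  # round-trip: 0-based half-open back to 1-based inclusive
  expect_equal(atp8$start + 1L, 95L)
  expect_equal(atp8$end, 10L)

  # duplicated tryptophan tRNAs get ordinal suffixes
  expect_setequal(f$name[f$kind == "trna"], c("L1", "W1", "W2"))

  # 3 * codons + incomplete_stop_len equals the feature length, every CDS
  for (i in which(f$kind == "cds")) {
    cds <- extract_cds(g, f$name[i])
    flen <- if (f$wraps_origin[i]) (g$length - f$start[i]) + f$end[i]
            else f$end[i] - f$start[i]
    expect_equal(3L * length(cds$codons) + f$incomplete_stop_len[i], flen)
  }
})

test_that("malformed or unsupported GenBank input fails loudly", {
  path <- tempfile()
  writeLines(c("LOCUS x 10 bp", "FEATURES", "     CDS             1..6",
               '                     /gene="cox1"'), path)
  expect_error(read_genbank(path), "ORIGIN")
  seq <- paste(rep("ACGT", 5), collapse = "")
  p <- synth_genbank(sub("A", "R", seq),
                     list(list(key = "CDS", loc = "1..6", quals = '/gene="cox1"')))
  expect_error(read_genbank(p), "ambiguity")
  p <- synth_genbank(seq, list(list(key = "CDS", loc = "1..6",
                                    quals = '/gene="mystery9"')))
  expect_error(read_genbank(p), "vocabulary")
  p <- synth_genbank(seq, list(list(key = "tRNA", loc = "1..6",
                                    quals = '/product="tRNA-Phe"')))
  expect_error(read_genbank(p), "no CDS or rRNA")
})

test_that("gene name normalization resolves synonyms and tRNA isoacceptors", {
  cases <- list(
    list("COIII", NULL, "cox3"), list("COI", NULL, "cox1"),
    list("cox2", NULL, "cox2"), list("CYTB", NULL, "cob"),
    list("ND4L", NULL, "nad4L"), list("NADH dehydrogenase subunit 5", NULL, "nad5"),
    list("ATPase subunit 6", NULL, "atp6"), list("12S ribosomal RNA", NULL, "rrnS"),
    list("l-rRNA", NULL, "rrnL"), list("D-loop", NULL, "MNCR"),
    list("tRNA-Leu", "UAG", "L1"), list("tRNA-Leu", "GAG", "L1"),
    list("tRNA-Leu", "UAA", "L2"), list("tRNA-Ser", "UCU", "S1"),
    list("tRNA-Ser", "UGA", "S2"), list("tRNA-Trp", NULL, "W"),
    list("trnM", NULL, "M"), list("tRNA-Leu(UUR)", NULL, "L2"))
  for (cs in cases)
    expect_identical(normalize_gene_name(cs[[1]], anticodon = cs[[2]]), cs[[3]])
  expect_error(normalize_gene_name("mystery9"), "vocabulary")
  expect_error(normalize_gene_name("tRNA-Leu"), "anticodon")
  expect_error(normalize_gene_name("tRNA-Ser"), "anticodon")
  # user-supplied synonym rows extend the packaged table
  expect_identical(
    normalize_gene_name("weird-name",
                        synonyms = data.frame(raw = "weird-name", token = "cox1")),
    "cox1")
})

test_that("CDS extraction reads frame, strand and incomplete stops", {
  # forward CDS ATG TTT TAA on a small genome
  seq <- paste0("ATGTTTTAA", "TTACATAAA", "GG")
  p <- synth_genbank(seq, list(
    list(key = "CDS", loc = "1..9", quals = '/gene="cox1"'),
    list(key = "CDS", loc = "complement(10..18)", quals = '/gene="ND1"'),
    list(key = "CDS", loc = "1..10", quals = '/gene="ND3"')),
    circular = FALSE)
  g <- read_genbank(p)
  fwd <- extract_cds(g, "cox1")
  expect_equal(fwd$codons, c("ATG", "TTT", "TAA"))
  expect_equal(fwd$translation, "MF*")
  # reverse strand: reverse complement of TTACATAAA is TTTATGTAA
  rev <- extract_cds(g, "nad1")
  expect_equal(rev$codons, c("TTT", "ATG", "TAA"))
  # trailing T marked as incomplete stop and excluded from the codons
  inc <- extract_cds(g, "nad3")
  expect_equal(inc$codons, c("ATG", "TTT", "TAA"))
  expect_equal(inc$incomplete_stop, "T")
  # internal stop warns but does not fail
  p2 <- synth_genbank("ATGTAATTTTAA", list(
    list(key = "CDS", loc = "1..12", quals = '/gene="cox1"')), circular = FALSE)
  expect_warning(extract_cds(read_genbank(p2), "cox1"), "internal stop")
})

test_that("gene order extraction follows genomic order, strand and filters", {
  g <- read_genbank(make_demo_genome())
  go <- extract_gene_order(g)
  expect_equal(go$tokens, c("cox1", "nad2", "rrnS", "rrnL", "atp8"))
  expect_equal(go$signs, c(1L, -1L, 1L, -1L, 1L))
  expect_true(go$circular)
  expect_length(extract_gene_order(g, include = character())$tokens, 0L)
  trn <- extract_gene_order(g, include = "trna")
  expect_equal(trn$tokens, c("L1", "W1", "W2"))
  # duplicated protein tokens are an error at parse time
  seq <- paste(rep("ACGT", 10), collapse = "")
  p <- synth_genbank(seq, list(
    list(key = "CDS", loc = "1..6", quals = '/gene="cox1"'),
    list(key = "CDS", loc = "10..15", quals = '/gene="COI"')))
  expect_error(read_genbank(p), "same token")
})

test_that("back-translation scaffolds codons onto the residue alignment", {
  aa <- mito_alignment(c(t1 = "M-F", t2 = "MKF"), alphabet = "AA20")
  nt <- backtranslate_alignment(aa, list(t1 = c("ATG", "TTT"),
                                         t2 = c("ATG", "AAA", "TTT")))
  expect_equal(paste(unclass(nt)["t1", ], collapse = ""), "ATG---TTT")
  expect_equal(ncol(nt), 3L * ncol(aa))
  # round trip: translating the codon alignment recovers the residues
  back <- translate_alignment(nt)
  expect_equal(unclass(back), unclass(aa), ignore_attr = TRUE)
  expect_error(
    backtranslate_alignment(aa, list(t1 = c("ATG"), t2 = c("ATG", "AAA", "TTT"))),
    "t1")
  # property: random toy alignments round-trip for all taxa and columns
  set.seed(42)
  gc5 <- Biostrings::getGeneticCode("5")
  sense <- names(gc5)[gc5 != "*"]
  for (rep in 1:5) {
    codons <- lapply(1:3, function(i) sample(sense, 6, TRUE))
    names(codons) <- paste0("s", 1:3)
    rows <- vapply(codons, function(cd) {
      aa <- strsplit(translate_codons(cd), "")[[1L]]
      pos <- sort(sample(8, 6))
      row <- rep("-", 8)
      row[pos] <- aa
      paste(row, collapse = "")
    }, character(1))
    al <- mito_alignment(rows, alphabet = "AA20")
    expect_equal(unclass(translate_alignment(backtranslate_alignment(al, codons))),
                 unclass(al), ignore_attr = TRUE)
  }
})

test_that("FASTA and report tables round-trip", {
  set.seed(7)
  al <- random_alignment(paste0("tax", 1:4), 150, gap_frac = 0.1)
  p <- tempfile(fileext = ".fasta")
  write_alignment(al, p)
  # wraps at 70 columns
  expect_lte(max(nchar(readLines(p))), 70L)
  back <- read_alignment(p)
  expect_identical(unclass(back), unclass(al))
  pe <- tempfile(); file.create(pe)
  expect_error(read_alignment(pe), "empty")
  pr <- tempfile()
  writeLines(c(">a", "ACGT", ">b", "ACG"), pr)
  expect_error(read_alignment(pr), "ragged")
  df <- data.frame(unit = c("a", "b"), value = c(1.5, 2.5))
  pt <- tempfile(fileext = ".tsv")
  write_table(df, pt)
  expect_equal(read_table(pt), df)
})
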