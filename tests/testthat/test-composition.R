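bac_total <- 113605L
te_path <- system.file("extdata", "bac2383a24_te_table.tsv", package = "retroclock")
gene_path <- system.file("extdata", "bac2383a24_genes.tsv", package = "retroclock")

test_that("the bundled BAC annotation reproduces the published fractions", {
  rec <- read_annotation(te_path)
  rep <- composition_report(rec, bac_total)
  frac <- function(cat) rep$fraction_pct[rep$category == cat]
  expect_equal(frac("class_I"), 51.6)
  expect_equal(frac("LTR_retrotransposons"), 50.7)
  expect_equal(frac("gypsy"), 27.9)
  expect_equal(frac("copia"), 21.4)
  expect_equal(frac("genes"), 4.3)
  expect_equal(frac("tandem_repeats"), 0.9)
  expect_equal(frac("class_II"), 3.3)
  expect_equal(frac("MITE"), 0.7)
  expect_equal(rep$length_bp[rep$category == "tandem_repeats"], 5L * 177L + 125L)
  expect_equal(rep$length_bp[rep$category == "class_I"], 58604L)
  expect_equal(rep$copies[rep$category == "LTR_retrotransposons"], 10L)
  # the family share of Fatima among LTR retrotransposons
  expect_equal(family_fraction(rec, "Fatima"), 47.2)
})

test_that("composition accounting handles empty input and over-assignment", {
  empty <- tibble::tibble(name = character(), category = character(),
                          copies = integer(), length_bp = integer())
  rep <- composition_report(empty, 1000)
  expect_equal(rep$fraction_pct[rep$category == "unassigned"], 100.0)
  too_big <- tibble::tibble(name = "x", category = "gene", copies = 1L,
                            length_bp = 2000L)
  expect_error(composition_report(too_big, 1000), "exceeds")
})

test_that("gene island geometry uses the coordinate-difference convention", {
  genes <- read_genes(gene_path)
  isl <- gene_island(genes)
  expect_equal(isl$offset_5prime, 9737L)
  expect_equal(isl$span, 23670L)
  expect_equal(isl$n_genes, 5L)

  one <- tibble::tibble(name = "g", start = 100L, end = 400L, strand = "+")
  isl1 <- gene_island(one)
  expect_equal(isl1$offset_5prime, 100L)
  expect_equal(isl1$span, 300L)

  # order-invariant
  shuffled <- genes[c(3, 1, 5, 2, 4), ]
  expect_equal(gene_island(shuffled), isl)
})

test_that("gene density rounds to the nearest kb per gene", {
  expect_equal(gene_density(bac_total, 5), 23)
  expect_equal(gene_density(100000, 1), 100)
  expect_equal(gene_density(bac_total, 1), 114)
})

test_that("protein lengths derive from intronless CDS spans minus the stop", {
  genes <- protein_length_from_cds(read_genes(gene_path))
  expect_equal(genes$protein_len, c(429, 502, 424, 164, 114))
  expect_equal(protein_length_from_cds(
    tibble::tibble(name = "t", start = 1L, end = 6L, strand = "+")
  )$protein_len, 1)
  expect_error(protein_length_from_cds(
    tibble::tibble(name = "t", start = 1L, end = 5L, strand = "+")
  ), "multiple of 3")
})

test_that("in-silico PCR reports product lengths from primer site arithmetic", {
  set.seed(430)
  fwd <- "CCAGATACCCATTCACCAAC"   # 20 nt
  rev <- "CCGAGGAGCACAACCTTAC"    # 19 nt
  rc <- function(x) retroclock:::revcomp(x)

  # fwd at 11-30, reverse site ending at 90 in a 100-bp template
  mid_len <- 90 - 30 - nchar(rev)  # 41
  tmpl <- paste0(rand_seq(10), fwd, rand_seq(mid_len), rc(rev), rand_seq(10))
  expect_equal(nchar(tmpl), 100)
  expect_equal(insilico_pcr(tmpl, fwd, rev), 80L)

  # template lacking the forward primer
  expect_equal(insilico_pcr(rand_seq(200), fwd, rev), integer(0))

  # minimal construction: fwd + 10 Ns + revcomp(rev)
  tmpl2 <- paste0(fwd, strrep("N", 10), rc(rev))
  expect_equal(insilico_pcr(tmpl2, fwd, rev), nchar(fwd) + 10L + nchar(rev))

  # hyphenated primer spelling is cleaned on input
  expect_equal(insilico_pcr(tmpl2, "ccaga-taccc-attca-ccaac", "ccgag-gagca-caacc-ttac"),
               nchar(fwd) + 10L + nchar(rev))

  # strand symmetry: reverse-complementing the template and swapping primers
  # reports the same product lengths
  expect_equal(insilico_pcr(rc(tmpl), rev, fwd), insilico_pcr(tmpl, fwd, rev))

  expect_error(insilico_pcr(tmpl, "ACGTACGTACGT", rev), "15 nt")
})
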