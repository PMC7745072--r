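test_that("FPKM follows its definition and is scale invariant", {
  counts <- data.frame(gene_id = "g1", rep = 1, count = 100)
  expect_equal(unname(fpkm(counts, c(g1 = 1000), totals = 1e6)), 100)

  two <- data.frame(gene_id = rep(c("g1", "g2"), 2), rep = rep(1:2, each = 2),
                    count = c(100, 300, 200, 600))
  lens <- c(g1 = 1000, g2 = 500)
  f1 <- fpkm(two, lens)
  doubled <- two; doubled$count <- doubled$count * 2
  expect_equal(fpkm(doubled, lens), f1)
  expect_error(fpkm(counts, c(g1 = 0), totals = 1e6), "length")
})

test_that("uniform expectation over a two-strand genome is ~630 FPKM", {
  # all reads spread evenly over 2 x 793,224 sites: FPKM = 1e9 / (2 * 793224 * ...)
  L <- 793224
  unif <- 1e6 / (2 * L / 1000)
  expect_equal(round(unif), 630)
  # the same number through the fpkm() code path: one "gene" covering a strand
  counts <- data.frame(gene_id = c("fwd", "rev"), rep = 1, count = 5e5)
  f <- fpkm(counts, c(fwd = L, rev = L), totals = c(1e6))
  expect_equal(unname(f), rep(unif, 2))
})

test_that("NSAF is the length-normalised spectral-count share", {
  expect_equal(unname(nsaf(c(p1 = 10), c(p1 = 100))), 1)
  two <- nsaf(c(p1 = 10, p2 = 10), c(p1 = 100, p2 = 300))
  expect_equal(unname(two), c(0.75, 0.25))
  expect_error(nsaf(c(p1 = 0), c(p1 = 100)), "zero")
  tr <- cached_truth(5)
  pp <- simulate_proteome(tr, seed = 1)
  ns <- nsaf(stats::setNames(pp$spc, pp$gene_id),
             stats::setNames(pp$length_aa, pp$gene_id))
  expect_equal(sum(ns), 1, tolerance = 1e-9)
})

test_that("molecular weights use average-mass residue sums", {
  expect_equal(protein_mw("G"), 75.07, tolerance = 1e-3)
  # dsDNA at the genome scale: a synthetic chromosome of the same length and
  # base composition weighs within 0.2% of the printed 489,954 kDa
  set.seed(10)
  chrom <- random_dna(793224, gc = 0.27)
  expect_lt(abs(dna_mw(chrom) / 1000 - 489954) / 489954, 0.002)
  # monotone in length for fixed composition
  mws <- vapply(c(10, 50, 100, 400), function(n) rna_mw(strrep("AUGC", n)),
                numeric(1))
  expect_true(all(diff(mws) > 0))
  expect_error(dna_mw("ACGN"), "position")
})

test_that("chromosome copy number matches the printed estimate", {
  expect_equal(round(chromosome_copies(1.70, 489954 * 1000), 1), 2.1)
  mw <- 4.9e8
  one_mass <- mw / 6.02214076e23 * 1e15
  expect_equal(chromosome_copies(one_mass, mw), 1, tolerance = 1e-12)
  expect_equal(chromosome_copies(2 * one_mass, mw), 2, tolerance = 1e-12)
})

test_that("RNA partition and equimolar counts follow the 80/15/5 split", {
  m <- rna_class_partition(4.9)
  expect_equal(unname(m), c(3.92, 0.735, 0.245))
  expect_error(rna_class_partition(4.9, c(a = 0.9, b = 0.2)), "more than 1")

  mw <- 3e5
  mass10 <- 10 * mw / 6.02214076e23 * 1e15
  eq <- equimolar_counts(mass10, mw)
  expect_equal(eq$per_set, 10, tolerance = 1e-9)
  eq3 <- equimolar_counts(1.5, c(a = 4e5, b = 5e5, c = 1e6))
  expect_equal(eq3$total, eq3$per_set * 3)
  expect_error(equimolar_counts(1, numeric()), "empty")
})

test_that("expression-weighted copies conserve mass and ignore scale", {
  x <- c(a = 3, b = 1, c = 6)
  mw <- c(a = 2e4, b = 5e4, c = 1e4)
  out <- copies_from_expression(x, mw, 0.24)
  expect_equal(sum(out$mass_fg), 0.24, tolerance = 1e-12)
  out10 <- copies_from_expression(x * 10, mw, 0.24)
  expect_equal(out10$copies, out$copies)
  single <- copies_from_expression(c(a = 5), c(a = 1e4), 0.1)
  expect_equal(single$copies, 0.1 / 1e15 * 6.02214076e23 / 1e4)
  sym <- copies_from_expression(c(a = 2, b = 2), c(a = 3e4, b = 3e4), 1)
  expect_equal(sym$mass_fg, c(0.5, 0.5))
  expect_equal(sym$copies[1], sym$copies[2])
})

test_that("planted protein copies are recovered within 10% at SpC >= 50", {
  tr <- cached_truth(5)
  pp <- simulate_proteome(tr, seed = 6)
  ns <- nsaf(stats::setNames(pp$spc, pp$gene_id),
             stats::setNames(pp$length_aa, pp$gene_id))
  mw <- vapply(tr$proteins, protein_mw, numeric(1))
  m_class <- sum(tr$protein_abundance * mw[names(tr$protein_abundance)]) /
    6.02214076e23 * 1e15
  out <- copies_from_expression(ns, mw[names(ns)], m_class)
  rel <- abs(out$copies - tr$protein_abundance[out$id]) /
    tr$protein_abundance[out$id]
  expect_lt(median(rel[pp$spc >= 50]), 0.10)
})

test_that("complex counts average subunit copies over stoichiometry", {
  rnap <- complex_counts(c(alpha = 400, beta = 190, beta_prime = 200),
                         c(alpha = 2, beta = 1, beta_prime = 1))
  expect_equal(round(rnap, 1), 196.7)
  expect_equal(complex_counts(c(a = 30, b = 10), c(a = 3, b = 1)), 10)
  expect_error(complex_counts(c(a = 1), c(a = 1, b = 2)), "missing subunit")
})

test_that("concentrations use the volume-window midpoint", {
  cc <- concentration(420, c(0.082, 0.097))
  expect_equal(signif(cc$midpoint, 2), 4.7e3)
  expect_equal(concentration(0, c(0.082, 0.097))$midpoint, 0)
  expect_equal(signif(concentration(250000, c(0.082, 0.097))$midpoint, 2), 2.8e6)
})

test_that("category shares split molecules and mass differently when MWs differ", {
  map <- data.frame(gene_id = c("g1", "g2"), category = c("translation", "metabolism"))
  copies <- c(g1 = 100, g2 = 100)
  masses <- c(g1 = 2, g2 = 1)
  out <- category_fractions(map, copies, masses)
  expect_equal(sum(out$share_molecules_pct), 100)
  expect_equal(sum(out$share_mass_pct), 100)
  mol <- stats::setNames(out$share_molecules_pct, out$category)
  mas <- stats::setNames(out$share_mass_pct, out$category)
  expect_equal(unname(mol["translation"]), 50)
  expect_equal(unname(mas["translation"]), 200 / 3, tolerance = 1e-9)
  expect_error(category_fractions(rbind(map, map[1, ]), copies, masses),
               "duplicate")
  # unmapped genes pool into their own category summing to 100
  out2 <- category_fractions(map[1, , drop = FALSE], copies, masses)
  expect_setequal(out2$category, c("translation", "unmapped"))
})

test_that("the molecular budget ties ribosomes to one third of the rRNA pool", {
  b <- molecular_budget(chromosome_copies = 2.1, rrna_molecules = 4900,
                        trna_molecules = 18000, mrna_molecules = 420,
                        protein_molecules = 250000,
                        ribosomes_from_proteins = 1600, rnap_cores = 270,
                        sigma70_copies = 230, volume_range = c(0.082, 0.097))
  expect_equal(unname(b$ribosomes["from_rrna"]), 4900 / 3)
  expect_equal(signif(unname(b$concentrations["mRNA"]), 2), 4.7e3)
  path <- withr::local_tempfile(fileext = ".json")
  write_budget_json(b, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})
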