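test_that("the stack-sum scorer behaves like a folding energy", {
  # a strong GC stem is much more stable than a weak AT stem
  strong <- hairpin_dg_stack("GCGCGCGC", "GCGCGCGC", 4)
  weak <- hairpin_dg_stack("ATATATAT", "ATATATAT", 4)
  expect_lt(strong, -15)
  expect_lt(strong, weak)
  # one mismatch destabilises
  mm <- hairpin_dg_stack("GCGCGCGC", "GCGCACGC", 4)
  expect_gt(mm, strong)
  # arms must match in length
  expect_error(hairpin_dg_stack("GCGC", "GC", 4), "length")
})

test_that("planted terminators are recovered with the TTS on the last stem base", {
  for (s in c(3, 9)) {
    tr <- cached_truth(s)
    tm <- predict_terminators(tr$genome)
    expect_setequal(pos_key(tm$tts, tm$strand),
                    pos_key(tr$terminators$tts, tr$terminators$strand))
  }
})

test_that("a poly-A tail downstream of a gene yields no terminator", {
  genes <- gene_row("gA", 21, 320, "+")
  seqstr <- paste0(random_dna(20, seed = 3), random_dna(300, seed = 4),
                   strrep("A", 200), random_dna(50, seed = 5))
  g <- toy_genome(seqstr, genes)
  expect_equal(nrow(predict_terminators(g)), 0L)
})

test_that("terminator calls mirror under reverse complement", {
  tr <- cached_truth(2)
  L <- tr$genome$length_bp
  fwd <- predict_terminators(tr$genome)
  rc <- predict_terminators(revcomp_genome(tr$genome))
  expect_setequal(pos_key(rc$tts, rc$strand),
                  pos_key(L + 1L - fwd$tts, ifelse(fwd$strand == "+", "-", "+")))
  # T-tract lengths are sequence properties and mirror exactly; free energies
  # need not (the mirrored hairpin is a different RNA molecule)
  expect_equal(sort(rc$t_tract_len), sort(fwd$t_tract_len))
})

test_that("scaffolds partition the circle between consecutive TTSs", {
  g <- toy_genome(random_dna(1000, seed = 1))
  terms <- data.frame(tts = c(100L, 400L), strand = "+", stringsAsFactors = FALSE)
  sc <- build_scaffolds(terms, g)
  plus <- sc[sc$strand == "+", ]
  expect_setequal(paste(plus$start, plus$end), c("101 400", "401 100"))
  expect_equal(sum(plus$length_bp), 1000)
  # single TTS: full circle ending there
  sc1 <- build_scaffolds(data.frame(tts = 250L, strand = "+"), g)
  p1 <- sc1[sc1$strand == "+", ]
  expect_equal(p1$end, 250L)
  expect_equal(p1$length_bp, 1000L)
  # no terminator on the minus strand: one full-circle scaffold
  minus <- sc[sc$strand == "-", ]
  expect_true(minus$full_circle)
  expect_equal(minus$length_bp, 1000L)
  # partition invariant on a simulated genome
  tr <- cached_truth(1)
  sc2 <- build_scaffolds(predict_terminators(tr$genome), tr$genome)
  expect_equal(as.numeric(tapply(sc2$length_bp, sc2$strand, sum)),
               rep(tr$genome$length_bp, 2))
})

make_tss_row <- function(position, strand, has_motif = TRUE,
                         context_class = "p-gTSS", overlapping = NA_character_,
                         plus_one = "A", count = 100) {
  data.frame(position = position, strand = strand, raw_count = count,
             rspm = count, has_motif = has_motif, minus10_start = NA_integer_,
             minus10_seq = NA_character_, spacer_len = NA_integer_,
             pwm_score = NA_real_, context_class = context_class,
             downstream_gene = NA_character_, overlapping_gene = overlapping,
             plus_one_base = plus_one, stringsAsFactors = FALSE)
}

test_that("gene attribution follows containment and the first-gene 5'UTR rule", {
  genes <- rbind(gene_row("gA", 100, 400, "+"), gene_row("gB", 450, 900, "+"))
  g <- toy_genome(random_dna(1200, seed = 9), genes)
  sc <- build_scaffolds(data.frame(tts = 950L, strand = "+"), g)
  tss <- make_tss_row(10L, "+")
  tus <- reconstruct_tus(sc, tss, g)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$gene_ids, "gA,gB")
  expect_equal(tus$utr5_len, 90L)
  expect_equal(tus$utr3_len, 50L)
  expect_equal(tus$category, "coding")

  # internal TSS: the host gene is excluded from its own TU
  itss <- make_tss_row(350L, "+", context_class = "p-iTSS", overlapping = "gA")
  tus2 <- reconstruct_tus(sc, itss, g)
  expect_equal(tus2$gene_ids, "gB")
  expect_equal(tus2$utr5_len, 100L)

  # a 5'UTR beyond 500 bp blocks attribution entirely
  far <- make_tss_row(10L, "+")
  g_far <- toy_genome(random_dna(1200, seed = 9),
                      rbind(gene_row("gA", 600, 800, "+")))
  tus3 <- reconstruct_tus(build_scaffolds(data.frame(tts = 950L, strand = "+"),
                                          g_far), far, g_far)
  expect_false(any(tus3$category == "coding"))
  # ... unless the per-gene mode admits later genes
  tus4 <- reconstruct_tus(build_scaffolds(data.frame(tts = 950L, strand = "+"),
                                          g_far), far, g_far,
                          per_gene_utr5 = TRUE)
  expect_false(any(tus4$category == "coding"))

  # leaderless: gene starting exactly on the TSS is attributed with UTR 0
  lead <- make_tss_row(100L, "+")
  tus5 <- reconstruct_tus(sc, lead, g)
  expect_equal(tus5$utr5_len, 0L)
  expect_true(tus5$leaderless)
})

test_that("noise-free reconstruction equals planted TUs", {
  for (s in c(4, 12)) {
    tr <- cached_truth(s)
    sig <- simulate_race(tr, background_rate = 0, seed = s)
    ann <- annotate_tss(sig, tr$genome)
    sc <- build_scaffolds(predict_terminators(tr$genome), tr$genome)
    tus <- reconstruct_tus(sc, ann$tss, tr$genome)
    expect_setequal(tu_key(tus[tus$category == "coding", ]), tu_key(tr$tus))
  }
})

test_that("orphan genes are rescued by purine non-motif TSSs, and only those", {
  genes <- gene_row("gA", 200, 500, "+")
  g <- toy_genome(random_dna(1000, seed = 2), genes)
  sc <- build_scaffolds(data.frame(tts = 600L, strand = "+"), g)
  # no motif-associated TSS at all -> gA orphan
  tss_pur <- make_tss_row(120L, "+", has_motif = FALSE, plus_one = "A")
  res <- rescue_orphans(empty_tu_with_flag(), tss_pur, sc, g)
  expect_equal(res$orphans, character(0))
  expect_equal(res$tus$gene_ids, "gA")
  expect_equal(res$tus$category, "rescue-nonmotif")

  tss_pyr <- make_tss_row(120L, "+", has_motif = FALSE, plus_one = "C")
  res2 <- rescue_orphans(empty_tu_with_flag(), tss_pyr, sc, g)
  expect_equal(res2$orphans, "gA")
})

test_that("read-through rescue crosses the previous terminator only for expressed genes", {
  genes <- gene_row("gA", 700, 900, "+")
  g <- toy_genome(random_dna(1200, seed = 2), genes)
  sc <- build_scaffolds(data.frame(tts = c(650L, 950L), strand = "+"), g)
  # motif TSS in the previous scaffold, 5'UTR across the TTS at 650
  tss <- make_tss_row(500L, "+", has_motif = TRUE)
  expr <- c(gA = 12)
  res <- rescue_orphans(empty_tu_with_flag(), tss, sc, g, expression = expr)
  expect_equal(res$tus$gene_ids, "gA")
  expect_equal(res$tus$category, "rescue-readthrough")
  expect_equal(res$tus$tts, 950L)

  res0 <- rescue_orphans(empty_tu_with_flag(), tss, sc, g,
                         expression = c(gA = 0))
  expect_equal(res0$orphans, "gA")
})

test_that("simulated motif-less operons are rescued end to end", {
  tr <- generate_genome(n_genes = 12, genome_length = 16000, seed = 31,
                        no_motif_frac = 0.3)
  sig <- simulate_race(tr, background_rate = 0, seed = 1)
  ann <- annotate_tss(sig, tr$genome)
  sc <- build_scaffolds(predict_terminators(tr$genome), tr$genome)
  tus <- reconstruct_tus(sc, ann$tss, tr$genome)
  res <- rescue_orphans(tus, ann$tss, sc, tr$genome,
                        expression = gene_expression_truth(tr))
  expect_equal(res$orphans, character(0))
  expect_setequal(tu_key(res$tus[res$tus$gene_ids != "", ]), tu_key(tr$tus))
})

test_that("TU statistics summarise the gene content", {
  genes <- rbind(gene_row("gA", 100, 200), gene_row("gB", 300, 400),
                 gene_row("gC", 500, 600), gene_row("gD", 700, 800))
  g <- toy_genome(random_dna(1000, seed = 3), genes)
  tus <- data.frame(
    tu_id = c("TU_001", "TU_002"), tss = c(50L, 250L), tts = c(220L, 900L),
    start = c(50L, 250L), end = c(220L, 900L), strand = "+",
    gene_ids = c("gA", "gB,gC,gD"), utr5_len = c(50L, 50L),
    utr3_len = c(20L, 100L), category = "coding", tss_class = "p-gTSS",
    stringsAsFactors = FALSE)
  st <- tu_statistics(tus, g)
  expect_equal(st$mean_genes_per_tu, 2)
  expect_equal(st$max_genes_per_tu, 3)
  expect_equal(st$genes_covered, 4)
  expect_equal(sum(as.integer(names(st$tus_per_gene)) * st$tus_per_gene), 4)
  expect_warning(tu_statistics(tus[0, ], g), "empty")
})

test_that("meta profiles align signal on anchors", {
  g <- toy_genome(random_dna(2000, seed = 4))
  const <- strand_signal(rep(3, 2000), rep(3, 2000))
  anchors <- data.frame(start = c(500L, 1200L), strand = "+")
  prof <- meta_profile(const, anchors, g, flank = 50)
  expect_true(all(prof$mean == 3))
  expect_true(all(prof$sem == 0))

  v <- rep(0, 2000); v[450:550] <- seq_len(101)
  sig <- strand_signal(v, rep(0, 2000))
  one <- meta_profile(sig, data.frame(start = 500L, strand = "+"), g, flank = 50)
  expect_equal(one$mean, as.numeric(v[450:550]))

  # step profile over TU-like intervals: interior >> outside
  tus <- data.frame(start = c(300L, 900L), end = c(600L, 1400L), strand = "+")
  v2 <- rep(0.1, 2000); v2[300:600] <- 5; v2[900:1400] <- 5
  sig2 <- strand_signal(v2, rep(0, 2000))
  prof2 <- meta_profile(sig2, tus, g, flank = 100, n_bins = 50)
  inside <- mean(prof2$mean[prof2$zone == "interior"])
  outside <- mean(prof2$mean[prof2$zone != "interior"])
  expect_gt(inside, 2 * outside)
})
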