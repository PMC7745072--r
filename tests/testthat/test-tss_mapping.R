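test_that("RSPM is read starts per million mapped reads", {
  g <- 1e6
  sig <- strand_signal(c(10, rep(0, 4)), rep(0, 5), total_mapped = 1e6)
  expect_equal(compute_rspm(sig)$plus[1], 10)
  sig2 <- strand_signal(c(5, rep(0, 4)), rep(0, 5), total_mapped = 2e6)
  expect_equal(compute_rspm(sig2)$plus[1], 2.5)
  # conservation: every mapped read start on-genome -> RSPM sums to 1e6
  set.seed(1)
  sig3 <- strand_signal(rpois(200, 2), rpois(200, 2))
  r <- compute_rspm(sig3)
  expect_equal(sum(r$plus) + sum(r$minus), 1e6)
  expect_error(compute_rspm(strand_signal(rep(0, 5), rep(0, 5))), "total_mapped")
})

test_that("the caller returns nothing on an all-zero track", {
  expect_equal(nrow(call_tss(strand_signal(rep(0, 100), rep(0, 100)))), 0L)
})

test_that("clustered significant positions are represented by the max count, ties leftmost", {
  v <- rep(0, 2000)
  v[100] <- 50; v[103] <- 80          # one cluster, max at 103
  v[500] <- 60; v[504] <- 60          # tie -> leftmost
  v[900] <- 70                        # singleton
  sig <- strand_signal(v, rep(0, 2000))
  out <- call_tss(sig)
  expect_equal(out$position[out$strand == "+"], c(103L, 500L, 900L))
  # count invariant: calls <= significant <= non-null
  expect_lte(nrow(out), sum(v > 0))
})

test_that("a PWM built from identical sites has that site as consensus", {
  seqstr <- paste0(strrep("C", 30), "TGATAAAAT", strrep("C", 30))
  g <- toy_genome(seqstr)
  sites <- data.frame(minus10_start = c(34L, 34L, 34L), strand = "+")
  pwm <- build_pwm(sites, g)
  expect_equal(pwm_consensus(pwm), "TGATAAAAT")
  expect_equal(colSums(pwm$probs), rep(1, 9))
})

test_that("promoter scan recovers a planted spacer and rejects motif-free sequence", {
  # promoter: EXT(TGA) + box(TAAAAT) + spacer 6 + purine +1 at position 101
  set.seed(21)
  up <- strrep("CA", 42)  # 84 bases; then a C pad: no box-like site upstream
  seqstr <- paste0(up, "C", "TGA", "TAAAAT", "ACCGCC", "A",
                   random_dna(100, gc = 0.27))
  g <- toy_genome(seqstr)
  sites <- data.frame(minus10_start = 89L, strand = "+")
  pwm <- build_pwm(sites, g)
  hit <- scan_promoter(101L, "+", g, pwm)
  expect_equal(hit$spacer_len, 6L)
  expect_equal(hit$minus10_start, 89L)
  expect_match(hit$minus10_seq, "^TA[AT]AAT$")

  # pure A/C stretch upstream: no admissible box placement
  g2 <- toy_genome(paste0(strrep("AC", 60), random_dna(50, 0.27)))
  expect_null(scan_promoter(100L, "+", g2, pwm))
})

test_that("TSS context classification follows gene topology", {
  genes <- rbind(gene_row("gA", 100, 200, "+"), gene_row("gB", 400, 450, "-"))
  g <- toy_genome(random_dna(1000, seed = 5), genes)
  df <- data.frame(position = c(50L, 150L, 320L), strand = "+",
                   stringsAsFactors = FALSE)
  out <- classify_tss(df, g)
  expect_equal(out$context_class, c("p-gTSS", "p-iTSS", "a-gTSS"))
  expect_equal(out$downstream_gene[1], "gA")
  expect_equal(out$overlapping_gene[2], "gA")
  expect_equal(out$downstream_gene[3], "gB")

  g3 <- toy_genome(random_dna(1000, seed = 5),
                   rbind(gene_row("gC", 100, 200, "-")))
  out3 <- classify_tss(data.frame(position = 150L, strand = "+"), g3)
  expect_equal(out3$context_class, "a-iTSS")

  g0 <- toy_genome(random_dna(300, seed = 6))
  out0 <- classify_tss(data.frame(position = 10L, strand = "+"), g0)
  expect_equal(out0$context_class, "unassigned")
})

test_that("the +1 base is read strand-correctly", {
  seqstr <- paste0(strrep("C", 49), "A", strrep("C", 50))
  g <- toy_genome(seqstr)
  out <- classify_tss(data.frame(position = c(50L, 50L), strand = c("+", "-")), g)
  expect_equal(out$plus_one_base, c("A", "T"))
})

test_that("noise-free pipeline assigns the motif to exactly the planted fraction", {
  tr <- generate_genome(n_genes = 12, genome_length = 16000, seed = 31,
                        no_motif_frac = 0.3)
  sig <- simulate_race(tr, background_rate = 0, seed = 1)
  ann <- annotate_tss(sig, tr$genome)
  expect_setequal(pos_key(ann$tss$position, ann$tss$strand),
                  pos_key(tr$promoters$tss, tr$promoters$strand))
  expect_equal(sum(ann$tss$has_motif), sum(tr$promoters$has_motif))
  with_motif <- ann$tss[ann$tss$has_motif, ]
  planted <- tr$promoters[tr$promoters$has_motif, ]
  expect_setequal(pos_key(with_motif$position, with_motif$strand),
                  pos_key(planted$tss, planted$strand))
  # spacers recovered where planted
  sp <- merge(with_motif, planted,
              by.x = c("position", "strand"), by.y = c("tss", "strand"))
  expect_true(mean(sp$spacer_len.x == sp$spacer_len.y) >= 0.9)
  # +1 bases are purines by construction
  expect_true(all(ann$tss$plus_one_base %in% c("A", "G")))
})

test_that("calls are strand-symmetric under genome reverse complement", {
  tr <- cached_truth(2)
  L <- tr$genome$length_bp
  sig <- simulate_race(tr, background_rate = 0, seed = 8)
  fwd <- call_tss(sig)
  flipped <- strand_signal(rev(sig$minus), rev(sig$plus))
  rc <- call_tss(flipped)
  expect_setequal(pos_key(rc$position, rc$strand),
                  pos_key(L + 1L - fwd$position,
                          ifelse(fwd$strand == "+", "-", "+")))
  expect_equal(sort(rc$raw_count), sort(fwd$raw_count))
})
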