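test_that("a single-gene genome plants one promoter, terminator and TU", {
  tr <- generate_genome(n_genes = 1, genome_length = 5000, seed = 7)
  expect_equal(nrow(tr$promoters), 1L)
  expect_equal(nrow(tr$terminators), 1L)
  expect_equal(nrow(tr$tus), 1L)
  expect_equal(tu_key(tr$tus),
               paste(tr$promoters$tss, tr$terminators$tts,
                     tr$promoters$strand, tr$genome$genes$id))
})

test_that("generation is deterministic per seed", {
  a <- generate_genome(n_genes = 10, genome_length = 12000, seed = 11)
  b <- generate_genome(n_genes = 10, genome_length = 12000, seed = 11)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_equal(a$tus, b$tus)
  expect_identical(simulate_race(a, seed = 5)$plus, simulate_race(b, seed = 5)$plus)
  expect_identical(simulate_rnaseq(a, seed = 5), simulate_rnaseq(b, seed = 5))
  expect_identical(simulate_proteome(a, seed = 5), simulate_proteome(b, seed = 5))
})

test_that("operon sizes in truth match the configured distribution", {
  probs <- c(0.45, 0.25, 0.15, 0.10, 0.05)
  target_mean <- sum(seq_along(probs) * probs)
  sizes <- unlist(lapply(1:5, function(s) {
    tr <- generate_genome(n_genes = 40, genome_length = 42000, seed = s,
                          itss_frac = 0, certify = FALSE)
    lengths(lapply(tr$tus$gene_ids, function(x) strsplit(x, ",")[[1]]))
  }))
  expect_lt(abs(mean(sizes) - target_mean), 0.5)
})

test_that("truth invariants hold: positive quantities, bounded 5'UTRs, TAWAAT boxes", {
  for (s in 1:3) {
    tr <- cached_truth(s)
    expect_true(all(tr$tus$abundance > 0))
    expect_true(all(tr$protein_abundance > 0))
    g <- tr$genome$genes
    for (i in seq_len(nrow(tr$tus))) {
      ids <- strsplit(tr$tus$gene_ids[i], ",")[[1]]
      first <- g[g$id == ids[1], ]
      utr5 <- if (tr$tus$strand[i] == "+") first$start - tr$tus$tss[i] else
        tr$tus$tss[i] - first$end
      expect_gte(utr5, 0)
      expect_lte(utr5, 500)
    }
    pm <- tr$promoters[tr$promoters$has_motif, ]
    for (i in seq_len(nrow(pm))) {
      box <- subseq_oriented(tr$genome, pm$minus10_start[i], 6L, pm$strand[i])
      expect_match(box, "^TA[AT]AAT$")
      expect_true(pm$spacer_len[i] >= 4 && pm$spacer_len[i] <= 9)
    }
    expect_true(all(tr$terminators$t_tract_len >= 4))
  }
})

test_that("read-start peaks land within 1 bp of the planted +1 and scale with depth", {
  tr <- generate_genome(n_genes = 1, genome_length = 5000, seed = 7)
  sig <- simulate_race(tr, depth = 500, background_rate = 0, seed = 3)
  v <- if (tr$promoters$strand == "+") sig$plus else sig$minus
  other <- if (tr$promoters$strand == "+") sig$minus else sig$plus
  nz <- which(v > 0)
  expect_true(all(abs(nz - tr$promoters$tss) <= 1))
  expect_true(all(other == 0))

  # mean count at +1 over repeated simulations ~ strength * depth * 0.8
  strength <- tr$promoters$strength
  depth <- 1500 / strength          # peak expectation >= 1000
  at_plus1 <- vapply(1:30, function(i) {
    s <- simulate_race(tr, depth = depth, background_rate = 0, seed = i)
    (if (tr$promoters$strand == "+") s$plus else s$minus)[tr$promoters$tss]
  }, numeric(1))
  expect_lt(abs(mean(at_plus1) / (strength * depth * 0.8) - 1), 0.05)
})

test_that("background-only read starts follow the Poisson tail", {
  tr <- cached_truth(1)
  bare <- tr
  bare$promoters <- tr$promoters[0, ]
  lambda <- 0.1
  sig <- simulate_race(bare, depth = 1, background_rate = lambda, seed = 9)
  v <- c(sig$plus, sig$minus)
  for (k in 1:3) {
    p_tail <- ppois(k - 1, lambda, lower.tail = FALSE)
    obs <- mean(v >= k)
    ci <- 4 * sqrt(p_tail * (1 - p_tail) / length(v))
    expect_lt(abs(obs - p_tail), ci + 1e-12)
  }
})

test_that("RNA-seq counts are proportional to abundance x length (zero dispersion)", {
  tt <- toy_truth(gene_lengths = c(300L, 600L), abundances = c(1, 1))
  rs <- simulate_rnaseq(tt, total_fragments = 9000, dispersion = 0, n_reps = 1)
  expect_equal(rs$count, c(3000, 6000))

  tt1 <- toy_truth(gene_lengths = 300L, abundances = 2)
  rs1 <- simulate_rnaseq(tt1, total_fragments = 1234, dispersion = 0, n_reps = 2)
  expect_equal(rs1$count, c(1234, 1234))
})

test_that("FPKM downstream of simulated RNA-seq recovers planted relative abundance", {
  tr <- cached_truth(5)
  rs <- simulate_rnaseq(tr, seed = 4)
  lens <- stats::setNames(rs$length_nt[rs$rep == 1], rs$gene_id[rs$rep == 1])
  f <- fpkm(rs, lens)
  expr <- gene_expression_truth(tr)
  expect_gte(length(expr), 30)
  expect_gte(cor(f[names(expr)], expr, method = "spearman"), 0.95)
})

test_that("spectral counts are multinomial in copies x length", {
  tt <- toy_truth(gene_lengths = 300L, abundances = 1)
  pp <- simulate_proteome(tt, total_spectra = 500)
  expect_equal(pp$spc, 500L)

  tt2 <- toy_truth(gene_lengths = c(300L, 900L), abundances = c(1, 1),
                   protein_lengths = c(100L, 300L), copies = c(1000, 1000))
  pp2 <- simulate_proteome(tt2, total_spectra = 40000, seed = 2)
  expect_lt(abs(pp2$spc[2] / pp2$spc[1] - 3), 0.3)
})

test_that("growth simulators reproduce their doubling time exactly without noise", {
  g <- simulate_growth(dt_minutes = 30, noise_sd = 0, seed = 1)
  expect_equal(fit_doubling_time(g)$dt_minutes, 30, tolerance = 1e-9)

  od <- simulate_od_dilutions(dt_minutes = 30, noise_sd = 0, seed = 1)
  res <- doubling_time_from_dilutions(od)
  expect_equal(res$dt_minutes, 30, tolerance = 1e-6)
  expect_lt(stats::sd(res$offsets), 1e-6)
})

test_that("truth serialises to YAML + TSV and the genome files reload", {
  tr <- generate_genome(n_genes = 3, genome_length = 8000, seed = 2)
  dir <- withr::local_tempdir()
  write_sim_truth(tr, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "genes.gff3", "promoters.tsv", "terminators.tsv",
           "tus.tsv", "protein_abundance.tsv", "truth.yaml")))))
  back <- read_genome(file.path(dir, "genome.fasta"), file.path(dir, "genes.gff3"))
  expect_identical(back$sequence, tr$genome$sequence)
  y <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(y$growth_truth$dt_minutes, 32)
})
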