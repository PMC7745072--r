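# Rho-independent terminator prediction, term-to-term scaffolds on the
# circular chromosome, transcription-unit reconstruction and TU statistics.
#
# Terminator model: an RNA stem-loop followed by a poly-T (poly-U in the
# transcript) tract. Candidates are enumerated downstream of every gene end
# (stem >= 6 bp with at most one mismatch, loop 3-10 nt), their hairpin free
# energy is evaluated by a nearest-neighbour stack-sum scorer (pluggable),
# and each candidate is scored
#     score = a * (-dG) + b * t_tract_len - c * dist_past_stop
# with a T-tract of >= 3 nt required and only stable folds (dG < 0)
# admitted. Candidates with score > 0 are retained; overlaps resolve by
# maximal score. The transcription termination site (TTS) is the last base
# of the stem-loop in transcription direction.

# Turner-style Watson-Crick stack energies (kcal/mol), keyed by the two
# consecutive top-strand bases (DNA alphabet, T == U); partner implied WC.
WC_STACK <- c(
  AA = -0.93, AT = -1.10, AC = -2.24, AG = -2.08,
  TA = -1.33, TT = -0.93, TG = -2.11, TC = -2.35,
  CA = -2.11, CT = -2.08, CC = -3.26, CG = -2.36,
  GA = -2.35, GT = -2.24, GC = -3.42, GG = -3.26)

# hairpin loop initiation penalties, loop length 3..10
LOOP_PENALTY <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4, 6.5)

MISMATCH_PENALTY <- 1.0
WOBBLE_STACK <- -0.5

is_wc <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
}
is_wobble <- function(x, y) (x == "G" & y == "T") | (x == "T" & y == "G")

#' Nearest-neighbour hairpin free energy
#'
#' Stack-sum estimate of the folding free energy of a hairpin given its two
#' stem arms (both written 5' to 3' in the transcript) and loop length.
#' Watson-Crick steps use Turner-style stack energies, wobble (G:U) pairs a
#' flat weak stack, mismatched positions break stacking and add a penalty,
#' and the loop contributes a length-dependent initiation penalty.
#'
#' @param stem5 5' arm sequence (transcription direction).
#' @param stem3 3' arm sequence (transcription direction).
#' @param loop_len loop length in nt (3-10).
#' @return estimated dG in kcal/mol (negative = stable).
#' @export
hairpin_dg_stack <- function(stem5, stem3, loop_len) {
  a <- strsplit(toupper(stem5), "")[[1]]
  b <- rev(strsplit(toupper(stem3), "")[[1]])  # pair partner of a[j] is b[j]
  k <- length(a)
  if (length(b) != k) stop("stem arms differ in length")
  paired <- is_wc(a, b) | is_wobble(a, b)
  dg <- sum(!paired) * MISMATCH_PENALTY
  for (j in seq_len(k - 1)) {
    if (paired[j] && paired[j + 1]) {
      if (is_wc(a[j], b[j]) && is_wc(a[j + 1], b[j + 1])) {
        dg <- dg + WC_STACK[paste0(a[j], a[j + 1])]
      } else {
        dg <- dg + WOBBLE_STACK
      }
    }
  }
  li <- min(max(loop_len, 3L), 10L)
  unname(dg + LOOP_PENALTY[li - 2L])
}

# 4x4 lookups over integer-coded bases (A=1, C=2, G=3, T=4)
PAIR_OK <- local({
  m <- matrix(FALSE, 4, 4)
  m[cbind(c(1, 4, 2, 3, 3, 4), c(4, 1, 3, 2, 4, 3))] <- TRUE  # WC + G:T wobble
  m
})
WC_OK <- local({
  m <- matrix(FALSE, 4, 4)
  m[cbind(c(1, 4, 2, 3), c(4, 1, 3, 2))] <- TRUE
  m
})
# stack energy for a WC step keyed by its two top-strand base codes
WC_STACK_MAT <- local({
  m <- matrix(NA_real_, 4, 4)
  for (nm in names(WC_STACK)) {
    ij <- match(strsplit(nm, "")[[1]], BASES)
    m[ij[1], ij[2]] <- WC_STACK[[nm]]
  }
  m
})

# Vectorised stack-sum energy for a candidate hairpin given integer codes.
dg_fast <- function(code, i, k, l) {
  top <- code[i:(i + k - 1L)]
  bot <- code[i + 2L * k + l - seq_len(k)]   # partner of top[j]
  paired <- PAIR_OK[cbind(top, bot)]
  wc <- WC_OK[cbind(top, bot)]
  dg <- sum(!paired) * MISMATCH_PENALTY
  both <- paired[-k] & paired[-1L]
  bothwc <- wc[-k] & wc[-1L]
  stacks <- ifelse(both & bothwc, WC_STACK_MAT[cbind(top[-k], top[-1L])],
                   ifelse(both, WOBBLE_STACK, 0))
  dg + sum(stacks) + LOOP_PENALTY[min(max(l, 3L), 10L) - 2L]
}

# Enumerate hairpin candidates in a transcription-frame window sequence.
# Returns a data.frame in local coordinates (1-based within the window).
# fold_fun = NULL uses the vectorised internal scorer (identical to
# hairpin_dg_stack); a user-supplied function is called per candidate.
enumerate_hairpins <- function(wseq, stem_range = c(6L, 13L),
                               loop_range = c(3L, 10L), max_mismatch = 1L,
                               fold_fun = NULL) {
  w <- strsplit(wseq, "")[[1]]
  W <- length(w)
  # length of the T run starting at each position (for T-tract lookup)
  trun <- integer(W + 1L)
  for (p in W:1) trun[p] <- if (w[p] == "T") trun[p + 1L] + 1L else 0L
  code <- match(w, BASES)
  # bad[[d]][u]: TRUE when code[u] cannot pair code[u + d]
  dmax <- 2L * stem_range[2] + loop_range[2] - 1L
  bad <- vector("list", dmax)
  for (d in seq_len(dmax)) {
    if (d < W) bad[[d]] <- !PAIR_OK[cbind(code[1:(W - d)], code[(1 + d):W])]
  }
  hits <- list()
  for (k in seq(stem_range[1], stem_range[2])) {
    for (l in seq(loop_range[1], loop_range[2])) {
      span <- 2L * k + l
      if (span > W) next
      n_i <- W - span + 1L
      mism <- integer(n_i)
      base <- seq_len(n_i)
      for (j in seq_len(k)) {
        d <- 2L * (k - j) + l + 1L
        mism <- mism + bad[[d]][base + j - 1L]
      }
      idx <- which(mism <= max_mismatch)
      if (length(idx)) hits[[length(hits) + 1L]] <- cbind(i = idx, k = k, l = l)
    }
  }
  if (!length(hits)) return(NULL)
  m <- do.call(rbind, hits)
  n <- nrow(m)
  dg <- numeric(n)
  if (is.null(fold_fun)) {
    for (r in seq_len(n)) dg[r] <- dg_fast(code, m[r, 1L], m[r, 2L], m[r, 3L])
  } else {
    for (r in seq_len(n)) {
      i <- m[r, 1L]; k <- m[r, 2L]; l <- m[r, 3L]
      dg[r] <- fold_fun(paste(w[i:(i + k - 1L)], collapse = ""),
                        paste(w[(i + k + l):(i + 2L * k + l - 1L)], collapse = ""),
                        l)
    }
  }
  span <- 2L * m[, 2L] + m[, 3L]
  data.frame(local_start = m[, 1L], stem_len = m[, 2L], loop_len = m[, 3L],
             local_end = m[, 1L] + span - 1L, dg = dg,
             t_tract_len = trun[pmin(m[, 1L] + span, W + 1L)])
}

#' Predict Rho-independent terminators
#'
#' Scans a window downstream of every gene end (per strand, circular wrap),
#' scores candidate hairpins and resolves overlaps by maximal score.
#'
#' @param genome a [genome_annotation()].
#' @param window_len search window length downstream of each gene end (bp).
#' @param a,b,c score weights: `a * (-dG) + b * t_tract - c * dist_past_stop`.
#' @param min_tract minimal T-tract length (nt).
#' @param stem_range,loop_range,max_mismatch hairpin enumeration bounds.
#' @param max_dg stability requirement: only hairpins folding at or below
#'   this free energy (kcal/mol) are admitted as candidates. Marginal folds
#'   (a few kT) in AT-rich sequence are not credible terminator structures;
#'   the default -6 sits well below the energies of canonical terminator
#'   hairpins while rejecting incidental weak stems.
#' @param fold_fun hairpin energy function (pluggable). `NULL` (default) uses
#'   the vectorised nearest-neighbour scorer equivalent to
#'   [hairpin_dg_stack()]; supply a function `(stem5, stem3, loop_len) -> dG`
#'   to use another folding engine.
#' @return data.frame of terminators: `term_id`, `strand`, stem/loop
#'   coordinates (numeric lo..hi; `stem5` is the transcription-first arm),
#'   `tts` (last stem base in transcription direction), `score`,
#'   `t_tract_len`, `dg`.
#' @export
predict_terminators <- function(genome, window_len = 200L, a = 1, b = 2,
                                c = 0.05, min_tract = 3L,
                                stem_range = c(6L, 13L), loop_range = c(3L, 10L),
                                max_mismatch = 1L, max_dg = -6,
                                fold_fun = NULL) {
  g <- genome$genes
  L <- genome$length_bp
  cands <- list()
  for (i in seq_len(nrow(g))) {
    s <- g$strand[i]
    anchor <- if (s == "+") g$end[i] else g$start[i]  # gene 3' end
    first <- if (s == "+") anchor + 1L else anchor - 1L
    wl <- min(window_len, L - 1L)
    wseq <- subseq_oriented(genome, first, wl, s)
    hp <- enumerate_hairpins(wseq, stem_range, loop_range, max_mismatch, fold_fun)
    if (is.null(hp)) next
    hp <- hp[hp$t_tract_len >= min_tract, , drop = FALSE]
    hp <- hp[hp$dg <= max_dg, , drop = FALSE]
    if (!nrow(hp)) next
    hp$dist <- hp$local_end  # distance from gene stop to TTS
    hp$score <- a * (-hp$dg) + b * hp$t_tract_len - c * hp$dist
    hp <- hp[hp$score > 0, , drop = FALSE]
    if (!nrow(hp)) next
    # map local (transcription-frame) coords to genome coords
    to_global <- function(p) if (s == "+") wrap_pos(anchor + p, L) else
      wrap_pos(anchor - p, L)
    g1 <- to_global(hp$local_start)
    g2 <- to_global(hp$local_start + hp$stem_len - 1L)
    g3 <- to_global(hp$local_start + hp$stem_len)
    g4 <- to_global(hp$local_start + hp$stem_len + hp$loop_len - 1L)
    g5 <- to_global(hp$local_end - hp$stem_len + 1L)
    g6 <- to_global(hp$local_end)
    cands[[length(cands) + 1L]] <- data.frame(
      strand = s, stem5_start = pmin(g1, g2), stem5_end = pmax(g1, g2),
      loop_start = pmin(g3, g4), loop_end = pmax(g3, g4),
      stem3_start = pmin(g5, g6), stem3_end = pmax(g5, g6),
      tts = g6, score = hp$score, t_tract_len = hp$t_tract_len, dg = hp$dg,
      stringsAsFactors = FALSE)
  }
  if (!length(cands)) {
    return(data.frame(term_id = character(), strand = character(),
                      stem5_start = integer(), stem5_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      stem3_start = integer(), stem3_end = integer(),
                      tts = integer(), score = numeric(),
                      t_tract_len = integer(), dg = numeric(),
                      stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, cands)
  all <- all[!duplicated(all[c("strand", "tts", "stem5_start")]), , drop = FALSE]
  all <- all[order(-all$score), , drop = FALSE]
  kept <- list()
  for (s in c("+", "-")) {
    sub <- all[all$strand == s, , drop = FALSE]
    occupied <- logical(L)
    for (j in seq_len(nrow(sub))) {
      span <- range(sub$stem5_start[j], sub$stem5_end[j],
                    sub$stem3_start[j], sub$stem3_end[j])
      idx <- span[1]:span[2]
      if (!any(occupied[idx])) {
        occupied[idx] <- TRUE
        kept[[length(kept) + 1L]] <- sub[j, ]
      }
    }
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$tts), , drop = FALSE]
  out$term_id <- sprintf("term_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("term_id", setdiff(names(out), "term_id"))]
}

#' Term-to-term scaffolds
#'
#' Partitions the circle, per strand, into intervals each starting one base
#' after a TTS and ending at the next TTS in transcription direction. With no
#' terminator on a strand a single full-circle scaffold is returned.
#'
#' @param terminators terminator table ([predict_terminators()] output or the
#'   truth table).
#' @param genome a [genome_annotation()].
#' @return data.frame: `scaffold_id`, `strand`, `start`, `end` (transcription
#'   direction, wrapping allowed), `length_bp`, `full_circle`.
#' @export
build_scaffolds <- function(terminators, genome) {
  L <- genome$length_bp
  rows <- list()
  for (s in c("+", "-")) {
    tts <- sort(terminators$tts[terminators$strand == s])
    if (!length(tts)) {
      rows[[s]] <- data.frame(strand = s,
                              start = if (s == "+") 1L else L,
                              end = if (s == "+") L else 1L,
                              length_bp = L, full_circle = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    if (s == "-") tts <- rev(tts)     # transcription order: decreasing coords
    n <- length(tts)
    prev <- tts[c(n, seq_len(n - 1L))]  # previous TTS in transcription order
    start <- if (s == "+") wrap_pos(prev + 1L, L) else wrap_pos(prev - 1L, L)
    len <- vapply(seq_len(n), function(i)
      circ_downstream_dist(start[i], tts[i], s, L) + 1, numeric(1))
    rows[[s]] <- data.frame(strand = s, start = start, end = tts,
                            length_bp = as.integer(len), full_circle = FALSE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$scaffold_id <- sprintf("scf_%s_%02d", out$strand,
                             as.integer(stats::ave(seq_len(nrow(out)), out$strand,
                                                   FUN = seq_along)))
  rownames(out) <- NULL
  out[c("scaffold_id", "strand", "start", "end", "length_bp", "full_circle")]
}

# Index of the scaffold containing position pos on strand s.
scaffold_of <- function(pos, s, scaffolds, L) {
  idx <- which(scaffolds$strand == s)
  for (i in idx) {
    d <- circ_downstream_dist(scaffolds$start[i], pos, s, L)
    if (d <= scaffolds$length_bp[i] - 1) return(i)
  }
  NA_integer_
}

# Attribute genes to a TU running from tss to tts on strand s.
attribute_genes <- function(tss, tts, s, genome, exclude_gene = NA_character_,
                            max_utr5 = 500L, per_gene_utr5 = FALSE) {
  g <- genome$genes
  L <- genome$length_bp
  span <- circ_downstream_dist(tss, tts, s, L) + 1
  excl <- if (is.na(exclude_gene)) rep(FALSE, nrow(g)) else g$id == exclude_gene
  cand <- which(g$strand == s & !excl)
  if (!length(cand)) return(NULL)
  g5 <- ifelse(g$strand == "+", g$start, g$end)
  g3 <- ifelse(g$strand == "+", g$end, g$start)
  d5 <- vapply(cand, function(j) circ_downstream_dist(tss, g5[j], s, L), numeric(1))
  d3 <- vapply(cand, function(j) circ_downstream_dist(tss, g3[j], s, L), numeric(1))
  inside <- d3 <= span - 1 & d5 <= d3
  cand <- cand[inside]; d5 <- d5[inside]; d3 <- d3[inside]
  if (!length(cand)) return(NULL)
  ord <- order(d5)
  cand <- cand[ord]; d5 <- d5[ord]; d3 <- d3[ord]
  if (per_gene_utr5) {
    keep <- d5 <= max_utr5
    cand <- cand[keep]; d5 <- d5[keep]; d3 <- d3[keep]
    if (!length(cand)) return(NULL)
  } else if (d5[1] > max_utr5) {
    return(NULL)
  }
  list(ids = g$id[cand], utr5 = d5[1], utr3 = span - 1 - d3[length(d3)],
       leaderless = d5[1] == 0)
}

#' Reconstruct transcription units
#'
#' For each motif-associated TSS, a TU runs from the TSS to the TTS of its
#' term-to-term scaffold. Genes are attributed when completely included in
#' the TU on the same strand; the gene overlapped by an internal TSS is
#' excluded from that TSS's TU; the 5'-UTR of the TU's first attributed gene
#' must not exceed `max_utr5` (set `per_gene_utr5 = TRUE` to apply the bound
#' to every gene instead). TUs with at least one gene are `coding`. A
#' gene-less TU whose TSS faces an antiparallel gene is dropped as an orphan
#' TSS; other gene-less TUs (intergenic TSS just upstream of a terminator,
#' or internal TSS at the end of a unit) are kept as `non-coding`.
#'
#' @param scaffolds [build_scaffolds()] output.
#' @param tss_df annotated TSS table ([annotate_tss()] output `$tss`).
#' @param genome a [genome_annotation()].
#' @param max_utr5 maximal 5'-UTR length (bp).
#' @param per_gene_utr5 apply the UTR bound per attributed gene.
#' @return TU table (see [write_tus_gff()] for the columns); a `leaderless`
#'   flag marks TUs whose first gene starts exactly at the TSS.
#' @export
reconstruct_tus <- function(scaffolds, tss_df, genome, max_utr5 = 500L,
                            per_gene_utr5 = FALSE) {
  L <- genome$length_bp
  use <- tss_df[isTRUE_vec(tss_df$has_motif), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(use))) {
    pos <- use$position[i]; s <- use$strand[i]
    sc <- scaffold_of(pos, s, scaffolds, L)
    if (is.na(sc)) next
    tts <- scaffolds$end[sc]
    att <- attribute_genes(pos, tts, s, genome,
                           exclude_gene = use$overlapping_gene[i],
                           max_utr5 = max_utr5, per_gene_utr5 = per_gene_utr5)
    cls <- use$context_class[i]
    if (is.null(att)) {
      if (startsWith(cls, "a-")) next  # orphan TSS: faces an opposite gene
      rows[[length(rows) + 1L]] <- data.frame(
        tu_id = NA_character_, tss = pos, tts = tts, start = pos, end = tts,
        strand = s, gene_ids = "", utr5_len = NA_integer_,
        utr3_len = NA_integer_, category = "non-coding", tss_class = cls,
        leaderless = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        tu_id = NA_character_, tss = pos, tts = tts, start = pos, end = tts,
        strand = s, gene_ids = paste(att$ids, collapse = ","),
        utr5_len = as.integer(att$utr5), utr3_len = as.integer(att$utr3),
        category = "coding", tss_class = cls, leaderless = att$leaderless,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- empty_tu_table(); out$leaderless <- logical(); return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$tss, out$strand), , drop = FALSE]
  out$tu_id <- sprintf("TU_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Rescue orphan genes with non-motif or upstream-scaffold TSSs
#'
#' Genes covered by no TU are revisited with a two-rule cascade: (1) a TSS
#' without promoter motif in the same scaffold, initiating on a purine, with
#' 5'-UTR within bound; (2) failing that, a TSS located at the end of the
#' previous term-to-term scaffold (separated from the gene by a predicted
#' terminator), provided the gene's expression is non-null and the 5'-UTR is
#' within bound. Candidates are ranked by signal intensity; at most one
#' rescue TU per orphan gene.
#'
#' @param tus TU table from [reconstruct_tus()].
#' @param tss_df full annotated TSS table (motif and non-motif).
#' @param scaffolds [build_scaffolds()] output.
#' @param genome a [genome_annotation()].
#' @param expression optional named per-gene expression vector (rule 2
#'   requires non-null expression).
#' @param max_utr5 maximal 5'-UTR length (bp).
#' @return list with `tus` (input plus rescue TUs, ids `RTU_*`) and
#'   `orphans` (ids of genes still uncovered).
#' @export
rescue_orphans <- function(tus, tss_df, scaffolds, genome, expression = NULL,
                           max_utr5 = 500L) {
  L <- genome$length_bp
  g <- genome$genes
  covered <- unique(unlist(lapply(tus$gene_ids, tu_gene_vector)))
  orphans <- setdiff(g$id, covered)
  new_rows <- list()
  for (gid in orphans) {
    gi <- which(g$id == gid)
    s <- g$strand[gi]
    g5 <- if (s == "+") g$start[gi] else g$end[gi]
    sc_gene <- scaffold_of(g5, s, scaffolds, L)
    if (is.na(sc_gene)) next
    pick <- NULL
    # rule 1: motif-less TSS in the same scaffold, purine +1
    cand <- which(!isTRUE_vec(tss_df$has_motif) & tss_df$strand == s &
                    tss_df$plus_one_base %in% c("A", "G"))
    cand <- cand[vapply(cand, function(j)
      identical(scaffold_of(tss_df$position[j], s, scaffolds, L), sc_gene),
      logical(1))]
    if (length(cand)) {
      d5 <- vapply(cand, function(j)
        circ_downstream_dist(tss_df$position[j], g5, s, L), numeric(1))
      ok <- d5 <= max_utr5 &
        d5 <= circ_downstream_dist(tss_df$position[cand], scaffolds$end[sc_gene], s, L)
      cand <- cand[ok]
      if (length(cand)) {
        pick <- cand[order(-tss_df$raw_count[cand])][1]
        rule <- "rescue-nonmotif"
      }
    }
    # rule 2: TSS at the end of the previous scaffold, expressed gene
    if (is.null(pick) && !is.null(expression) &&
        !is.na(expression[gid]) && expression[gid] > 0) {
      prev_end <- wrap_pos(if (s == "+") scaffolds$start[sc_gene] - 1L else
        scaffolds$start[sc_gene] + 1L, L)
      sc_prev <- scaffold_of(prev_end, s, scaffolds, L)
      if (!is.na(sc_prev) && sc_prev != sc_gene) {
        cand <- which(tss_df$strand == s)
        cand <- cand[vapply(cand, function(j)
          identical(scaffold_of(tss_df$position[j], s, scaffolds, L), sc_prev),
          logical(1))]
        if (length(cand)) {
          d5 <- vapply(cand, function(j)
            circ_downstream_dist(tss_df$position[j], g5, s, L), numeric(1))
          cand <- cand[d5 <= max_utr5]
          if (length(cand)) {
            pick <- cand[order(-tss_df$raw_count[cand])][1]
            rule <- "rescue-readthrough"
          }
        }
      }
    }
    if (is.null(pick)) next
    pos <- tss_df$position[pick]
    tts <- scaffolds$end[sc_gene]
    att <- attribute_genes(pos, tts, s, genome,
                           exclude_gene = tss_df$overlapping_gene[pick],
                           max_utr5 = max_utr5)
    if (is.null(att) || !(gid %in% att$ids)) next
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      tu_id = NA_character_, tss = pos, tts = tts, start = pos, end = tts,
      strand = s, gene_ids = paste(att$ids, collapse = ","),
      utr5_len = as.integer(att$utr5), utr3_len = as.integer(att$utr3),
      category = rule, tss_class = tss_df$context_class[pick],
      leaderless = att$leaderless, stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    add <- add[!duplicated(add[c("tss", "strand", "gene_ids")]), , drop = FALSE]
    add$tu_id <- sprintf("RTU_%03d", seq_len(nrow(add)))
    tus <- rbind(tus, add)
  }
  covered <- unique(unlist(lapply(tus$gene_ids, tu_gene_vector)))
  list(tus = tus, orphans = setdiff(g$id, covered))
}

#' Transcription-unit summary statistics
#'
#' @param tus TU table.
#' @param genome a [genome_annotation()] (for circular TU lengths).
#' @return list: genes-per-TU distribution, mean and max; mean TU length;
#'   mean UTR lengths; genes covered; TUs-per-gene distribution; TU share by
#'   TSS class. All zero (with a warning) on an empty table.
#' @export
tu_statistics <- function(tus, genome) {
  if (!nrow(tus)) {
    warning("empty TU list; all-zero summary")
    return(list(n_tus = 0, genes_per_tu = table(integer()), mean_genes_per_tu = 0,
                max_genes_per_tu = 0, mean_length_bp = 0, mean_utr5 = 0,
                mean_utr3 = 0, genes_covered = 0, tus_per_gene = table(integer()),
                tss_class_share = table(character())))
  }
  L <- genome$length_bp
  glist <- lapply(tus$gene_ids, tu_gene_vector)
  ngenes <- lengths(glist)
  coding <- ngenes > 0
  span <- vapply(seq_len(nrow(tus)), function(i)
    circ_downstream_dist(tus$start[i], tus$end[i], tus$strand[i], L) + 1,
    numeric(1))
  all_genes <- unlist(glist)
  list(
    n_tus = nrow(tus),
    genes_per_tu = table(ngenes[coding]),
    mean_genes_per_tu = mean(ngenes[coding]),
    max_genes_per_tu = max(ngenes),
    mean_length_bp = mean(span[coding]),
    mean_utr5 = mean(tus$utr5_len[coding], na.rm = TRUE),
    mean_utr3 = mean(tus$utr3_len[coding], na.rm = TRUE),
    genes_covered = length(unique(all_genes)),
    tus_per_gene = table(table(all_genes)),
    tss_class_share = table(tus$tss_class[coding]) / sum(coding)
  )
}

#' Anchor-aligned aggregate signal profile
#'
#' Single-reference mode (`n_bins = NULL`, point anchors): the mean and SEM of
#' the strand-matched track over `position - flank .. position + flank` in
#' transcription direction. Two-reference mode (interval anchors plus
#' `n_bins`): upstream flank, interior linearly rescaled to `n_bins` bins,
#' downstream flank.
#'
#' @param signal a [strand_signal()].
#' @param anchors data.frame with `start`, `strand` (plus `end` for
#'   two-reference mode).
#' @param genome a [genome_annotation()] (length, topology).
#' @param flank flank size in bp.
#' @param n_bins interior bin count for two-reference mode.
#' @return data.frame with `bin`, `rel_pos` (NA in the rescaled interior),
#'   `mean`, `sem`, `zone` (up/interior/down).
#' @export
meta_profile <- function(signal, anchors, genome, flank = 100L, n_bins = NULL) {
  if (!nrow(anchors)) stop("anchors must be non-empty")
  L <- genome$length_bp
  track <- function(s) if (s == "+") signal$plus else signal$minus
  oriented <- function(pos, len, s) {
    idx <- if (s == "+") seq.int(pos, pos + len - 1L) else seq.int(pos, pos - len + 1L)
    if (any(idx < 1L | idx > L)) {
      if (!genome$circular) return(NULL)
      idx <- wrap_pos(idx, L)
    }
    track(s)[idx]
  }
  two_ref <- !is.null(n_bins) && "end" %in% names(anchors)
  mats <- list()
  for (i in seq_len(nrow(anchors))) {
    s <- anchors$strand[i]; a <- anchors$start[i]
    if (two_ref) {
      b <- anchors$end[i]
      span <- circ_downstream_dist(a, b, s, L) + 1
      up <- oriented(if (s == "+") a - flank else a + flank, flank, s)
      interior <- oriented(a, span, s)
      down <- oriented(if (s == "+") b + 1L else b - 1L, flank, s)
      if (is.null(up) || is.null(interior) || is.null(down)) {
        warning("anchor flank beyond linear contig; skipped"); next
      }
      sel <- interior[pmin(span, floor((seq_len(n_bins) - 0.5) / n_bins * span) + 1L)]
      mats[[length(mats) + 1L]] <- c(up, sel, down)
    } else {
      row <- oriented(if (s == "+") a - flank else a + flank, 2L * flank + 1L, s)
      if (is.null(row)) { warning("anchor flank beyond linear contig; skipped"); next }
      mats[[length(mats) + 1L]] <- row
    }
  }
  if (!length(mats)) stop("no usable anchors")
  m <- do.call(rbind, mats)
  mu <- colMeans(m)
  sem <- apply(m, 2, function(x) stats::sd(x) / sqrt(length(x)))
  if (two_ref) {
    zone <- c(rep("up", flank), rep("interior", n_bins), rep("down", flank))
    rel <- c(seq(-flank, -1L), rep(NA_integer_, n_bins), seq_len(flank))
  } else {
    zone <- rep("point", 2L * flank + 1L)
    rel <- seq(-flank, flank)
  }
  data.frame(bin = seq_along(mu), rel_pos = rel, mean = mu, sem = sem,
             zone = zone, stringsAsFactors = FALSE)
}
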