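# Conversion of expression measurements and biomass masses into absolute
# molecular abundances: FPKM / NSAF normalisation, molecular weights from
# sequence, chromosome copy number, RNA class partition, expression-weighted
# mass fractions -> copies per cell, complex counts and concentrations.

AVOGADRO <- 6.02214076e23
FG_PER_G <- 1e15

# average masses (Da); residue = monomer contribution inside the polymer
DNA_RESIDUE_MW <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.2)
DNA_LINEAR_END <- -61.96          # per strand, linear molecules
RNA_RESIDUE_MW <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17, T = 306.17)
RNA_5P_END <- 159.0               # 5'-triphosphate convention
AA_RESIDUE_MW <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MW <- 18.02

count_letters <- function(seq, letters) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !chars %in% letters
  if (any(bad)) {
    stop("unexpected letter(s) at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  table(factor(chars, levels = letters))
}

#' Molecular weight of a DNA molecule
#'
#' Average-mass formula: sum of residue masses per strand, minus a terminal
#' correction per strand for linear molecules (none for circles). For
#' double-stranded DNA the complementary strand is included.
#'
#' @param seq sequence of one strand (A/C/G/T).
#' @param double_stranded include the complementary strand.
#' @param circular circular molecule (no terminal correction).
#' @return molecular weight in Da.
#' @export
dna_mw <- function(seq, double_stranded = TRUE, circular = TRUE) {
  n <- count_letters(seq, names(DNA_RESIDUE_MW))
  mw <- sum(n * DNA_RESIDUE_MW[names(n)])
  if (double_stranded) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    n2 <- n[c("T", "G", "C", "A")]  # complement counts
    names(n2) <- names(n)
    mw <- mw + sum(n2 * DNA_RESIDUE_MW[names(n2)])
  }
  strands <- if (double_stranded) 2 else 1
  if (!circular) mw <- mw + strands * DNA_LINEAR_END
  unname(mw)
}

#' Molecular weight of an RNA molecule
#'
#' Average-mass residue sum plus a 5'-triphosphate terminal correction.
#' `T` in the input is read as `U`.
#'
#' @param seq RNA (or DNA template of the transcript) sequence.
#' @return molecular weight in Da.
#' @export
rna_mw <- function(seq) {
  n <- count_letters(seq, names(RNA_RESIDUE_MW))
  unname(sum(n * RNA_RESIDUE_MW[names(n)]) + RNA_5P_END)
}

#' Molecular weight of a protein
#'
#' Average residue masses plus one water (peptide condensation convention);
#' a single free amino acid G gives 75.07 Da.
#'
#' @param seq one-letter amino-acid sequence.
#' @return molecular weight in Da.
#' @export
protein_mw <- function(seq) {
  n <- count_letters(seq, names(AA_RESIDUE_MW))
  unname(sum(n * AA_RESIDUE_MW[names(n)]) + WATER_MW)
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length * total)`, averaged over replicates.
#'
#' @param counts data.frame with columns `gene_id`, `rep`, `count` (e.g.
#'   [simulate_rnaseq()] output) or a gene x replicate matrix.
#' @param lengths named vector of gene lengths (nt).
#' @param totals optional named/per-replicate totals of mapped fragments;
#'   defaults to per-replicate column sums.
#' @return named vector of mean FPKM per gene.
#' @export
fpkm <- function(counts, lengths, totals = NULL) {
  if (is.data.frame(counts)) {
    m <- stats::xtabs(count ~ gene_id + rep, data = counts)
    m <- m[, , drop = FALSE]
  } else {
    m <- as.matrix(counts)
  }
  if (is.null(totals)) totals <- colSums(m)
  if (any(totals <= 0)) stop("replicate totals must be > 0")
  len <- lengths[rownames(m)]
  if (any(is.na(len)) || any(len <= 0)) stop("missing or non-positive gene length")
  f <- sweep(m, 2, totals, "/") * 1e9 / len
  rowMeans(f)
}

#' Normalised spectral abundance factor
#'
#' `NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j)`; undetected proteins get 0.
#'
#' @param spc named vector of spectral counts.
#' @param lengths named vector of protein lengths (aa).
#' @return named NSAF vector summing to 1.
#' @export
nsaf <- function(spc, lengths) {
  if (sum(spc) <= 0) stop("all spectral counts are zero")
  saf <- spc / lengths[names(spc)]
  saf / sum(saf)
}

#' Chromosome copies per cell
#'
#' `copies = mass * N_A / MW` with femtogram-to-gram conversion.
#'
#' @param dna_mass_fg DNA mass per cell (fg).
#' @param chrom_mw_da chromosome molecular weight (Da).
#' @return copy number.
#' @export
chromosome_copies <- function(dna_mass_fg, chrom_mw_da) {
  if (dna_mass_fg <= 0 || chrom_mw_da <= 0) stop("inputs must be > 0")
  dna_mass_fg / FG_PER_G * AVOGADRO / chrom_mw_da
}

#' Partition total RNA mass into classes
#'
#' Default split: 80% rRNA, 15% tRNA, 5% mRNA (the conserved bacterial
#' proportions).
#'
#' @param total_rna_fg total RNA mass (fg/cell).
#' @param fractions named fractions summing to at most 1.
#' @return named masses (fg).
#' @export
rna_class_partition <- function(total_rna_fg,
                                fractions = c(rRNA = 0.80, tRNA = 0.15, mRNA = 0.05)) {
  if (sum(fractions) > 1 + 1e-9) stop("fractions sum to more than 1")
  total_rna_fg * fractions
}

#' Molecule counts for equimolar species sharing a class mass
#'
#' Assuming all species of a class are present in equimolar amounts (e.g.
#' 5S/16S/23S rRNA), the per-set count is `n = mass * N_A / sum(MW)` and the
#' total molecule count is `n * n_species`.
#'
#' @param class_mass_fg class mass (fg/cell).
#' @param species_mw_da molecular weights of the species (Da).
#' @return list with `per_set`, `total`, `n_species`.
#' @export
equimolar_counts <- function(class_mass_fg, species_mw_da) {
  if (!length(species_mw_da)) stop("empty species list")
  per_set <- class_mass_fg / FG_PER_G * AVOGADRO / sum(species_mw_da)
  list(per_set = per_set, total = per_set * length(species_mw_da),
       n_species = length(species_mw_da))
}

#' Expression-weighted absolute copy numbers
#'
#' Expression values are normalised to relative expression, converted to
#' mass fractions via the species molecular weights, multiplied by the class
#' mass, and divided by the molecular weight (times Avogadro) to give copies
#' per cell. Mass is conserved: the per-species masses sum to `class_mass_fg`
#' exactly.
#'
#' @param x named expression values (FPKM or NSAF; sum must be > 0).
#' @param mw named molecular weights (Da), same names as `x`.
#' @param class_mass_fg total class mass (fg/cell).
#' @return data.frame with `id`, `rel_expr`, `mass_fraction`, `mass_fg`,
#'   `copies`.
#' @export
copies_from_expression <- function(x, mw, class_mass_fg) {
  if (class_mass_fg <= 0) stop("class mass must be > 0")
  if (sum(x) <= 0) stop("expression values sum to zero")
  mw <- mw[names(x)]
  if (any(is.na(mw))) stop("missing molecular weight")
  rel <- x / sum(x)
  w <- rel * mw
  frac <- w / sum(w)
  mass <- frac * class_mass_fg
  copies <- mass / FG_PER_G * AVOGADRO / mw
  data.frame(id = names(x), rel_expr = unname(rel),
             mass_fraction = unname(frac), mass_fg = unname(mass),
             copies = unname(copies), stringsAsFactors = FALSE)
}

#' Complex count from subunit copy numbers and stoichiometry
#'
#' `count = mean over subunits of copies / stoichiometry` (e.g. RNA
#' polymerase core: two alpha, one beta, one beta-prime).
#'
#' @param copies named per-subunit copies.
#' @param stoich named stoichiometry (subunits per complex).
#' @return complex count.
#' @export
complex_counts <- function(copies, stoich) {
  missing_sub <- setdiff(names(stoich), names(copies))
  if (length(missing_sub)) {
    stop("missing subunit(s): ", paste(missing_sub, collapse = ", "))
  }
  mean(copies[names(stoich)] / stoich)
}

#' Concentration over the most probable volume window
#'
#' Point estimate at the volume-window midpoint; bounds at the window edges.
#'
#' @param copies molecules per cell.
#' @param volume_range c(min, max) cell volume (um^3).
#' @return list with `midpoint` (copies/um^3), `bounds`, `volume_midpoint`.
#' @export
concentration <- function(copies, volume_range) {
  if (any(volume_range <= 0)) stop("volume must be > 0")
  vmid <- mean(volume_range)
  list(midpoint = copies / vmid,
       bounds = sort(copies / volume_range),
       volume_midpoint = vmid)
}

#' Per-category shares of molecules and mass
#'
#' @param category_map data.frame with columns `gene_id`, `category`; every
#'   gene at most once (unmapped genes are pooled into `"unmapped"`).
#' @param copies named per-gene copy numbers.
#' @param masses named per-gene masses (fg).
#' @return data.frame with per-category `share_molecules_pct` and
#'   `share_mass_pct`, summing to 100 each.
#' @export
category_fractions <- function(category_map, copies, masses) {
  if (anyDuplicated(category_map$gene_id)) stop("duplicate gene in category map")
  cat <- stats::setNames(category_map$category, category_map$gene_id)
  ids <- names(copies)
  assigned <- ifelse(ids %in% names(cat), cat[ids], "unmapped")
  mol <- tapply(copies, assigned, sum)
  mas <- tapply(masses[ids], assigned, sum)
  data.frame(category = names(mol),
             share_molecules_pct = 100 * as.numeric(mol) / sum(copies),
             share_mass_pct = 100 * as.numeric(mas) / sum(masses[ids]),
             stringsAsFactors = FALSE)
}

#' Assemble a whole-cell molecular budget
#'
#' Collects per-class molecule counts into one summary, derives the second
#' ribosome estimate (all rRNA incorporated into ribosomes: one third of the
#' rRNA molecules, three rRNAs per ribosome), and normalises every count by
#' the most probable cell volume window.
#'
#' @param chromosome_copies,rrna_molecules,trna_molecules,mrna_molecules,protein_molecules
#'   per-cell counts.
#' @param ribosomes_from_proteins ribosome estimate (i), from mean ribosomal
#'   protein copies (NA when unavailable).
#' @param rnap_cores,sigma70_copies RNA polymerase core and sigma-factor
#'   counts (NA when unavailable).
#' @param volume_range most probable cell-volume window (um^3).
#' @return object of class `molecular_budget`: the counts, the two ribosome
#'   estimates, and `concentrations` (per um^3, volume-window midpoint).
#' @export
molecular_budget <- function(chromosome_copies, rrna_molecules, trna_molecules,
                             mrna_molecules, protein_molecules,
                             ribosomes_from_proteins = NA_real_,
                             rnap_cores = NA_real_, sigma70_copies = NA_real_,
                             volume_range) {
  counts <- c(chromosome = chromosome_copies, rRNA = rrna_molecules,
              tRNA = trna_molecules, mRNA = mrna_molecules,
              protein = protein_molecules)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  conc <- vapply(counts, function(x) concentration(x, volume_range)$midpoint,
                 numeric(1))
  structure(list(
    counts = counts,
    ribosomes = c(from_proteins = ribosomes_from_proteins,
                  from_rrna = rrna_molecules / 3),
    rnap_cores = rnap_cores, sigma70_copies = sigma70_copies,
    volume_range = volume_range, concentrations = conc
  ), class = "molecular_budget")
}

#' @export
print.molecular_budget <- function(x, ...) {
  cat("<molecular_budget> per cell:\n")
  print(round(x$counts, 1))
  cat(sprintf("ribosomes: %.0f (proteins) / %.0f (rRNA/3); RNAP cores: %.0f; sigma70: %.0f\n",
              x$ribosomes[1], x$ribosomes[2], x$rnap_cores, x$sigma70_copies))
  cat("concentrations per um^3 (volume midpoint", mean(x$volume_range), "):\n")
  print(signif(x$concentrations, 2))
  invisible(x)
}

#' Write a molecular budget (or any list of results) as JSON
#' @param x a `molecular_budget` or plain list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_budget_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
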