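# Cell geometry and mass-balance equations.
#
# Units are fixed internally to micrometres and femtograms; densities given in
# g/ml convert as 1 g/ml == 1000 fg/um^3. All four mean cell-mass curves are
# functions of the (spherical) cell diameter d; the most probable diameter and
# mass window is read off the pairwise intersections of the mean curves.

G_PER_ML_TO_FG_PER_UM3 <- 1000

#' Sphere geometry
#'
#' Volume, surface area and surface-area-to-volume ratio of a sphere of
#' diameter `d` (micrometres). `sa_to_v(d) == 6 / d`.
#'
#' @param d diameter in micrometres (vectorised). Must be `>= 0`
#'   (`> 0` for `sa_to_v`).
#' @return volume in um^3, area in um^2, or SA:V in 1/um.
#' @export
sphere_volume <- function(d) {
  if (any(d < 0)) stop("diameter must be non-negative")
  pi * d^3 / 6
}

#' @rdname sphere_volume
#' @export
sphere_area <- function(d) {
  if (any(d < 0)) stop("diameter must be non-negative")
  pi * d^2
}

#' @rdname sphere_volume
#' @export
sa_to_v <- function(d) {
  if (any(d <= 0)) stop("diameter must be positive")
  sphere_area(d) / sphere_volume(d)
}

#' Physical cell parameters
#'
#' The measured/assumed quantities feeding the cell-mass equations: buoyant
#' density range `D` (g/ml), dry mass `DM` (mean and sd, fg), dry-mass
#' fraction range `DF` (dimensionless), and dry-mass-specific density range
#' `D_DM` (g/ml). Defaults are the measured values for an exponential-phase
#' near-minimal Mollicute: density between 1.05 and 1.08 g/ml, dry mass
#' 22.1 +/- 4.2 fg, and the typical bacterial ranges 20-30% and 1.3-1.5 g/ml
#' for the dry-mass fraction and dry-mass-specific density.
#'
#' @param D length-2 buoyant density range (g/ml).
#' @param DM c(mean, sd) dry mass (fg).
#' @param DF length-2 dry-mass fraction range in (0, 1).
#' @param D_DM length-2 dry-mass-specific density range (g/ml).
#' @param rho_water density of cell water (g/ml).
#' @return object of class `cell_phys_params`.
#' @export
cell_phys_params <- function(D = c(1.05, 1.08), DM = c(22.1, 4.2),
                             DF = c(0.20, 0.30), D_DM = c(1.3, 1.5),
                             rho_water = 1.0) {
  chk_range <- function(x, nm) {
    if (length(x) != 2 || any(x <= 0) || x[1] > x[2])
      stop(nm, " must be a positive (min, max) range")
  }
  chk_range(D, "D"); chk_range(D_DM, "D_DM")
  chk_range(DF, "DF")
  if (any(DF >= 1)) stop("DF must lie in (0, 1)")
  if (length(DM) != 2 || DM[1] <= 0 || DM[2] < 0)
    stop("DM must be c(mean, sd) with positive mean")
  structure(list(D = D, DM = DM, DF = DF, D_DM = D_DM, rho_water = rho_water),
            class = "cell_phys_params")
}

#' Cell-mass curves CM(d)
#'
#' Builds the four cell-mass relations as functions of the diameter:
#' \describe{
#'   \item{eq4}{`CM = V(d) * D` (buoyant mass).}
#'   \item{eq5}{`CM = DM / DF` (constant in d).}
#'   \item{eq6}{`CM = (V - DM/D_DM) * rho_w + DM` (water mass + dry mass,
#'     water volume = total volume minus dry-matter volume).}
#'   \item{eq7}{as eq6 with the dry mass substituted by `V * D * DF`.}
#' }
#' For each equation the mean curve uses parameter means and the min/max
#' curves use the range (or mean +/- sd) extremes. Diameters at which the
#' water volume in eq6 would be negative are flagged `NA` (curve undefined
#' there), not an error.
#'
#' @param params a [cell_phys_params()].
#' @return named list of four functions; each takes a diameter vector (um) and
#'   returns a data.frame with columns `min`, `mean`, `max` (fg).
#' @export
cell_mass_curves <- function(params) {
  stopifnot(inherits(params, "cell_phys_params"))
  k <- G_PER_ML_TO_FG_PER_UM3
  D <- params$D * k            # fg/um^3
  DMm <- params$DM[1]; DMs <- params$DM[2]
  DMrng <- c(DMm - DMs, DMm + DMs)
  DF <- params$DF
  DDM <- params$D_DM * k
  rho <- params$rho_water * k

  eq4 <- function(d) {
    V <- sphere_volume(d)
    data.frame(min = V * D[1], mean = V * mean(D), max = V * D[2])
  }
  eq5 <- function(d) {
    n <- length(d)
    data.frame(min = rep(DMrng[1] / DF[2], n),
               mean = rep(DMm / mean(DF), n),
               max = rep(DMrng[2] / DF[1], n))
  }
  eq6_val <- function(V, DMv, DDMv) {
    Vw <- V - DMv / DDMv
    out <- Vw * rho + DMv
    out[Vw < 0] <- NA_real_
    out
  }
  eq6 <- function(d) {
    V <- sphere_volume(d)
    combos <- expand.grid(DM = DMrng, DDM = DDM)
    vals <- mapply(function(dm, dd) eq6_val(V, dm, dd), combos$DM, combos$DDM)
    vals <- matrix(vals, nrow = length(V))
    data.frame(min = apply(vals, 1, min),
               mean = eq6_val(V, DMm, mean(DDM)),
               max = apply(vals, 1, max))
  }
  eq7_val <- function(V, Dv, DFv, DDMv) {
    DMv <- V * Dv * DFv
    eq6_val(V, DMv, DDMv)
  }
  eq7 <- function(d) {
    V <- sphere_volume(d)
    combos <- expand.grid(D = D, DF = DF, DDM = DDM)
    vals <- mapply(function(dv, f, dd) eq7_val(V, dv, f, dd),
                   combos$D, combos$DF, combos$DDM)
    vals <- matrix(vals, nrow = length(V))
    data.frame(min = apply(vals, 1, min),
               mean = eq7_val(V, mean(D), mean(DF), mean(DDM)),
               max = apply(vals, 1, max))
  }
  list(eq4 = eq4, eq5 = eq5, eq6 = eq6, eq7 = eq7)
}

# Bisection refinement of a sign change of f between lo and hi.
refine_root <- function(f, lo, hi, tol = 1e-6) {
  flo <- f(lo)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (!is.finite(fm)) return(NA_real_)
    if (hi - lo < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Most probable cell diameter / mass window
#'
#' Computes all pairwise intersections of the four mean cell-mass curves over
#' a diameter scan range, refined by bisection to `|delta d| < 1e-6` um. The
#' most probable diameter and mass ranges are the min/max over the
#' intersection coordinates; volume, area and SA:V windows are derived from
#' the diameter range.
#'
#' @param params a [cell_phys_params()].
#' @param d_range scan range in um.
#' @param n_grid grid density for bracketing sign changes.
#' @return object of class `phys_window`: list with `d_range` (um),
#'   `d_range_nm`, `mass_range` (fg), `volume_range` (um^3), `area_range`
#'   (um^2), `sav_range` (1/um) and the `intersections` table.
#' @export
most_probable_window <- function(params = cell_phys_params(),
                                 d_range = c(0.2, 1.2), n_grid = 2001L) {
  curves <- cell_mass_curves(params)
  grid <- seq(d_range[1], d_range[2], length.out = n_grid)
  means <- lapply(curves, function(f) f(grid)$mean)
  pairs <- utils::combn(names(curves), 2, simplify = FALSE)
  hits <- list(); diag <- character()
  for (p in pairs) {
    diffg <- means[[p[1]]] - means[[p[2]]]
    ok <- is.finite(diffg)
    sgn <- sign(diffg)
    cross <- which(ok[-1] & ok[-n_grid] & sgn[-1] * sgn[-n_grid] < 0)
    if (!length(cross)) {
      z <- which(ok & diffg == 0)
      if (length(z)) cross <- z  # tangential contact on the grid
      else { diag <- c(diag, sprintf("%s vs %s: no crossing", p[1], p[2])); next }
    }
    f <- function(d) curves[[p[1]]](d)$mean - curves[[p[2]]](d)$mean
    for (i in cross) {
      d_star <- if (i <= n_grid - 1 && sign(diffg[i]) * sign(diffg[i + 1]) < 0)
        refine_root(f, grid[i], grid[i + 1]) else grid[i]
      if (is.na(d_star)) next
      hits[[length(hits) + 1L]] <- data.frame(
        pair = paste(p, collapse = ":"), d = d_star,
        cm = curves[[p[1]]](d_star)$mean)
    }
  }
  if (length(hits) < 2) {
    stop("fewer than 2 mean-curve intersections in scan range; ",
         paste(diag, collapse = "; "))
  }
  its <- do.call(rbind, hits)
  d_rng <- range(its$d)
  mass_rng <- range(its$cm)
  structure(list(
    d_range = d_rng,
    d_range_nm = d_rng * 1000,
    mass_range = mass_rng,
    volume_range = sphere_volume(d_rng),
    area_range = sphere_area(d_rng),
    sav_range = sort(sa_to_v(d_rng)),
    intersections = its,
    no_crossing = diag
  ), class = "phys_window")
}

#' @export
print.phys_window <- function(x, ...) {
  cat(sprintf(paste0(
    "<phys_window>\n  diameter: %.0f-%.0f nm\n  mass:     %.1f-%.1f fg\n",
    "  volume:   %.3f-%.3f um^3\n  area:     %.3f-%.3f um^2\n",
    "  SA:V:     %.1f-%.1f um^-1\n"),
    x$d_range_nm[1], x$d_range_nm[2], x$mass_range[1], x$mass_range[2],
    x$volume_range[1], x$volume_range[2], x$area_range[1], x$area_range[2],
    x$sav_range[1], x$sav_range[2]))
  invisible(x)
}

#' Biomass panel
#'
#' Per-class macromolecule masses (fg/cell) plus the measured total dry mass.
#' Defaults are the measured composition of the exponential-phase cell: dry
#' mass 22.1 fg with proteins 10.3, RNA 4.9, lipids 4.0, DNA 1.7 and
#' carbohydrates 0.9 fg; the carbohydrate pool split into galactose 0.50,
#' glucose 0.19, rhamnose 0.18 and mannose 0.04 fg.
#'
#' @param masses named numeric vector of class masses (fg/cell).
#' @param dry_mass total dry mass (fg/cell).
#' @param carbohydrate_species named numeric vector of per-sugar masses (fg).
#' @return object of class `biomass_panel`.
#' @export
biomass_panel <- function(masses = c(protein = 10.3, rna = 4.9, lipid = 4.0,
                                     dna = 1.7, carbohydrate = 0.9),
                          dry_mass = 22.1,
                          carbohydrate_species = c(galactose = 0.50,
                                                   glucose = 0.19,
                                                   rhamnose = 0.18,
                                                   mannose = 0.04)) {
  if (any(masses < 0) || dry_mass <= 0) stop("masses must be non-negative, dry_mass > 0")
  if (sum(masses) > dry_mass * 1.05) {
    stop("sum of class masses exceeds dry mass beyond tolerance")
  }
  structure(list(masses = masses, dry_mass = dry_mass,
                 carbohydrate_species = carbohydrate_species),
            class = "biomass_panel")
}

#' Biomass fractions of the dry mass
#'
#' `fraction = 100 * mass / dry_mass` per macromolecule class, with the
#' residual ("other") mass obtained by subtracting all quantified classes from
#' the total dry mass. A residual more negative than 5% of the dry mass
#' triggers a warning and is clamped to 0.
#'
#' @param panel a [biomass_panel()].
#' @return data.frame with columns `class`, `mass_fg`, `fraction_pct`,
#'   including the residual `other` row.
#' @export
biomass_fractions <- function(panel) {
  stopifnot(inherits(panel, "biomass_panel"))
  m <- panel$masses
  residual <- panel$dry_mass - sum(m)
  if (residual < -1e-9 * panel$dry_mass) {
    warning("negative residual beyond tolerance; reported as 0")
  }
  residual <- max(residual, 0)
  out <- data.frame(class = c(names(m), "other"),
                    mass_fg = c(unname(m), residual),
                    stringsAsFactors = FALSE)
  out$fraction_pct <- 100 * out$mass_fg / panel$dry_mass
  out
}

#' Carbohydrate composition
#'
#' Per-sugar fraction of the total carbohydrate mass, computed over the sum of
#' the measured sugar masses (not over the rounded class total).
#'
#' @param panel a [biomass_panel()].
#' @return data.frame with columns `sugar`, `mass_fg`, `fraction_pct`.
#' @export
carb_composition <- function(panel) {
  stopifnot(inherits(panel, "biomass_panel"))
  s <- panel$carbohydrate_species
  if (!length(s) || all(s == 0)) stop("no non-zero sugar masses")
  data.frame(sugar = names(s), mass_fg = unname(s),
             fraction_pct = 100 * unname(s) / sum(s),
             stringsAsFactors = FALSE)
}
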