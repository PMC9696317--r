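#' Specify a unilamellar vesicle's geometry
#'
#' @param outer_diameter Outer diameter in nm,
#'   \code{> 2 * bilayer_thickness}.
#' @param bilayer_thickness Bilayer thickness in nm (default 5, typical for
#'   a fluid phosphatidylcholine membrane).
#' @param area_per_lipid Mean headgroup area per lipid in nm\eqn{^2}
#'   (default 0.71 for fluid PC).
#' @return Object of class \code{"vesicle_spec"}.
#' @examples
#' vesicle_spec(110)
#' @export
vesicle_spec <- function(outer_diameter, bilayer_thickness = 5,
                         area_per_lipid = 0.71) {
  if (outer_diameter <= 0 || bilayer_thickness <= 0 || area_per_lipid <= 0)
    stop("vesicle parameters must be positive", call. = FALSE)
  if (outer_diameter <= 2 * bilayer_thickness)
    stop("outer_diameter must exceed twice the bilayer thickness",
         call. = FALSE)
  structure(list(outer_diameter = outer_diameter,
                 bilayer_thickness = bilayer_thickness,
                 area_per_lipid = area_per_lipid),
            class = "vesicle_spec")
}

#' Specify an adsorbed protein's footprint
#'
#' Serum albumin is modelled as a 14 x 4 x 4 nm ellipsoid of revolution;
#' the two footprint axes are those of the ellipse it presents to the
#' membrane (14 x 4 side-on, 4 x 4 end-on).
#'
#' @param axis_a,axis_b Footprint axes in nm.
#' @param molar_mass Protein molar mass in g/mol (default 66,430 for BSA).
#' @return Object of class \code{"protein_footprint"}.
#' @export
protein_footprint <- function(axis_a = 14, axis_b = 4, molar_mass = 66430) {
  if (axis_a <= 0 || axis_b <= 0 || molar_mass <= 0)
    stop("footprint parameters must be positive", call. = FALSE)
  structure(list(axis_a = axis_a, axis_b = axis_b, molar_mass = molar_mass),
            class = "protein_footprint")
}

#' Surface area of a sphere
#'
#' @param diameter Diameter in nm, \code{> 0}.
#' @return Surface area \eqn{4\pi (d/2)^2} in nm\eqn{^2}.
#' @examples
#' sphere_surface_area(110)  # ~38,000 nm^2
#' @export
sphere_surface_area <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be > 0", call. = FALSE)
  4 * pi * (diameter / 2)^2
}

#' Number of lipid molecules in a unilamellar vesicle
#'
#' Outer plus inner leaflet areas divided by the area per lipid, rounded
#' to the nearest integer:
#' \deqn{N = [4\pi(d/2)^2 + 4\pi(d/2 - h)^2] / a}
#'
#' @param v A \code{\link{vesicle_spec}}.
#' @return Lipid count (integer-valued numeric).
#' @examples
#' lipids_per_vesicle(vesicle_spec(110))  # ~97,700
#' @export
lipids_per_vesicle <- function(v) {
  stopifnot(inherits(v, "vesicle_spec"))
  r_out <- v$outer_diameter / 2
  r_in <- r_out - v$bilayer_thickness
  if (r_in < 0) stop("inner radius must be >= 0", call. = FALSE)
  round((4 * pi * r_out^2 + 4 * pi * r_in^2) / v$area_per_lipid)
}

#' Theoretical protein capacity of a vesicle surface
#'
#' How many protein molecules of elliptical footprint
#' \eqn{\pi \cdot a \cdot b} fit on the sphere's surface (floored):
#' \deqn{N = \lfloor 4\pi(d/2)^2 / (\pi a b) \rfloor}
#' With the printed footprint axes entering the ellipse area directly,
#' this reproduces both the side-on (~216 for 14 x 4) and end-on (~756 for
#' 4 x 4) monolayer capacities of a 110 nm vesicle.
#'
#' @param diameter Vesicle diameter in nm.
#' @param fp A \code{\link{protein_footprint}}.
#' @return Protein count (floored).
#' @examples
#' protein_surface_capacity(110, protein_footprint(14, 4))  # 216
#' protein_surface_capacity(110, protein_footprint(4, 4))   # 756
#' @export
protein_surface_capacity <- function(diameter, fp = protein_footprint()) {
  stopifnot(inherits(fp, "protein_footprint"))
  if (diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  floor(sphere_surface_area(diameter) / (pi * fp$axis_a * fp$axis_b))
}

#' Bound protein molecules per vesicle from a P_B value
#'
#' P_B is grams of bound protein per mole of liposomal lipid; combined
#' with the lipid count of one vesicle and the protein molar mass it gives
#' the adsorbed stoichiometry:
#' \deqn{N_{protein} = P_B \times N_{lipids} / M_{protein}}
#'
#' @param p_b Protein binding value in g protein / mol lipid, \code{>= 0}.
#' @param v A \code{\link{vesicle_spec}}.
#' @param fp A \code{\link{protein_footprint}} (supplies the molar mass).
#' @return Protein molecules per vesicle (fractional).
#' @examples
#' bound_protein_per_vesicle(4.72, vesicle_spec(121.3))  # ~8.5
#' @export
bound_protein_per_vesicle <- function(p_b, v, fp = protein_footprint()) {
  if (any(p_b < 0)) stop("p_b must be >= 0", call. = FALSE)
  p_b * lipids_per_vesicle(v) / fp$molar_mass
}

#' P_B from measured concentrations
#'
#' @param protein Protein mass concentration in g/L.
#' @param lipid Lipid molar concentration in mol/L, \code{> 0}.
#' @return P_B in g protein / mol lipid.
#' @export
pb_from_concentrations <- function(protein, lipid) {
  if (any(lipid <= 0)) stop("lipid concentration must be > 0", call. = FALSE)
  protein / lipid
}

#' Stoichiometry table from per-sample diameters and P_B values
#'
#' Convenience wrapper applying \code{\link{lipids_per_vesicle}} and
#' \code{\link{bound_protein_per_vesicle}} row-wise to a table of samples.
#'
#' @param df Data frame with columns \code{sample}, \code{diameter} (nm)
#'   and \code{p_b} (g/mol).
#' @param bilayer_thickness,area_per_lipid Geometry constants passed to
#'   \code{\link{vesicle_spec}}.
#' @param fp A \code{\link{protein_footprint}}.
#' @return The input with \code{lipids_per_vesicle} and
#'   \code{protein_per_vesicle} columns appended.
#' @export
binding_table <- function(df, bilayer_thickness = 5, area_per_lipid = 0.71,
                          fp = protein_footprint()) {
  stopifnot(all(c("sample", "diameter", "p_b") %in% names(df)))
  n <- vapply(seq_len(nrow(df)), function(i) {
    lipids_per_vesicle(vesicle_spec(df$diameter[i], bilayer_thickness,
                                    area_per_lipid))
  }, numeric(1))
  df$lipids_per_vesicle <- n
  df$protein_per_vesicle <- df$p_b * n / fp$molar_mass
  df
}
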