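#' Pipeline configuration
#'
#' Collects every tunable of the pocket-finding funnel in one place. The
#' defaults are the method's published operating point where one is stated
#' (1 Angstrom voxels, 0.8 overlap cutoff, 3.5 Angstrom residue-ligand
#' distance cutoff); the remaining knobs (facet atom-selection depth, number
#' of empty voxel neighbours per atom, biochemical class minima) are exposed
#' because the method leaves them free.
#'
#' @param spacing Voxel edge length in Angstrom.
#' @param overlap_cutoff Minimum (asymmetric, max-of-both-directions) atom
#'   overlap fraction at which two candidate pockets are linked for merging.
#' @param atom_depth_cutoff Maximum perpendicular distance (Angstrom) from a
#'   hull facet plane at which an atom inside the facet's extreme box is still
#'   assigned to that facet's pocket.
#' @param k_max Maximum number of empty voxel neighbours (out of the 26-voxel
#'   shell) kept per pocket atom, nearest first.
#' @param min_hba,min_hbd Minimum number of pocket atoms classified as
#'   hydrogen-bond acceptors / donors for the biochemical filter.
#' @param min_other Minimum number of pocket atoms carrying any of the
#'   remaining classes (van der Waals, carbon ring, ionic, sulfur).
#' @param distance_cutoff Residue-to-ligand minimum-distance cutoff (Angstrom)
#'   for the optional residue filter.
#' @param altloc Alternate-location policy: `"first"` keeps the first listed
#'   conformer of each atom, `"highest"` the highest-occupancy one.
#' @param drop_waters Remove water records (HOH/WAT/DOD) on parsing.
#' @param keep_het Keep HETATM records on parsing.
#' @param dims_rounding Grid dimensioning rule: `"floor"` gives
#'   `floor(extent/spacing) + 1` voxels per axis, `"ceiling"` gives
#'   `ceiling(extent/spacing)`.
#' @param ligand_length,ligand_area Optional overrides (Angstrom, Angstrom^2)
#'   for the physical-filter thresholds normally measured from the ligand.
#'
#' @return A named list of class `pg_config`.
#' @examples
#' cfg <- pg_config(overlap_cutoff = 0.5)
#' cfg$overlap_cutoff
#' @export
pg_config <- function(spacing = 1.0,
                      overlap_cutoff = 0.8,
                      atom_depth_cutoff = 8.0,
                      k_max = 26L,
                      min_hba = 1L,
                      min_hbd = 1L,
                      min_other = 1L,
                      distance_cutoff = 3.5,
                      altloc = c("first", "highest"),
                      drop_waters = TRUE,
                      keep_het = TRUE,
                      dims_rounding = c("floor", "ceiling"),
                      ligand_length = NULL,
                      ligand_area = NULL) {
  altloc <- match.arg(altloc)
  dims_rounding <- match.arg(dims_rounding)
  stopifnot(spacing > 0, overlap_cutoff > 0, overlap_cutoff <= 1,
            atom_depth_cutoff > 0, k_max >= 0, distance_cutoff > 0,
            min_hba >= 0, min_hbd >= 0, min_other >= 0)
  structure(
    list(spacing = spacing,
         overlap_cutoff = overlap_cutoff,
         atom_depth_cutoff = atom_depth_cutoff,
         k_max = as.integer(k_max),
         min_hba = as.integer(min_hba),
         min_hbd = as.integer(min_hbd),
         min_other = as.integer(min_other),
         distance_cutoff = distance_cutoff,
         altloc = altloc,
         drop_waters = drop_waters,
         keep_het = keep_het,
         dims_rounding = dims_rounding,
         ligand_length = ligand_length,
         ligand_area = ligand_area),
    class = "pg_config"
  )
}

#' @export
print.pg_config <- function(x, ...) {
  cat("<pg_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

# one deterministic line used in report headers (criterion: byte-identical runs)
format_config <- function(config) {
  vals <- vapply(config, function(v) {
    if (is.null(v)) "NULL"
    else if (is.numeric(v)) sprintf("%g", v)
    else as.character(v)
  }, character(1))
  paste(paste0(names(config), "=", vals), collapse = " ")
}
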