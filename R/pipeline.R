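#' Run the full pocket-finding funnel on a structure
#'
#' Voxelises the protein atoms, computes their convex hull, builds one
#' candidate pocket per hull facet, merges candidates by the overlap
#' criterion, profiles the survivors biochemically and applies the
#' biochemical filter; when ligand dimensions are available the physical
#' (depth/surface) filter runs last. HETATM and water records never enter
#' the geometry — pockets are found on the protein alone.
#'
#' @param structure A `pg_structure` (or an atom data frame with the
#'   `pg_structure` atom columns).
#' @param config A [pg_config()].
#' @param ligand_dims Optional [ligand_dimensions()] for the physical filter;
#'   when absent, `config$ligand_length`/`config$ligand_area` are used if
#'   set, else the physical stage is skipped.
#' @return An object of class `pg_pocket_run`: `id`, `config`, `atoms` (the
#'   protein atoms used), `grid`, `hull`, `merged` (pockets after merging),
#'   `pockets` (the final filtered `pg_pockets` with interaction-profile
#'   columns), `funnel` (tibble of stage names and counts) and `ligand_dims`.
#' @examples
#' fx <- make_planted_structure(fixture_spec(seed = 1, n_shell_atoms = 80))
#' run <- find_pockets(fx$structure, pg_config(k_max = 10))
#' run$funnel
#' @export
find_pockets <- function(structure, config = pg_config(), ligand_dims = NULL) {
  if (inherits(structure, "pg_structure")) {
    atoms <- structure$atoms
    id <- structure$id
  } else {
    atoms <- as_tibble(structure)
    id <- "structure"
  }
  atoms <- filter(atoms, !.data$is_hetero,
                  !.data$res_name %in% WATER_RESIDUES)
  if (nrow(atoms) == 0) abort("No protein atoms to search for pockets.")

  grid <- build_grid(atoms, config$spacing, config$dims_rounding)
  hull <- compute_hull(atoms)
  candidates <- build_pockets(atoms, hull, grid, config)
  merged <- merge_pockets(candidates, config$overlap_cutoff,
                          hull = hull, grid = grid, atoms = atoms)
  merged <- interaction_profile(merged, atoms)
  bio <- biochemical_filter(merged, config$min_hba, config$min_hbd,
                            config$min_other, atoms = atoms)

  if (is.null(ligand_dims) &&
      (!is.null(config$ligand_length) || !is.null(config$ligand_area))) {
    ligand_dims <- list(n_atoms = NA_integer_,
                        length = config$ligand_length %||% 0,
                        surface_area = config$ligand_area %||% 0)
    class(ligand_dims) <- "pg_ligand_dims"
  }
  final <- if (!is.null(ligand_dims)) {
    physical_filter(bio, ligand_dims)
  } else {
    bio
  }

  funnel <- tibble(
    stage = c("candidates", "merged", "biochemical",
              if (!is.null(ligand_dims)) "physical"),
    n = c(attr(candidates, "n_candidates"), nrow(merged), nrow(bio),
          if (!is.null(ligand_dims)) nrow(final))
  )

  run <- list(id = id, config = config, atoms = atoms, grid = grid,
              hull = hull, merged = merged, pockets = final, funnel = funnel,
              ligand_dims = ligand_dims)
  class(run) <- "pg_pocket_run"
  run
}

#' @export
print.pg_pocket_run <- function(x, ...) {
  cat(sprintf("<pg_pocket_run> %s: %d atoms, grid %d x %d x %d, %d hull facets\n",
              x$id, nrow(x$atoms), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3], nrow(x$hull$facets)))
  cat("  funnel:", paste(sprintf("%s=%d", x$funnel$stage, x$funnel$n),
                         collapse = " -> "), "\n")
  invisible(x)
}

#' Tidy the final pockets of a run
#'
#' @param x A `pg_pocket_run` (or a `pg_pockets` tibble).
#' @param ... Unused.
#' @return A tibble with one row per pocket and only scalar columns
#'   (counts, depth, surface, volume, interaction profile).
#' @method tidy pg_pocket_run
#' @export
tidy.pg_pocket_run <- function(x, ...) tidy_pockets(x$pockets)

#' @rdname tidy.pg_pocket_run
#' @method tidy pg_pockets
#' @export
tidy.pg_pockets <- function(x, ...) tidy_pockets(x)

tidy_pockets <- function(pockets) {
  scalar <- !vapply(pockets, is.list, logical(1))
  as_tibble(as.data.frame(pockets[, scalar, drop = FALSE]))
}

#' One-row summary of a pocket run
#'
#' @param x A `pg_pocket_run`.
#' @param ... Unused.
#' @return A tibble with the structure id, atom count, grid dimensions, hull
#'   facet count and the funnel counts.
#' @method glance pg_pocket_run
#' @export
glance.pg_pocket_run <- function(x, ...) {
  wide <- setNames(as.list(x$funnel$n), paste0("n_", x$funnel$stage))
  dplyr::bind_cols(
    tibble(id = x$id, n_atoms = nrow(x$atoms),
           dim_x = x$grid$dims[1], dim_y = x$grid$dims[2],
           dim_z = x$grid$dims[3], n_facets = nrow(x$hull$facets),
           hull_volume = x$hull$volume, hull_area = x$hull$area),
    as_tibble(wide)
  )
}
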