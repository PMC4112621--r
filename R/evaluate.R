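RESIDUE_KEY <- c("res_name", "res_seq", "chain_id", "insertion_code")

#' Residue label in "<resname> <resseq><chain>" form
#'
#' @param res_name,res_seq,chain_id Residue identity vectors.
#' @return Character vector of labels like `"ARG 350H"`.
#' @export
residue_label <- function(res_name, res_seq, chain_id) {
  sprintf("%s %d%s", res_name, res_seq, chain_id)
}

#' Correct fraction (cf) of an active site recovered by a pocket
#'
#' The number of active-site residues present among the pocket's residues,
#' divided by the number of residues in the active site. Residues match on
#' (res_name, res_seq, chain_id, insertion_code); duplicates on either side
#' are ignored.
#'
#' @param pocket_residues Data frame of the pocket's residues (columns
#'   `res_name`, `res_seq`, `chain_id`, `insertion_code`).
#' @param site_residues Data frame of the active site's residues (same
#'   columns); must be non-empty.
#' @return A fraction in `[0, 1]`.
#' @examples
#' pocket <- data.frame(res_name = c("ARG", "TYR", "GLY"),
#'                      res_seq = 1:3, chain_id = "A", insertion_code = "")
#' site <- data.frame(res_name = c("ARG", "TYR", "TRP", "SER"),
#'                    res_seq = c(1, 2, 7, 8), chain_id = "A",
#'                    insertion_code = "")
#' compute_cf(pocket, site)  # 2/4
#' @export
compute_cf <- function(pocket_residues, site_residues) {
  site <- distinct(as_tibble(site_residues)[, RESIDUE_KEY])
  if (nrow(site) == 0) abort("Active site has no residues; cf is undefined.")
  if (nrow(pocket_residues) == 0) return(0)
  pocket <- distinct(as_tibble(pocket_residues)[, RESIDUE_KEY])
  nrow(semi_join(site, pocket, by = RESIDUE_KEY)) / nrow(site)
}

#' Minimum distance between two atom sets
#'
#' The smallest Euclidean distance over all pairs of atoms, e.g. between a
#' pocket residue's atoms and a ligand's atoms. Coordinates are taken in the
#' frames as deposited — no superposition is applied.
#'
#' @param residue_atoms,ligand_atoms Non-empty data frames with `x`,`y`,`z`.
#' @return Distance in Angstrom.
#' @export
min_residue_ligand_distance <- function(residue_atoms, ligand_atoms) {
  a <- as.matrix(residue_atoms[, c("x", "y", "z")])
  b <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  if (nrow(a) == 0 || nrow(b) == 0) abort("Empty atom set; distance undefined.")
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Minimum residue-to-ligand distances for a residue table
#'
#' @param residues Data frame of residues (columns `res_name`, `res_seq`,
#'   `chain_id`, `insertion_code`, and optionally `pocket_id`).
#' @param atoms Atom tibble supplying the residues' coordinates.
#' @param ligand A `pg_ligand` or data frame of ligand atoms.
#' @return `residues` with `min_distance` (A) added.
#' @export
residue_ligand_distances <- function(residues, atoms, ligand) {
  lig <- if (inherits(ligand, "pg_ligand")) ligand$atoms else ligand
  keys <- distinct(as_tibble(residues)[, RESIDUE_KEY])
  keys$min_distance <- vapply(seq_len(nrow(keys)), function(i) {
    ra <- semi_join(atoms, keys[i, ], by = RESIDUE_KEY)
    min_residue_ligand_distance(ra, lig)
  }, numeric(1))
  left_join(as_tibble(residues), keys, by = RESIDUE_KEY)
}

#' Filter residues by their minimum distance to the ligand
#'
#' Keeps residues whose minimum atom-to-atom distance to the ligand does not
#' exceed `cutoff` (default 3.5 Angstrom) — the optional final step that
#' prunes pocket residues too far from the bound ligand to interact.
#'
#' @param residue_distances A [residue_ligand_distances()] result (needs a
#'   `min_distance` column).
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return The surviving rows.
#' @export
distance_filter <- function(residue_distances, cutoff = 3.5) {
  stopifnot(cutoff > 0, "min_distance" %in% names(residue_distances))
  filter(residue_distances, .data$min_distance <= cutoff)
}

#' Evaluate predicted pockets against a liganded partner's active sites
#'
#' Runs the full pocket-finding funnel on the unliganded structure (with the
#' physical filter thresholds measured from the partner's ligand), then
#' scores every surviving pocket against every active site declared by the
#' liganded structure's SITE records via the correct fraction (cf), and
#' computes each pocket residue's minimum distance to the ligand atoms.
#' Distances are computed in the deposited coordinate frames with no
#' superposition; a warning is emitted when the two frames look inconsistent
#' (protein centroid shift above 5 Angstrom).
#'
#' @param unliganded A `pg_structure` to predict pockets on.
#' @param liganded Its liganded partner `pg_structure` (must declare at least
#'   one SITE).
#' @param ligand_code Heterogen code of the ligand in `liganded`.
#' @param config A [pg_config()].
#' @return An object of class `pg_evaluation`: `run` (the [find_pockets()]
#'   result), `cf` (tibble pocket_id x site_id with cf), `site_summary`
#'   (per-site max cf and best pocket), `residue_distances`, `ligand_dims`,
#'   `max_cf` (best cf over all pockets and sites).
#' @export
evaluate_pair <- function(unliganded, liganded, ligand_code,
                          config = pg_config()) {
  stopifnot(inherits(unliganded, "pg_structure"),
            inherits(liganded, "pg_structure"))
  sites <- active_sites(liganded)
  if (nrow(sites) == 0) {
    abort(sprintf("Structure %s declares no active sites (SITE records).",
                  liganded$id))
  }
  ligand <- ligand_atoms(liganded, ligand_code)
  dims <- ligand_dimensions(ligand)
  if (!is.null(config$ligand_length)) dims$length <- config$ligand_length
  if (!is.null(config$ligand_area)) dims$surface_area <- config$ligand_area

  prot_u <- filter(unliganded$atoms, !.data$is_hetero)
  prot_l <- filter(liganded$atoms, !.data$is_hetero)
  shift <- sqrt(sum((colMeans(as.matrix(prot_u[, c("x", "y", "z")])) -
                     colMeans(as.matrix(prot_l[, c("x", "y", "z")])))^2))
  if (shift > 5) {
    warn(sprintf("Coordinate frames of %s and %s differ by %.1f A (centroid shift); raw cross-structure distances may be meaningless.",
                 unliganded$id, liganded$id, shift))
  }

  run <- find_pockets(unliganded, config, ligand_dims = dims)
  pockets <- run$pockets
  residues <- pocket_residues(pockets, atoms = run$atoms)

  site_ids <- unique(sites$site_id)
  cf_tab <- tidyr::expand_grid(pocket_id = pockets$pocket_id,
                               site_id = site_ids)
  cf_tab$cf <- vapply(seq_len(nrow(cf_tab)), function(i) {
    compute_cf(filter(residues, .data$pocket_id == cf_tab$pocket_id[i]),
               filter(sites, .data$site_id == cf_tab$site_id[i]))
  }, numeric(1))

  site_summary <- if (nrow(cf_tab) > 0) {
    summarise(group_by(cf_tab, .data$site_id),
              max_cf = max(.data$cf),
              best_pocket_id = .data$pocket_id[which.max(.data$cf)],
              .groups = "drop")
  } else {
    tibble(site_id = site_ids, max_cf = 0, best_pocket_id = NA_integer_)
  }

  res_dist <- if (nrow(residues) > 0) {
    residue_ligand_distances(residues, run$atoms, ligand)
  } else {
    mutate(residues, min_distance = numeric(0))
  }
  res_dist <- mutate(res_dist,
                     label = residue_label(.data$res_name, .data$res_seq,
                                           .data$chain_id))

  out <- list(run = run, cf = cf_tab, site_summary = site_summary,
              residue_distances = res_dist, ligand_dims = dims,
              max_cf = if (nrow(cf_tab) > 0) max(cf_tab$cf) else 0,
              unliganded_id = unliganded$id, liganded_id = liganded$id,
              ligand_code = toupper(ligand_code))
  class(out) <- "pg_evaluation"
  out
}

#' @export
print.pg_evaluation <- function(x, ...) {
  cat(sprintf("<pg_evaluation> %s vs %s (%s): %d pockets, %d site(s), max cf %.2f\n",
              x$unliganded_id, x$liganded_id, x$ligand_code,
              nrow(x$run$pockets), nrow(x$site_summary), x$max_cf))
  invisible(x)
}

#' Tidy an evaluation into the pocket-by-site cf table
#'
#' @param x A `pg_evaluation`.
#' @param ... Unused.
#' @return A tibble: pocket_id, site_id, cf.
#' @method tidy pg_evaluation
#' @export
tidy.pg_evaluation <- function(x, ...) x$cf

#' One-row evaluation summary
#'
#' @param x A `pg_evaluation`.
#' @param ... Unused.
#' @return A tibble with the pair ids, pocket/site counts and the best cf.
#' @method glance pg_evaluation
#' @export
glance.pg_evaluation <- function(x, ...) {
  tibble(unliganded = x$unliganded_id, liganded = x$liganded_id,
         ligand_code = x$ligand_code, n_pockets = nrow(x$run$pockets),
         n_sites = nrow(x$site_summary), max_cf = x$max_cf)
}

#' Benchmark a manifest of unliganded/liganded pairs
#'
#' Runs [evaluate_pair()] for every row of a manifest, records each pair's
#' maximum cf, and reports the fraction of pairs whose best pocket recovers
#' at least half of an active site (`max_cf >= 0.5`). Pairs that fail to
#' parse or evaluate are skipped and reported in the summary.
#'
#' @param manifest Data frame with columns `unliganded`, `liganded` (PDB file
#'   paths) and `ligand_code`.
#' @param config A [pg_config()].
#' @return An object of class `pg_benchmark`: `results` (per-pair tibble with
#'   `max_cf` and `status`), `success_fraction`, `n_ok`, `n_failed`.
#' @export
benchmark_pairs <- function(manifest, config = pg_config()) {
  stopifnot(is.data.frame(manifest),
            all(c("unliganded", "liganded", "ligand_code") %in% names(manifest)))
  if (nrow(manifest) == 0) abort("Empty benchmark manifest.")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    res <- tryCatch({
      ev <- evaluate_pair(read_structure(m$unliganded),
                          read_structure(m$liganded),
                          m$ligand_code, config)
      tibble(unliganded = m$unliganded, liganded = m$liganded,
             ligand_code = m$ligand_code, max_cf = ev$max_cf, status = "ok",
             message = "")
    }, error = function(e) {
      inform(sprintf("Skipping pair %s/%s: %s", m$unliganded, m$liganded,
                     conditionMessage(e)))
      tibble(unliganded = m$unliganded, liganded = m$liganded,
             ligand_code = m$ligand_code, max_cf = NA_real_,
             status = "failed", message = conditionMessage(e))
    })
    res
  })
  results <- bind_rows(rows)
  ok <- filter(results, .data$status == "ok")
  if (nrow(ok) == 0) abort("All benchmark pairs failed.")
  out <- list(results = results,
              success_fraction = mean(ok$max_cf >= 0.5),
              n_ok = nrow(ok), n_failed = nrow(results) - nrow(ok))
  class(out) <- "pg_benchmark"
  out
}

#' @export
print.pg_benchmark <- function(x, ...) {
  cat(sprintf("<pg_benchmark> %d pair(s) evaluated (%d failed); success fraction (max cf >= 0.5): %.2f\n",
              x$n_ok, x$n_failed, x$success_fraction))
  invisible(x)
}

#' Tidy benchmark results (one row per pair)
#'
#' @param x A `pg_benchmark`.
#' @param ... Unused.
#' @return The per-pair results tibble.
#' @method tidy pg_benchmark
#' @export
tidy.pg_benchmark <- function(x, ...) x$results

#' One-row benchmark summary
#'
#' @param x A `pg_benchmark`.
#' @param ... Unused.
#' @return A tibble with pair counts and the success fraction.
#' @method glance pg_benchmark
#' @export
glance.pg_benchmark <- function(x, ...) {
  tibble(n_ok = x$n_ok, n_failed = x$n_failed,
         success_fraction = x$success_fraction)
}
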