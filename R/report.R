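#' Write a pocket report
#'
#' Emits a plain-text, tab-delimited report with two sections: `[pockets]`
#' (one row per pocket: atom and empty-voxel counts, surface, depth, volume,
#' per-class interaction atom counts, and — when an evaluation is supplied —
#' one cf column per active site) and `[residues]` (one row per pocket
#' residue, labelled `"<resname> <resseq><chain>"`, with its minimum distance
#' to the ligand when known). The header records the structure id, the full
#' configuration and the funnel counts, so a report is self-describing;
#' identical inputs and configuration always produce byte-identical files.
#'
#' @param run A `pg_pocket_run` (or a `pg_pockets` tibble with profile
#'   columns).
#' @param evaluation Optional `pg_evaluation` supplying cf values and
#'   residue-ligand distances.
#' @param path Output file path; `NULL` returns the lines invisibly without
#'   writing.
#' @return The report lines, invisibly.
#' @export
write_pocket_report <- function(run, evaluation = NULL, path = NULL) {
  if (inherits(run, "pg_pocket_run")) {
    pockets <- run$pockets
    id <- run$id
    config <- run$config
    funnel <- paste(sprintf("%s=%d", run$funnel$stage, run$funnel$n),
                    collapse = " ")
    atoms <- run$atoms
  } else {
    pockets <- run
    id <- "pockets"
    config <- NULL
    funnel <- ""
    atoms <- attr(pockets, "atoms")
  }
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))

  tab <- tidy_pockets(pockets)
  prof_cols <- intersect(c("n_hba", "n_hbd", "n_vdw", "n_ionic", "n_sulfur",
                           "n_cring"), names(tab))
  site_ids <- if (!is.null(evaluation)) {
    sort(unique(evaluation$cf$site_id))
  } else {
    character(0)
  }

  header <- c("# pocketgrid pocket report",
              sprintf("# structure: %s", id),
              if (!is.null(config)) sprintf("# config: %s", format_config(config)),
              if (nzchar(funnel)) sprintf("# funnel: %s", funnel))

  cf_cols <- if (length(site_ids) > 0) paste0("cf_", site_ids) else character(0)
  cols <- c("pocket_id", "n_atoms", "n_empty_voxels", "surface", "depth",
            "volume", prof_cols, cf_cols)
  lines <- c(header, "[pockets]", paste(cols, collapse = "\t"))
  for (i in seq_len(nrow(tab))) {
    vals <- c(tab$pocket_id[i], tab$n_atoms[i], tab$n_empty_voxels[i],
              num(tab$surface[i]), num(tab$depth[i]), num(tab$volume[i]))
    for (pc in prof_cols) vals <- c(vals, tab[[pc]][i])
    for (s in site_ids) {
      cfv <- evaluation$cf$cf[evaluation$cf$pocket_id == tab$pocket_id[i] &
                                evaluation$cf$site_id == s]
      vals <- c(vals, if (length(cfv) == 1) num(cfv) else "NA")
    }
    lines <- c(lines, paste(vals, collapse = "\t"))
  }

  lines <- c(lines, "[residues]", "pocket_id\tresidue\tmin_dist_to_ligand")
  res <- if (!is.null(evaluation)) {
    evaluation$residue_distances
  } else if (!is.null(atoms) && nrow(pockets) > 0) {
    r <- pocket_residues(pockets, atoms)
    mutate(r, label = residue_label(.data$res_name, .data$res_seq,
                                    .data$chain_id),
           min_distance = NA_real_)
  } else {
    NULL
  }
  if (!is.null(res) && nrow(res) > 0) {
    res <- arrange(res, .data$pocket_id, .data$label)
    lines <- c(lines, sprintf("%d\t%s\t%s", res$pocket_id, res$label,
                              num(res$min_distance)))
  }

  if (!is.null(path)) {
    tryCatch(writeLines(lines, path),
             error = function(e) abort(sprintf("Cannot write report to '%s': %s",
                                               path, conditionMessage(e))))
  }
  invisible(lines)
}

#' Read a pocket report back
#'
#' @param path Path to a [write_pocket_report()] file (or its lines).
#' @return A list with `header` (character), `pockets` (tibble) and
#'   `residues` (tibble); numeric columns are parsed back to numbers.
#' @export
read_pocket_report <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  header <- lines[startsWith(lines, "#")]
  ip <- which(lines == "[pockets]")
  ir <- which(lines == "[residues]")
  if (length(ip) != 1 || length(ir) != 1 || ir < ip) {
    abort("Not a pocket report: missing [pockets]/[residues] sections.")
  }
  parse_tsv <- function(block) {
    if (length(block) < 1) return(tibble())
    con <- paste(block, collapse = "\n")
    out <- readr::read_tsv(I(con), col_types = readr::cols(), progress = FALSE,
                           na = "NA")
    as_tibble(out)
  }
  pockets <- parse_tsv(lines[(ip + 1):(ir - 1)])
  res_block <- if (ir + 1 <= length(lines)) lines[(ir + 1):length(lines)] else character(0)
  residues <- parse_tsv(res_block)
  list(header = header, pockets = pockets, residues = residues)
}
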