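WATER_RESIDUES <- c("HOH", "WAT", "DOD")

# record tags defined by PDB format v3.3; anything else triggers one warning
PDB_KNOWN_RECORDS <- c(
  "HEADER", "OBSLTE", "TITLE", "SPLIT", "CAVEAT", "COMPND", "SOURCE", "KEYWDS",
  "EXPDTA", "NUMMDL", "MDLTYP", "AUTHOR", "REVDAT", "SPRSDE", "JRNL", "REMARK",
  "DBREF", "DBREF1", "DBREF2", "SEQADV", "SEQRES", "MODRES", "HET", "HETNAM",
  "HETSYN", "FORMUL", "HELIX", "SHEET", "SSBOND", "LINK", "CISPEP", "SITE",
  "CRYST1", "ORIGX1", "ORIGX2", "ORIGX3", "SCALE1", "SCALE2", "SCALE3",
  "MTRIX1", "MTRIX2", "MTRIX3", "MODEL", "ATOM", "ANISOU", "TER", "HETATM",
  "ENDMDL", "CONECT", "MASTER", "END"
)

pdb_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (via [bio3d::read.pdb()]) together with the
#' CONECT bond records, SITE active-site records and REMARK 800 site
#' descriptions that declare a liganded entry's binding sites.
#'
#' @param source Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param keep_het Keep HETATM records (ligands, ions). Waters are governed by
#'   `drop_waters` regardless.
#' @param drop_waters Drop water records (residue names HOH, WAT, DOD).
#' @param altloc Alternate-location policy: `"first"` keeps the first listed
#'   conformer of each duplicated atom, `"highest"` the highest-occupancy one
#'   (ties broken by file order).
#' @param id Structure identifier; defaults to the file base name or the
#'   HEADER id when parsing text.
#'
#' @return An object of class `pg_structure`: a list with `id`, `atoms`
#'   (a tibble, one row per kept atom: serial, atom_name, alt_loc, res_name,
#'   chain_id, res_seq, insertion_code, x, y, z, element, is_hetero,
#'   occupancy), `bonds` (tibble of unordered serial pairs from CONECT), and
#'   `sites` (tibble of SITE residues: site_id, description, res_name,
#'   res_seq, chain_id, insertion_code).
#' @examples
#' pdb <- make_planted_structure(fixture_spec(seed = 1))
#' str <- read_structure(pdb$pdb_text, id = "toy")
#' nrow(str$atoms)
#' @export
read_structure <- function(source, keep_het = TRUE, drop_waters = TRUE,
                           altloc = c("first", "highest"), id = NULL) {
  altloc <- match.arg(altloc)
  lines <- pdb_lines(source)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort("Empty PDB input: no records found.")
  }
  recs <- toupper(substr(lines, 1, 6))
  recs <- trimws(recs)
  atom_mask <- recs %in% c("ATOM", "HETATM")
  if (!any(atom_mask)) {
    abort(sprintf(
      "No ATOM/HETATM records found (first line: %s).",
      dQuote(substr(lines[1], 1, 40))
    ))
  }
  unknown <- setdiff(unique(recs[nzchar(recs)]), PDB_KNOWN_RECORDS)
  if (length(unknown) > 0) {
    warn(sprintf("Skipping unknown PDB record type(s): %s",
                 paste(unknown, collapse = ", ")))
  }

  # bio3d does the fixed-column ATOM/HETATM parsing; feed it exactly the lines
  # we saw so line numbers stay attributable
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- tryCatch(
    bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(sprintf("Malformed PDB input: %s", conditionMessage(e)))
  )

  a <- pdb$atom
  atoms <- tibble(
    serial = as.integer(a$eleno),
    atom_name = as.character(a$elety),
    alt_loc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    res_name = toupper(as.character(a$resid)),
    chain_id = ifelse(is.na(a$chain), "", as.character(a$chain)),
    res_seq = as.integer(a$resno),
    insertion_code = ifelse(is.na(a$insert), "", as.character(a$insert)),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     guess_element(a$elety), toupper(as.character(a$elesy))),
    is_hetero = a$type == "HETATM",
    occupancy = ifelse(is.na(a$o), 1, as.numeric(a$o))
  )

  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad) > 0) {
    atom_line_no <- which(atom_mask)[bad[1]]
    abort(sprintf("Non-numeric coordinates at line %d: %s",
                  atom_line_no, dQuote(lines[atom_line_no])))
  }

  if (drop_waters) atoms <- filter(atoms, !.data$res_name %in% WATER_RESIDUES)
  if (!keep_het) atoms <- filter(atoms, !.data$is_hetero)

  atoms <- resolve_altlocs(atoms, altloc)

  bonds <- parse_conect_lines(lines)
  bonds <- filter(bonds, .data$serial_a %in% atoms$serial,
                  .data$serial_b %in% atoms$serial)

  sites <- parse_site_lines(lines)
  if (nrow(sites) > 0) {
    known <- distinct(atoms, .data$res_name, .data$res_seq, .data$chain_id,
                      .data$insertion_code)
    missing <- anti_join(sites, known,
                         by = c("res_name", "res_seq", "chain_id", "insertion_code"))
    if (nrow(missing) > 0) {
      warn(sprintf("%d SITE residue(s) not found among kept atoms (kept anyway), e.g. %s %d%s",
                   nrow(missing), missing$res_name[1], missing$res_seq[1],
                   missing$chain_id[1]))
    }
  }

  if (is.null(id)) {
    hdr <- lines[recs == "HEADER"]
    id <- if (length(hdr) > 0 && nchar(hdr[1]) >= 66) {
      trimws(substr(hdr[1], 63, 66))
    } else if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
      sub("\\.(pdb|ent)$", "", basename(source), ignore.case = TRUE)
    } else ""
    if (!nzchar(id)) id <- "structure"
  }

  structure(list(id = id, atoms = atoms, bonds = bonds, sites = sites),
            class = "pg_structure")
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(as.character(atom_name)))
  # strip digits/primes, take leading letters; two-letter elements keep both
  lead <- sub("[^A-Z].*$", "", sub("^[0-9]*", "", nm))
  two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "CA", "SE", "NI", "CO")
  ifelse(lead %in% two, lead, substr(lead, 1, 1))
}

resolve_altlocs <- function(atoms, policy) {
  atoms <- mutate(atoms, .ord = row_number())
  atoms <- group_by(atoms, .data$chain_id, .data$res_seq, .data$insertion_code,
                    .data$res_name, .data$atom_name)
  atoms <- if (policy == "highest") {
    filter(atoms, order(-.data$occupancy, .data$.ord)[1] == row_number())
  } else {
    filter(atoms, row_number() == 1)
  }
  atoms <- ungroup(atoms)
  atoms <- arrange(atoms, .data$.ord)
  select(atoms, -".ord")
}

parse_conect_lines <- function(lines) {
  con <- lines[startsWith(lines, "CONECT")]
  if (length(con) == 0) {
    return(tibble(serial_a = integer(), serial_b = integer()))
  }
  starts <- c(7, 12, 17, 22, 27)
  pairs <- lapply(con, function(ln) {
    f <- vapply(starts, function(s) suppressWarnings(
      as.integer(trimws(substr(ln, s, s + 4)))), integer(1))
    base <- f[1]
    nb <- f[-1]
    nb <- nb[!is.na(nb)]
    if (is.na(base) || length(nb) == 0) return(NULL)
    cbind(pmin(base, nb), pmax(base, nb))
  })
  m <- do.call(rbind, pairs)
  if (is.null(m)) return(tibble(serial_a = integer(), serial_b = integer()))
  distinct(tibble(serial_a = as.integer(m[, 1]), serial_b = as.integer(m[, 2])))
}

parse_site_lines <- function(lines) {
  empty <- tibble(site_id = character(), description = character(),
                  res_name = character(), res_seq = integer(),
                  chain_id = character(), insertion_code = character())
  sl <- lines[startsWith(lines, "SITE")]
  descr <- parse_remark800(lines)
  if (length(sl) == 0) return(empty)
  rows <- lapply(sl, function(ln) {
    site_id <- trimws(substr(ln, 12, 14))
    out <- list()
    for (i in 0:3) {
      base <- 19 + 11 * i
      rn <- trimws(substr(ln, base, base + 2))
      if (!nzchar(rn)) next
      ch <- trimws(substr(ln, base + 4, base + 4))
      sq <- suppressWarnings(as.integer(trimws(substr(ln, base + 5, base + 8))))
      ic <- trimws(substr(ln, base + 9, base + 9))
      if (is.na(sq)) next
      out[[length(out) + 1]] <- tibble(site_id = site_id, res_name = toupper(rn),
                                       res_seq = sq, chain_id = ch,
                                       insertion_code = ic)
    }
    bind_rows(out)
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) return(empty)
  res <- distinct(res)
  res$description <- unname(descr[res$site_id])
  res$description[is.na(res$description)] <- ""
  select(res, "site_id", "description", "res_name", "res_seq", "chain_id",
         "insertion_code")
}

parse_remark800 <- function(lines) {
  r8 <- lines[startsWith(lines, "REMARK 800")]
  ids <- character(0); descs <- character(0); cur <- NA_character_
  for (ln in r8) {
    body <- trimws(substr(ln, 12, nchar(ln)))
    if (startsWith(body, "SITE_IDENTIFIER:")) {
      cur <- trimws(sub("^SITE_IDENTIFIER:", "", body))
    } else if (startsWith(body, "SITE_DESCRIPTION:") && !is.na(cur)) {
      ids <- c(ids, cur)
      descs <- c(descs, trimws(sub("^SITE_DESCRIPTION:", "", body)))
      cur <- NA_character_
    }
  }
  setNames(descs, ids)
}

#' @export
print.pg_structure <- function(x, ...) {
  cat(sprintf("<pg_structure> %s: %d atoms (%d hetero), %d bonds, %d site(s)\n",
              x$id, nrow(x$atoms), sum(x$atoms$is_hetero), nrow(x$bonds),
              length(unique(x$sites$site_id))))
  invisible(x)
}

#' Extract a ligand from a structure
#'
#' Returns the non-water HETATM records with the given heterogen code,
#' together with the CONECT bonds internal to that ligand.
#'
#' @param structure A [read_structure()] result.
#' @param het_code 1-3 character heterogen residue code (e.g. `"NIP"`).
#' @return A list of class `pg_ligand` with `atoms` (tibble) and `bonds`
#'   (tibble of serial pairs restricted to the ligand).
#' @examples
#' pdb <- make_planted_structure(fixture_spec(seed = 1))
#' str <- read_structure(pdb$pdb_text)
#' lig <- ligand_atoms(str, "TOY")
#' nrow(lig$atoms)
#' @export
ligand_atoms <- function(structure, het_code) {
  stopifnot(inherits(structure, "pg_structure"),
            is.character(het_code), nchar(het_code) >= 1, nchar(het_code) <= 3)
  het_code <- toupper(het_code)
  het <- filter(structure$atoms, .data$is_hetero,
                !.data$res_name %in% WATER_RESIDUES)
  atoms <- filter(het, .data$res_name == het_code)
  if (nrow(atoms) == 0) {
    avail <- sort(unique(het$res_name))
    abort(sprintf("No HETATM records with code '%s'; available het codes: %s",
                  het_code,
                  if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
  }
  bonds <- filter(structure$bonds, .data$serial_a %in% atoms$serial,
                  .data$serial_b %in% atoms$serial)
  out <- list(het_code = het_code, atoms = atoms, bonds = bonds)
  class(out) <- "pg_ligand"
  out
}

#' @export
print.pg_ligand <- function(x, ...) {
  cat(sprintf("<pg_ligand> %s: %d atoms, %d bonds\n",
              x$het_code, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Active sites declared by a structure's SITE records
#'
#' @param structure A [read_structure()] result.
#' @return A tibble with one row per site residue (site_id, description,
#'   res_name, res_seq, chain_id, insertion_code); zero rows when the entry
#'   declares no sites.
#' @export
active_sites <- function(structure) {
  stopifnot(inherits(structure, "pg_structure"))
  structure$sites
}

#' Write a structure back out as PDB text
#'
#' Emits REMARK 800 site descriptions, SITE records, ATOM/HETATM coordinate
#' records and CONECT bonds in fixed-column PDB v3.3 format.
#'
#' @param structure A `pg_structure`.
#' @param path Output path; when `NULL` the text is returned invisibly as a
#'   character vector of lines.
#' @return The lines, invisibly.
#' @export
write_structure <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "pg_structure"))
  lines <- character(0)
  sites <- structure$sites
  if (nrow(sites) > 0) {
    for (sid in unique(sites$site_id)) {
      d <- sites$description[sites$site_id == sid][1]
      lines <- c(lines,
                 sprintf("REMARK 800 SITE_IDENTIFIER: %s", sid),
                 sprintf("REMARK 800 SITE_DESCRIPTION: %s", d))
    }
    lines <- c(lines, format_site_records(sites))
  }
  lines <- c(lines, format_atom_records(structure$atoms))
  b <- structure$bonds
  if (nrow(b) > 0) {
    lines <- c(lines, sprintf("CONECT%5d%5d", b$serial_a, b$serial_b))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) abort(sprintf(
                     "Cannot write '%s': %s", path, conditionMessage(e))))
  }
  invisible(lines)
}

format_atom_records <- function(atoms) {
  nm <- ifelse(nchar(atoms$atom_name) < 4,
               sprintf(" %-3s", atoms$atom_name), atoms$atom_name)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$is_hetero, "HETATM", "ATOM"),
          atoms$serial, nm, atoms$alt_loc, atoms$res_name, atoms$chain_id,
          atoms$res_seq, atoms$insertion_code, atoms$x, atoms$y, atoms$z,
          atoms$occupancy, 0, atoms$element)
}

format_site_records <- function(sites) {
  out <- character(0)
  for (sid in unique(sites$site_id)) {
    s <- sites[sites$site_id == sid, ]
    n <- nrow(s)
    chunks <- split(seq_len(n), ceiling(seq_len(n) / 4))
    for (k in seq_along(chunks)) {
      idx <- chunks[[k]]
      grp <- sprintf("%3s %1s%4d%1s", s$res_name[idx],
                     ifelse(nzchar(s$chain_id[idx]), s$chain_id[idx], " "),
                     s$res_seq[idx],
                     ifelse(nzchar(s$insertion_code[idx]),
                            s$insertion_code[idx], " "))
      out <- c(out, sprintf("SITE   %3d %3s %2d %s", k, sid, n,
                            paste(grp, collapse = " ")))
    }
  }
  out
}

#' Download a PDB entry
#'
#' Fetches `https://files.rcsb.org/download/<ID>.pdb`. Requires network
#' access.
#'
#' @param id 4-character PDB accession.
#' @param destdir Directory to save into.
#' @param timeout Seconds before giving up.
#' @return Path to the downloaded file.
#' @export
fetch_pdb <- function(id, destdir = tempdir(), timeout = 60) {
  stopifnot(is.character(id), nchar(id) == 4)
  dest <- file.path(destdir, paste0(toupper(id), ".pdb"))
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    abort(sprintf("Could not download PDB entry %s from %s", id, url))
  }
  dest
}
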