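#' Read a protein structure from a PDB file into an atom tibble
#'
#' Parses a PDB file (or raw PDB text) into a normalised atom table.
#' Normalisation applies the conventions used throughout the package:
#' only the first MODEL of a multi-model (e.g. NMR) file is kept, only the
#' first-encountered alternate location of each atom is kept, waters are
#' always dropped, and other HETATM records are dropped unless
#' `include_hetatm = TRUE`. Selenomethionine (MSE) is treated as
#' methionine. Hydrogens present in the file are retained.
#'
#' Parsing of the fixed-column record format is delegated to
#' [bio3d::read.pdb()]; this function applies the model/altloc policy and
#' returns a tibble.
#'
#' @param path Path to a PDB file. Ignored when `text` is given.
#' @param text Optional character scalar (or vector of lines) of raw PDB
#'   text, used instead of `path`.
#' @param include_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @param source_id Label stored on the result (defaults to the file name).
#'
#' @return A tibble of class `fn_structure` with one row per atom and
#'   columns `serial`, `name`, `altloc`, `resid`, `chain`, `resno`,
#'   `insert`, `x`, `y`, `z`, `element`, `het`, `is_heavy`, `res_key`,
#'   `res_label`.
#' @export
#' @examples
#' pdb <- make_pair("LEU", "LEU", 5)
#' s <- read_structure(text = pdb)
#' nrow(s)
read_structure <- function(path = NULL, text = NULL, include_hetatm = FALSE,
                           source_id = NULL) {
  if (is.null(text)) {
    if (is.null(path)) abort("either `path` or `text` must be given")
    lines <- readLines(path, warn = FALSE)
    if (is.null(source_id)) source_id <- basename(path)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "text"
  }

  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines))) {
    abort("no ATOM records found: not a parseable PDB file")
  }

  # validate coordinate fields before handing off (wwPDB v3.3 columns 31-54)
  for (i in which(is_coord)) {
    xyz_txt <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    vals <- suppressWarnings(as.numeric(xyz_txt))
    if (any(is.na(vals)) || any(!is.finite(vals))) {
      abort(sprintf("malformed coordinate fields on line %d", i))
    }
  }

  # first-model policy: truncate at the first ENDMDL when MODEL records exist
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]
  lines <- lines[!grepl("^(MODEL|ANISOU)", lines)]

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE))

  at <- pdb$atom
  df <- tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", trimws(at$alt)),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", trimws(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy), "", trimws(at$elesy)),
    het = at$type == "HETATM"
  )

  # altloc resolution: first-encountered record per (chain, residue, atom name)
  df <- df |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain, .data$resno, .data$insert, .data$resid, .data$name) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")

  # MSE is chemically methionine; fold it into the protein
  mse <- df$resid == "MSE"
  if (any(mse)) {
    df$resid[mse] <- "MET"
    df$het[mse] <- FALSE
  }
  water <- df$resid %in% c("HOH", "WAT", "DOD", "H2O")
  df <- df[!water, , drop = FALSE]
  if (!include_hetatm) df <- df[!df$het, , drop = FALSE]

  blank <- df$element == ""
  if (any(blank)) df$element[blank] <- infer_element(df$name[blank])

  as_structure(df, source_id = source_id)
}

#' Construct a structure tibble from a plain atom data frame
#'
#' Lower-level constructor used by the synthetic-fixture generator and by
#' tests. Required columns: `name`, `resid`, `resno`, `x`, `y`, `z`.
#' Missing bookkeeping columns (`serial`, `chain`, `insert`, `altloc`,
#' `element`, `het`) are filled with defaults.
#'
#' @param df A data frame of atoms.
#' @param source_id Label stored on the result.
#' @return A `fn_structure` tibble (see [read_structure()]).
#' @export
as_structure <- function(df, source_id = "synthetic") {
  df <- as_tibble(df)
  need <- c("name", "resid", "resno", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("missing atom columns: ", paste(miss, collapse = ", ")))
  }
  if (!"serial" %in% names(df)) df$serial <- seq_len(nrow(df))
  if (!"chain" %in% names(df)) df$chain <- "A"
  if (!"insert" %in% names(df)) df$insert <- ""
  if (!"altloc" %in% names(df)) df$altloc <- ""
  if (!"het" %in% names(df)) df$het <- FALSE
  if (!"element" %in% names(df)) df$element <- infer_element(df$name)
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  df$is_heavy <- !(df$element %in% c("H", "D"))
  df$res_key <- paste(df$chain, df$resno, df$insert, df$resid, sep = "|")
  df$res_label <- paste0(df$resid, df$resno, df$insert)
  structure(df, source_id = source_id,
            class = c("fn_structure", class(df)))
}

# element symbol from a PDB atom name ("CA" -> C, "OD1" -> O, "1HG1" -> H)
infer_element <- function(name) {
  stripped <- sub("^[0-9 ]+", "", trimws(name))
  first <- toupper(substr(stripped, 1, 1))
  ifelse(first %in% c("H", "D"), "H", first)
}

#' One row per residue of a structure, in file order
#' @param structure A structure tibble from [read_structure()].
#' @return A tibble with `res_key`, `res_label`, `chain`, `resno`,
#'   `insert`, `resid`, `n_atoms`.
#' @export
residue_table <- function(structure) {
  structure |>
    as_tibble() |>
    group_by(.data$res_key) |>
    summarise(
      res_label = .data$res_label[1], chain = .data$chain[1],
      resno = .data$resno[1], insert = .data$insert[1],
      resid = .data$resid[1], n_atoms = n(), .groups = "drop"
    ) |>
    arrange(match(.data$res_key, unique(structure$res_key)))
}

#' Extract the one-letter amino-acid sequence of a structure
#'
#' Residues are taken in file order; an optional chain filter restricts to
#' one chain. Non-standard residues map to `X` (MSE is already folded into
#' MET at parse time).
#'
#' @param structure A structure tibble.
#' @param chain Optional chain identifier.
#' @return A single character string of one-letter codes.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  res <- residue_table(structure)
  if (!is.null(chain)) res <- res[res$chain %in% chain, , drop = FALSE]
  paste(aa_three_to_one(res$resid), collapse = "")
}

aa_three_to_one <- function(three) {
  map <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  out <- unname(map[three])
  out[is.na(out)] <- "X"
  out
}

#' Fetch a structure from the Protein Data Bank by identifier
#'
#' Downloads `https://files.rcsb.org/download/<id>.pdb` and parses it with
#' [read_structure()]. This is the only networked operation in the
#' package; every analysis accepts a local file instead.
#'
#' @param id 4-character PDB identifier.
#' @inheritParams read_structure
#' @return A `fn_structure` tibble.
#' @export
fetch_structure <- function(id, include_hetatm = FALSE) {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", id)) {
    abort("`id` must be a 4-character PDB identifier")
  }
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, tmp, quiet = TRUE, mode = "wb"),
    error = function(e) -1L, warning = function(w) -1L
  )
  if (!identical(status, 0L)) {
    abort(sprintf("could not download %s from the PDB (network required)", id))
  }
  read_structure(tmp, include_hetatm = include_hetatm, source_id = tolower(id))
}

#' Serialise a structure tibble back to PDB text
#'
#' @param structure A structure tibble.
#' @param path Optional file to write; when `NULL` the text is returned.
#' @return The PDB text, invisibly when written to a file.
#' @export
write_structure <- function(structure, path = NULL) {
  txt <- c(pdb_atom_lines(structure), "END")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(paste(txt, collapse = "\n")))
  }
  paste(txt, collapse = "\n")
}

# fixed-column ATOM/HETATM records (wwPDB v3.3)
pdb_atom_lines <- function(atoms) {
  name4 <- ifelse(
    nchar(atoms$name) >= 4, substr(atoms$name, 1, 4),
    paste0(" ", formatC(atoms$name, width = -3))
  )
  occ <- if ("occ" %in% names(atoms)) atoms$occ else rep(1, nrow(atoms))
  sprintf(
    "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$het, "HETATM", "ATOM"), atoms$serial %% 100000L, name4,
    substr(paste0(atoms$altloc, " "), 1, 1), atoms$resid,
    substr(paste0(atoms$chain, " "), 1, 1), atoms$resno %% 10000L,
    substr(paste0(atoms$insert, " "), 1, 1),
    atoms$x, atoms$y, atoms$z, occ, 0, atoms$element
  )
}

#' Write a table of records as an RFC 4180 CSV file
#'
#' @param rows A data frame (possibly zero rows; the header is still
#'   written).
#' @param destination Output path.
#' @return `destination`, invisibly.
#' @export
write_table <- function(rows, destination) {
  readr::write_csv(as_tibble(rows), destination, progress = FALSE)
  invisible(destination)
}

# fixed colour palette cycled over groups; deterministic output
viewer_palette <- function() {
  c("red", "green", "yellow", "orange", "blue", "magenta", "cyan",
    "salmon", "limegreen", "slate", "hotpink", "deepteal")
}

#' Write a PyMOL-dialect command script colouring residue groups
#'
#' Emits a plain-text `.pml` script that loads the source structure,
#' creates one named selection per group and assigns each a distinct
#' colour from a fixed palette.
#'
#' @param structure A structure tibble (used to validate the groups).
#' @param groups Named list; each element a character vector of residue
#'   labels (e.g. `"GLU30"`) present in the structure.
#' @param destination Output path for the script.
#' @param structure_file File name the script should load (defaults to the
#'   structure's source label).
#' @return `destination`, invisibly.
#' @export
write_viewer_script <- function(structure, groups, destination,
                                structure_file = NULL) {
  if (is.null(structure_file)) {
    structure_file <- attr(structure, "source_id") %||% "structure.pdb"
  }
  known <- unique(structure$res_label)
  lines <- c(sprintf("load %s", structure_file), "hide everything",
             "show cartoon")
  pal <- viewer_palette()
  if (length(groups) > 0 && is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (i in seq_along(groups)) {
    members <- groups[[i]]
    unknown <- setdiff(members, known)
    if (length(unknown) > 0) {
      abort(paste0("unknown residues in group '", names(groups)[i], "': ",
                   paste(unknown, collapse = ", ")))
    }
    resnos <- structure$resno[match(members, structure$res_label)]
    lines <- c(
      lines,
      sprintf("select %s, resi %s", names(groups)[i],
              paste(resnos, collapse = "+")),
      sprintf("show sticks, %s", names(groups)[i]),
      sprintf("color %s, %s", pal[(i - 1L) %% length(pal) + 1L],
              names(groups)[i])
    )
  }
  writeLines(lines, destination)
  invisible(destination)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
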