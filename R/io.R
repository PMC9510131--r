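## Structure file I/O: PDB and mmCIF, read and write.
##
## Only ATOM/HETATM content is interpreted; a single model is read (for
## multi-model files, model 1). Alternate locations are resolved on read to
## a single conformer: highest occupancy wins, ties broken by alphabetical
## alt-loc id, so downstream geometry always sees one position per atom.

#' Read a macromolecular structure
#'
#' @param source path to a file, or a character vector of file lines.
#' @param format `"pdb"` or `"mmcif"`; guessed from the file extension when
#'   `NULL` (`.cif`/`.mmcif` vs anything else).
#' @param keep_alt_locs if `TRUE`, keep all alternate-location conformers
#'   instead of resolving to one.
#' @return a [structure_model()].
#' @export
read_structure <- function(source, format = NULL, keep_alt_locs = FALSE) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(format)) {
      ext <- tolower(tools::file_ext(source))
      format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
    }
    src <- source
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n",
                             fixed = TRUE))
    if (is.null(format)) {
      format <- if (any(grepl("^_atom_site\\.", lines))) "mmcif" else "pdb"
    }
    src <- "<text>"
  }
  if (!format %in% c("pdb", "mmcif")) {
    stop("unknown format '", format, "': expected 'pdb' or 'mmcif'")
  }
  atoms <- switch(format,
                  pdb = parse_pdb_lines(lines),
                  mmcif = parse_mmcif_lines(lines))
  if (!keep_alt_locs) atoms <- resolve_alt_locs(atoms)
  structure_model(atoms, metadata = list(source = src, format = format))
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  ## stop at ENDMDL: only model 1 of multi-model files is read
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0L) {
    lines <- lines[seq_len(endmdl[1] - 1L)]
    rec <- rec[seq_len(endmdl[1] - 1L)]
  }
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  ln <- lines[sel]
  if (length(ln) == 0L) stop("no ATOM/HETATM records found")
  bad <- which(nchar(ln) < 54)
  if (length(bad) > 0L) {
    stop("malformed PDB record at line ", sel[bad[1]], ": '",
         lines[sel[bad[1]]], "'")
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(ln, 31, 38))
  y <- num(substr(ln, 39, 46))
  z <- num(substr(ln, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    i <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop("malformed coordinates in PDB record at line ", sel[i], ": '",
         ln[i], "'")
  }
  occ <- num(substr(ln, 55, 60))
  occ[is.na(occ)] <- 1
  bf <- num(substr(ln, 61, 66))
  bf[is.na(bf)] <- 0
  name <- trimws(substr(ln, 13, 16))
  element <- toupper(trimws(substr(ln, 77, 78)))
  ## fall back to first letter of the atom name when element is absent
  noel <- element == ""
  element[noel] <- substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]*", "", name[noel])), 1, 1)
  data.frame(
    serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name = name,
    alt_loc = trimws(substr(ln, 17, 17)),
    res_name = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    res_number = suppressWarnings(as.integer(substr(ln, 23, 26))),
    ins_code = trimws(substr(ln, 27, 27)),
    x = x, y = y, z = z,
    occupancy = occ, b_factor = bf,
    element = toupper(element),
    is_hetero = rec[sel] == "HETATM",
    stringsAsFactors = FALSE)
}

parse_mmcif_lines <- function(lines) {
  lines <- trimws(lines, which = "right")
  hdr <- grep("^_atom_site\\.", lines)
  if (length(hdr) == 0L) stop("no _atom_site loop found in mmCIF input")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  body_start <- max(hdr) + 1L
  body <- character(0)
  for (i in body_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || l == "#" || startsWith(l, "loop_") ||
        startsWith(l, "_") || startsWith(l, "data_")) break
    body <- c(body, l)
  }
  if (length(body) == 0L) stop("empty _atom_site loop in mmCIF input")
  toks <- strsplit(body, "[[:space:]]+")
  nf <- length(fields)
  badlen <- which(vapply(toks, length, 1L) != nf)
  if (length(badlen) > 0L) {
    stop("malformed mmCIF atom_site row at line ",
         body_start + badlen[1] - 1L, ": '", body[badlen[1]], "'")
  }
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(nm, default = NA_character_) {
    if (nm %in% fields) m[, nm] else rep(default, nrow(m))
  }
  dot_blank <- function(v) ifelse(v %in% c(".", "?"), "", v)
  ## author fields preferred; fall back to label fields
  chain <- get("auth_asym_id")
  if (all(is.na(chain))) chain <- get("label_asym_id")
  resno <- get("auth_seq_id")
  if (all(is.na(resno))) resno <- get("label_seq_id")
  occ <- suppressWarnings(as.numeric(dot_blank(get("occupancy", "1"))))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(dot_blank(get("B_iso_or_equiv", "0"))))
  bf[is.na(bf)] <- 0
  xyz <- suppressWarnings(cbind(as.numeric(m[, "Cartn_x"]),
                                as.numeric(m[, "Cartn_y"]),
                                as.numeric(m[, "Cartn_z"])))
  if (anyNA(xyz)) {
    i <- which(apply(is.na(xyz), 1, any))[1]
    stop("malformed coordinates in mmCIF row ", i)
  }
  data.frame(
    serial = suppressWarnings(as.integer(get("id", "0"))),
    name = gsub('"', "", dot_blank(get("label_atom_id"))),
    alt_loc = dot_blank(get("label_alt_id", "")),
    res_name = dot_blank(get("label_comp_id")),
    chain = dot_blank(chain),
    res_number = suppressWarnings(as.integer(dot_blank(resno))),
    ins_code = dot_blank(get("pdbx_PDB_ins_code", "")),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = occ, b_factor = bf,
    element = toupper(dot_blank(get("type_symbol"))),
    is_hetero = get("group_PDB", "ATOM") == "HETATM",
    stringsAsFactors = FALSE)
}

## Keep one conformer per (residue, atom name): highest occupancy first,
## alphabetical alt-loc id on ties. Blank alt-locs are untouched.
resolve_alt_locs <- function(atoms) {
  has_alt <- atoms$alt_loc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(residue_key(atoms), atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$alt_loc)
  keep_first <- !duplicated(key[ord])
  keep <- logical(nrow(atoms))
  keep[ord] <- keep_first
  keep[!has_alt] <- TRUE
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure to PDB or mmCIF
#'
#' @param model a [structure_model()].
#' @param path output file path; when `NULL` the lines are returned invisibly
#'   instead of written.
#' @param format `"pdb"` or `"mmcif"`; guessed from the extension of `path`.
#' @return invisibly, the character vector of file lines.
#' @export
write_structure <- function(model, path = NULL, format = NULL) {
  if (is.null(format)) {
    ext <- if (is.null(path)) "" else tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (!format %in% c("pdb", "mmcif")) {
    stop("unknown format '", format, "'")
  }
  lines <- switch(format,
                  pdb = format_pdb_lines(model$atoms),
                  mmcif = format_mmcif_lines(model$atoms))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

format_pdb_lines <- function(a) {
  if (nrow(a) == 0L) return("END")
  rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
  ## atom-name column convention: names of <4 chars start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, a$serial %% 100000L, nm, substr(a$alt_loc, 1, 1), a$res_name,
    substr(a$chain, 1, 1), a$res_number, substr(a$ins_code, 1, 1),
    a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  c(lines, "END")
}

format_mmcif_lines <- function(a) {
  hdr <- c("data_model", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "auth_asym_id", "auth_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv")))
  dot <- function(v) ifelse(v == "" | is.na(v), ".", v)
  rows <- sprintf("%s %d %s %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f",
                  ifelse(a$is_hetero, "HETATM", "ATOM"), a$serial,
                  dot(a$element), dot(a$name), dot(a$alt_loc),
                  dot(a$res_name), dot(a$chain), dot(a$chain),
                  a$res_number, dot(a$ins_code),
                  a$x, a$y, a$z, a$occupancy, a$b_factor)
  c(hdr, rows, "#")
}
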