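#' Read a protein structure from a PDB file
#'
#' Reads one model of a fixed-column PDB file into an atom table. Waters and
#' other heteroatoms are dropped, alternate locations other than blank or `'A'`
#' are discarded, hydrogens are kept, and residues are renumbered sequentially
#' from 1 in order of appearance (the construct used throughout this package
#' starts at the first ordered residue of the EC1 domain, so e.g. Q24 of the
#' full-length numbering becomes residue 1). Files containing insertion codes
#' are rejected: the renumbering contract assumes a plain sequential chain.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param model_index 1-based model to read from a multi-model file.
#'
#' @return A `cdh_structure`: a tibble with one row per atom and columns
#'   `atom` (PDB atom name), `element`, `resno` (renumbered, 1-based),
#'   `resname` (3-letter), `chain`, `x`, `y`, `z` (Angstrom). The derived
#'   one-letter sequence is stored in `attr(, "sequence")`.
#' @export
read_structure <- function(pdb, model_index = 1L) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }
  if (!any(grepl("^(ATOM|HETATM)", lines))) {
    first_bad <- lines[nzchar(trimws(lines))][1] %||% "<empty file>"
    abort(sprintf("no ATOM records found; first line was: %s", first_bad))
  }
  # split into models; files without MODEL records are a single model
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    if (model_index != 1L) abort(sprintf("model %d not present (file has 1 model)", model_index))
    block <- lines
  } else {
    if (model_index > length(model_starts)) {
      abort(sprintf("model %d not present (file has %d models)", model_index, length(model_starts)))
    }
    ends <- c(model_starts[-1] - 1L, length(lines))
    block <- lines[model_starts[model_index]:ends[model_index]]
  }
  at <- block[grepl("^ATOM  |^HETATM", block)]
  parse_field <- function(x, a, b) substr(x, a, b)
  resname <- trimws(parse_field(at, 18, 20))
  keep_het <- resname %in% names(.AA3_TO_1)          # drop waters/ligands
  rec <- trimws(parse_field(at, 1, 6))
  keep <- (rec == "ATOM" | (rec == "HETATM" & keep_het)) & keep_het
  at <- at[keep]; resname <- resname[keep]
  if (length(at) == 0L) abort("no protein ATOM records after filtering")
  altloc <- parse_field(at, 17, 17)
  sel <- altloc %in% c(" ", "", "A")
  at <- at[sel]; resname <- resname[sel]
  icode <- parse_field(at, 27, 27)
  if (any(icode %!in% c(" ", ""))) {
    abort(sprintf("insertion codes are not supported (first offender: %s)",
                  trimws(at[which(icode %!in% c(" ", ""))[1]])))
  }
  xyz <- suppressWarnings(cbind(
    as.numeric(parse_field(at, 31, 38)),
    as.numeric(parse_field(at, 39, 46)),
    as.numeric(parse_field(at, 47, 54))
  ))
  if (anyNA(xyz)) {
    abort(sprintf("malformed coordinate field at line: %s", at[which(rowSums(is.na(xyz)) > 0)[1]]))
  }
  name <- trimws(parse_field(at, 13, 16))
  chain <- parse_field(at, 22, 22)
  resid_raw <- trimws(parse_field(at, 23, 26))
  element <- trimws(parse_field(at, 77, 78))
  guess <- substr(gsub("^[0-9]+", "", name), 1, 1)
  element <- ifelse(nzchar(element), element, guess)
  key <- paste(chain, resid_raw, sep = "|")
  resno <- match(key, unique(key))
  atoms <- tibble(
    atom = name, element = element, resno = as.integer(resno),
    resname = resname, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  new_cdh_structure(atoms)
}

.AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

new_cdh_structure <- function(atoms) {
  stopifnot(all(c("atom", "element", "resno", "resname", "chain", "x", "y", "z") %in% names(atoms)))
  ca <- atoms[atoms$atom == "CA", ]
  n_res <- length(unique(atoms$resno))
  if (nrow(ca) < n_res) {
    missing <- setdiff(unique(atoms$resno), ca$resno)
    abort(sprintf("residue(s) without a CA atom: %s", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) abort("non-finite coordinates")
  by_chain <- split(atoms$resno, atoms$chain)
  ok <- vapply(by_chain, function(r) all(diff(unique(r)) > 0), logical(1))
  if (!all(ok)) abort("residue indices must be strictly increasing within a chain")
  seq1 <- unname(.AA3_TO_1[ca$resname[order(ca$resno)]])
  seq1[is.na(seq1)] <- "X"
  out <- as_tibble(atoms)
  attr(out, "sequence") <- paste(seq1, collapse = "")
  class(out) <- c("cdh_structure", class(out))
  out
}

#' @export
print.cdh_structure <- function(x, ...) {
  cat(sprintf("<cdh_structure> %d atoms, %d residues\n",
              nrow(x), n_residues(x)))
  cat("sequence:", attr(x, "sequence"), "\n")
  NextMethod()
}

#' Number of residues in a structure
#' @param s A `cdh_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) length(unique(s$resno))

#' One-letter sequence of a structure
#' @param s A `cdh_structure`.
#' @return Character scalar.
#' @export
structure_sequence <- function(s) attr(s, "sequence")

# Calpha coordinate matrix (n_res x 3), ordered by resno
ca_coords <- function(s) {
  ca <- s[s$atom == "CA", ]
  ca <- ca[order(ca$resno), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Write a structure (or trajectory) as a fixed-column PDB file
#'
#' Coordinates are written with the standard `%8.3f` PDB precision; structures
#' generated by the toy builders round their coordinates to 3 decimals, so a
#' write/read cycle round-trips them exactly. A list of coordinate matrices
#' produces a multi-model file.
#'
#' @param s A `cdh_structure`.
#' @param path Output file path.
#' @param coords Optional list of `n_atoms x 3` matrices (one per model)
#'   replacing the structure's own coordinates.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, coords = NULL) {
  fmt <- function(xyz) {
    sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(s)),
      ifelse(nchar(s$atom) < 4, paste0(" ", s$atom), s$atom),
      s$resname, s$chain, s$resno, xyz[, 1], xyz[, 2], xyz[, 3], s$element
    )
  }
  con <- file(path, "w"); on.exit(close(con))
  if (is.null(coords)) {
    writeLines(fmt(as.matrix(s[, c("x", "y", "z")])), con)
  } else {
    for (i in seq_along(coords)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(fmt(coords[[i]]), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param pdb Path or character lines of a multi-model PDB file.
#' @return A list with `structure` (the first model as a [read_structure()]
#'   atom table) and `coords`, a list of `n_atoms x 3` coordinate matrices,
#'   one per model.
#' @export
read_trajectory <- function(pdb) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }
  n_models <- max(1L, length(grep("^MODEL", lines)))
  s1 <- read_structure(lines, 1L)
  coords <- vector("list", n_models)
  coords[[1]] <- as.matrix(s1[, c("x", "y", "z")])
  if (n_models > 1L) {
    for (m in 2:n_models) {
      sm <- read_structure(lines, m)
      if (nrow(sm) != nrow(s1)) abort("models differ in atom count")
      coords[[m]] <- as.matrix(sm[, c("x", "y", "z")])
    }
  }
  list(structure = s1, coords = coords)
}
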