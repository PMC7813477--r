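# Plain-text exchange formats: contact maps as TSV, reports as JSON.

#' Write / read a contact map as TSV
#'
#' Columns `i`, `j`, `r0` (plus `n_atomic` for the WSME flavor) with a
#' `# flavor=` / `# n_residues=` header; WSME maps carry their per-residue
#' charges in an accompanying `# charges=` header line.
#'
#' @param cmap A `contact_map`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_contact_map <- function(cmap, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# flavor=%s", attr(cmap, "flavor")), con)
  writeLines(sprintf("# n_residues=%d", attr(cmap, "n_residues")), con)
  q <- attr(cmap, "charges")
  if (!is.null(q)) {
    writeLines(paste0("# charges=", paste(q, collapse = ",")), con)
  }
  utils::write.table(as.data.frame(cmap), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    h <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(h) == 0L) NULL else sub(paste0("^# ", key, "="), "", h[1])
  }
  flavor <- get("flavor") %||% abort("missing flavor header")
  n_res <- as.integer(get("n_residues"))
  charges <- get("charges")
  if (!is.null(charges)) charges <- as.numeric(strsplit(charges, ",")[[1]])
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t")
  new_contact_map(as_tibble(body), flavor, n_res, charges = charges)
}

#' Superposition report as JSON
#'
#' @param fit A [superpose_rmsd()] result.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_rmsd_report <- function(fit, path) {
  jsonlite::write_json(
    list(rmsd_A = fit$rmsd, n_atoms = fit$n_atoms,
         rotation = fit$rotation, translation = fit$translation),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
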