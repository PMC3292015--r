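#' Read a topology from its JSON schema file
#'
#' The on-disk topology schema is a single JSON document with fields
#' `format` ("mmgbsa-topology"), `scale14` (`ele`, `vdw`), `atoms` (array of
#' atom records), `bonds`, `angles`, `dihedrals` (arrays of bonded-term
#' records, 1-based indices). Numbers are written at full double precision so
#' a write/read round trip is lossless.
#'
#' @param path file path.
#' @return an `"mmtopology"`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$atoms) || !length(doc$atoms))
    stop("topology schema error: missing required field 'atoms'")
  sc <- doc$scale14
  build_topology(doc$atoms, doc$bonds, doc$angles, doc$dihedrals,
                 scale14_ele = if (!is.null(sc$ele)) sc$ele else 1.2,
                 scale14_vdw = if (!is.null(sc$vdw)) sc$vdw else 2.0)
}

#' Write a topology to its JSON schema file
#' @param top an `"mmtopology"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(top, path) {
  doc <- list(format = "mmgbsa-topology", version = 1L,
              scale14 = top$scale14, atoms = top$atoms, bonds = top$bonds,
              angles = top$angles, dihedrals = top$dihedrals)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a snapshot ensemble from a multi-model PDB file
#'
#' One frame is read per `MODEL` record; coordinates are taken from the
#' fixed-width ATOM/HETATM columns (PDB precision, 1e-3 A). Optional per-model
#' `REMARK   6 TIME_PS <t>` records populate the frame times.
#'
#' @param path multi-model PDB file.
#' @param topology the owning `"mmtopology"`; every model must contain exactly
#'   its number of atoms, in topology order.
#' @return an `"mmensemble"`.
#' @export
load_ensemble <- function(path, topology) {
  if (!file.exists(path)) stop("ensemble file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts) || length(starts) != length(ends))
    stop("no MODEL records found in ", path)
  nexp <- nrow(topology$atoms)
  frames <- vector("list", length(starts))
  times <- rep(NA_real_, length(starts))
  for (m in seq_along(starts)) {
    blk <- lines[starts[m]:ends[m]]
    at <- blk[grepl("^(ATOM  |HETATM)", blk)]
    if (length(at) != nexp)
      stop("atom-count mismatch in model ", m, ": expected ", nexp,
           ", found ", length(at))
    frames[[m]] <- cbind(as.numeric(substr(at, 31, 38)),
                         as.numeric(substr(at, 39, 46)),
                         as.numeric(substr(at, 47, 54)))
    tm <- blk[grepl("^REMARK   6 TIME_PS", blk)]
    if (length(tm)) times[m] <- as.numeric(sub("^REMARK   6 TIME_PS *", "", tm[1]))
  }
  new_ensemble(frames, times = if (all(is.finite(times))) times else NULL,
               topology = topology)
}

#' Write a snapshot ensemble as a multi-model PDB file
#' @param ens an `"mmensemble"`.
#' @param topology the owning `"mmtopology"` (atom/residue names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, topology, path) {
  if (nrow(topology$atoms) != ens$natoms)
    stop("atom-count mismatch between ensemble and topology")
  a <- topology$atoms
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ens$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    if (!is.null(ens$times))
      writeLines(sprintf("REMARK   6 TIME_PS %.6f", ens$times[m]), con)
    f <- ens$frames[[m]]
    writeLines(sprintf("ATOM  %5d %-4s%-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       seq_len(nrow(a)), nm, a$resname, a$resno,
                       f[, 1], f[, 2], f[, 3], toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
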