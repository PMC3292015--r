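#' Construct a snapshot ensemble
#'
#' An ensemble is an ordered list of Cartesian coordinate frames (N x 3
#' matrices, Angstrom) tied to one topology, optionally time-stamped in ps.
#'
#' @param frames list of N x 3 numeric matrices.
#' @param times optional numeric vector of per-frame times (ps), strictly
#'   increasing.
#' @param topology optional `"mmtopology"`; when given, frame dimensions are
#'   checked against its atom count.
#' @return an object of class `"mmensemble"` with elements `frames`, `times`,
#'   `natoms`.
#' @export
new_ensemble <- function(frames, times = NULL, topology = NULL) {
  if (!length(frames)) stop("ensemble must contain at least one frame")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3) stop("frames must be N x 3 matrices")
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  n <- nrow(frames[[1]])
  nr <- vapply(frames, nrow, 1L)
  if (any(nr != n))
    stop("atom-count mismatch across frames: expected ", n, ", found ",
         nr[which(nr != n)[1]], " in frame ", which(nr != n)[1])
  if (!is.null(topology) && n != nrow(topology$atoms))
    stop("atom-count mismatch: topology has ", nrow(topology$atoms),
         " atoms, frames have ", n)
  if (!is.null(times)) {
    if (length(times) != length(frames))
      stop("times length must equal number of frames")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  structure(list(frames = frames, times = times, natoms = n),
            class = "mmensemble")
}

#' @export
print.mmensemble <- function(x, ...) {
  cat("mmgbsa ensemble:", length(x$frames), "frames of", x$natoms, "atoms")
  if (!is.null(x$times))
    cat(sprintf(" (%.6g to %.6g ps)", x$times[1], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' Keep a subset of frames
#' @param ens an `"mmensemble"`.
#' @param frames integer frame indices (kept in the given order).
#' @return an `"mmensemble"`.
#' @export
subset_frames <- function(ens, frames) {
  new_ensemble(ens$frames[frames],
               if (!is.null(ens$times)) ens$times[frames] else NULL)
}

# keep a subset of atoms in every frame
.subset_atoms_ens <- function(ens, idx) {
  new_ensemble(lapply(ens$frames, function(f) f[idx, , drop = FALSE]), ens$times)
}
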