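#' Trajectory and topology containers
#'
#' A `topology` is a data.frame with one row per atom and columns
#' `name` (PDB atom name), `resname`, `resid` (1-based author numbering),
#' and `chain`.  A `traj` binds a topology to a coordinate array of
#' dimension frames x atoms x 3, in Angstrom.
#'
#' @param name,resname,resid,chain per-atom vectors, recycled to a common
#'   length.
#' @return `topology()` returns an object of class `topology`;
#'   `trajectory()` an object of class `traj`.
#' @examples
#' top <- topology(name = "CA", resname = "ALA", resid = 1:3, chain = "A")
#' tr  <- trajectory(top, array(rnorm(2 * 3 * 3), c(2, 3, 3)))
#' nframes(tr)
#' @export
topology <- function(name, resname, resid, chain = "A") {
  top <- data.frame(name = as.character(name),
                    resname = as.character(resname),
                    resid = as.integer(resid),
                    chain = as.character(chain),
                    stringsAsFactors = FALSE)
  key <- paste(top$chain, top$resid, top$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, atom name) in topology: ",
         key[duplicated(key)][1])
  class(top) <- c("topology", "data.frame")
  top
}

#' @param topology a `topology`.
#' @param coords numeric array, frames x atoms x 3 (a single frame may be
#'   given as an atoms x 3 matrix).
#' @rdname topology
#' @export
trajectory <- function(topology, coords) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(1L, nrow(coords), 3L))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[2] != nrow(topology))
    stop("coords has ", dim(coords)[2], " atoms but topology has ",
         nrow(topology))
  if (dim(coords)[1] < 1L) stop("trajectory must have at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  structure(list(topology = topology, coords = coords), class = "traj")
}

#' @param x,traj a `traj` object.
#' @rdname topology
#' @export
nframes <- function(traj) dim(traj$coords)[1]

#' @rdname topology
#' @export
natoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame's coordinates as an atoms x 3 matrix
#' @param traj a `traj`.
#' @param i frame index.
#' @return numeric matrix, atoms x 3.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= nframes(traj))
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @param ... ignored.
#' @rdname topology
#' @export
print.traj <- function(x, ...) {
  cat(sprintf("MD trajectory: %d frames, %d atoms, %d residues\n",
              nframes(x), natoms(x),
              length(unique(paste(x$topology$chain, x$topology$resid)))))
  invisible(x)
}

#' Subset a trajectory by atom indices and/or frames
#' @param traj a `traj`.
#' @param atoms integer atom indices (topology order kept).
#' @param frames integer frame indices.
#' @return a `traj`.
#' @export
subset_traj <- function(traj, atoms = NULL, frames = NULL) {
  if (is.null(atoms)) atoms <- seq_len(natoms(traj))
  if (is.null(frames)) frames <- seq_len(nframes(traj))
  atoms <- sort(unique(as.integer(atoms)))
  top <- traj$topology[atoms, , drop = FALSE]
  rownames(top) <- NULL
  class(top) <- c("topology", "data.frame")
  trajectory(top, traj$coords[frames, atoms, , drop = FALSE])
}
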