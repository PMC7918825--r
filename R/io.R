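#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a plain single-structure
#' PDB yields a one-frame trajectory.  All models must share one topology.
#' Parsing is delegated to \code{bio3d::read.pdb}; a line scan beforehand
#' enforces the consistency the multi-model contract needs, because a file
#' whose models disagree in atom count must fail loudly, naming the model.
#'
#' @param path path to a PDB file.
#' @return a [trajectory()] (`traj`).
#' @seealso [write_pdb_models()]
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # coordinate fields must parse; report the first offending line number
  atom_lines <- lines[is_atom]
  for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
    v <- suppressWarnings(as.numeric(substr(atom_lines, fld[1], fld[2])))
    if (anyNA(v)) {
      bad <- which(is_atom)[which(is.na(v))[1]]
      stop("unreadable coordinate field at line ", bad, " of ", path)
    }
  }

  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    # count atom records per model block
    model_id <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_id, nbins = length(model_starts))
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1])[1]
      stop("inconsistent atom count across models: MODEL ", bad,
           " has ", counts[bad], " atoms, expected ", counts[1])
    }
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- topology(name = pdb$atom$elety, resname = pdb$atom$resid,
                  resid = pdb$atom$resno,
                  chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3L), drop = FALSE]
  trajectory(top, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written at the format's 0.001 Angstrom precision with
#' `MODEL`/`ENDMDL` brackets (omitted for a single frame).
#'
#' @param traj a `traj`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(traj, path) {
  top <- traj$topology
  nf <- nframes(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    nm <- ifelse(nchar(top$name) < 4L, paste0(" ", top$name), top$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(top)) %% 100000L, nm, top$resname, top$chain, top$resid,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read / write a labeled numeric matrix as delimited text
#'
#' Header row carries column labels; the first column carries row labels.
#' Round trips are lossless at the written precision (full double precision
#' by default).
#'
#' @param path file path.
#' @param sep field separator; tab by default, comma accepted.
#' @return `read_matrix` returns a numeric matrix with dimnames.
#' @export
read_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw)]
  if (length(raw) < 2L) stop("empty or header-only matrix file: ", path)
  parts <- strsplit(raw, sep, fixed = TRUE)
  ncol_expect <- length(parts[[1]])
  lens <- lengths(parts)
  if (any(lens != ncol_expect))
    stop("ragged rows in ", path, ": row ", which(lens != ncol_expect)[1],
         " has ", lens[lens != ncol_expect][1], " fields, expected ",
         ncol_expect)
  header <- parts[[1]][-1]
  body <- parts[-1]
  rn <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(p) as.numeric(p[-1]), numeric(ncol_expect - 1L)))
  vals <- t(matrix(vals, nrow = ncol_expect - 1L))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at row ", ij[1], ", column ", ij[2])
  }
  dimnames(vals) <- list(rn, header)
  vals
}

#' @param m numeric matrix (dimnames used as labels; defaults generated).
#' @param digits significant digits to keep; `NA` writes full precision.
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path, sep = "\t", digits = NA) {
  stopifnot(is.matrix(m))
  rn <- rownames(m)
  cn <- colnames(m)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(m)))
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(m)))
  fmt <- function(x) if (is.na(digits)) formatC(x, digits = 17, format = "g")
                     else formatC(x, digits = digits, format = "g")
  rows <- vapply(seq_len(nrow(m)),
                 function(i) paste(c(rn[i], fmt(m[i, ])), collapse = sep), "")
  writeLines(c(paste(c("label", cn), collapse = sep), rows), path)
  invisible(path)
}
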