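#' Resolve an atom-selection expression against a trajectory
#'
#' A small selection grammar over the topology:
#' \itemize{
#'   \item `name <atom> [<atom> ...]` — PDB atom names;
#'   \item `resid <n> [<n> ...]` — residue ids, ranges written `a:b` or `a-b`;
#'   \item `chain <id> [<id> ...]` — chain identifiers;
#'   \item `all` — every atom.
#' }
#' Terms combine with `and` and `or`; `and` binds tighter than `or`
#' (so `resid 458 or resid 510 and name CA` selects all atoms of residue 458
#' plus the CA of 510).  Parentheses are not supported.
#'
#' @param traj a `traj` (or a `topology`).
#' @param selection selection string.
#' @return sorted integer atom indices into the topology.  An empty result
#'   is allowed but raises a warning.
#' @examples
#' top <- topology(name = c("CA", "CB", "CA"), resname = "ALA",
#'                 resid = c(1, 1, 2))
#' tr <- trajectory(top, array(0, c(1, 3, 3)))
#' select_atoms(tr, "resid 1 and name CA")
#' @export
select_atoms <- function(traj, selection) {
  top <- if (inherits(traj, "traj")) traj$topology else traj
  stopifnot(inherits(top, "topology"))
  tokens <- strsplit(trimws(selection), "[[:space:]]+")[[1]]
  if (length(tokens) == 0L || !nzchar(tokens[1]))
    stop("empty selection expression")

  n <- nrow(top)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_

  parse_resid_values <- function(vals) {
    out <- integer(0)
    for (v in vals) {
      if (grepl("^[0-9]+[:-][0-9]+$", v)) {
        ab <- as.integer(strsplit(v, "[:-]")[[1]])
        out <- c(out, ab[1]:ab[2])
      } else if (grepl("^[0-9]+$", v)) {
        out <- c(out, as.integer(v))
      } else stop("selection syntax error: bad resid token '", v, "'")
    }
    out
  }

  parse_term <- function() {
    kw <- peek()
    pos <<- pos + 1L
    if (is.na(kw)) stop("selection syntax error: expression ends early")
    if (identical(kw, "all")) return(rep(TRUE, n))
    if (!kw %in% c("name", "resid", "chain"))
      stop("selection syntax error at token '", kw, "'")
    vals <- character(0)
    while (!is.na(peek()) && !peek() %in% c("and", "or")) {
      vals <- c(vals, peek())
      pos <<- pos + 1L
    }
    if (length(vals) == 0L)
      stop("selection syntax error: '", kw, "' needs at least one value")
    switch(kw,
           name  = top$name %in% vals,
           resid = top$resid %in% parse_resid_values(vals),
           chain = top$chain %in% vals)
  }

  parse_and <- function() {
    acc <- parse_term()
    while (identical(peek(), "and")) {
      pos <<- pos + 1L
      acc <- acc & parse_term()
    }
    acc
  }

  acc <- parse_and()
  while (identical(peek(), "or")) {
    pos <- pos + 1L
    acc <- acc | parse_and()
  }
  if (!is.na(peek()))
    stop("selection syntax error at token '", peek(), "'")

  idx <- which(acc)
  if (length(idx) == 0L)
    warning("selection '", selection, "' matches no atoms")
  idx
}
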