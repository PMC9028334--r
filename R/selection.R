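#' Select atoms by a small expression grammar
#'
#' Resolves a named selection against the atom metadata of a trajectory.
#' The grammar supports four keywords, each followed by one or more values
#' (values under the same keyword are OR-ed), combined with `and`, `or`,
#' `not` and parentheses:
#'
#' * `resname SOL TIP3` — residue name
#' * `resid 187 200:210` — residue id (single ids or `lo:hi` ranges)
#' * `name OW HW1` — atom name
#' * `chain A C` — chain id
#'
#' The keyword `all` matches every atom. Matching is case-sensitive, as atom
#' and residue names in topologies are.
#'
#' @param trajectory A [trajectory()].
#' @param expression Character scalar, e.g. `"resname SOL and name OW"`.
#' @param label Optional label stored with the selection (defaults to the
#'   expression text).
#' @return An object of class `"Selection"`: list with `label` and sorted
#'   unique `indices`. An empty selection is legal but reported via `message`.
#' @examples
#' tr <- trajectory(array(0, c(1, 2, 3)), box = c(10, 10, 10),
#'                  atoms = data.frame(name = c("OW", "HW1"),
#'                                     resname = "SOL", resid = 1, chain = "A"))
#' select(tr, "resname SOL and name OW")
#' @export
select <- function(trajectory, expression, label = expression) {
  if (!inherits(trajectory, "Trajectory")) stop("'trajectory' must be a Trajectory")
  mask <- eval_selection(expression, trajectory$atoms)
  idx <- which(mask)
  if (length(idx) == 0L)
    message("selection '", expression, "' matched no atoms")
  structure(list(label = label, indices = idx), class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# Resolve anything select-like to integer indices.
selection_indices <- function(sel, traj) {
  if (inherits(sel, "Selection")) return(sel$indices)
  if (is.character(sel) && length(sel) == 1L) return(select(traj, sel)$indices)
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > n_atoms(traj))) stop("atom index out of range")
    return(idx)
  }
  stop("selection must be a Selection, an expression string or atom indices")
}

# --- tiny recursive-descent parser ------------------------------------------

sel_tokenize <- function(expression) {
  spaced <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(spaced), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

sel_keywords <- c("resname", "resid", "name", "chain", "all")
sel_ops <- c("and", "or", "not", "(", ")")

eval_selection <- function(expression, atoms) {
  if (!is.character(expression) || length(expression) != 1L || !nzchar(trimws(expression)))
    stop("selection expression must be a non-empty string")
  toks <- sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$atoms <- atoms
  out <- sel_parse_or(st)
  if (st$pos <= length(st$toks))
    stop(sprintf("selection parse error at token %d ('%s') in '%s'",
                 st$pos, st$toks[st$pos], expression))
  out
}

sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
sel_next <- function(st) { t <- sel_peek(st); st$pos <- st$pos + 1L; t }

sel_parse_or <- function(st) {
  out <- sel_parse_and(st)
  while (identical(sel_peek(st), "or")) {
    sel_next(st)
    out <- out | sel_parse_and(st)
  }
  out
}

sel_parse_and <- function(st) {
  out <- sel_parse_factor(st)
  while (identical(sel_peek(st), "and")) {
    sel_next(st)
    out <- out & sel_parse_factor(st)
  }
  out
}

sel_parse_factor <- function(st) {
  t <- sel_peek(st)
  if (is.na(t))
    stop(sprintf("selection parse error: unexpected end of expression at token %d", st$pos))
  if (t == "not") { sel_next(st); return(!sel_parse_factor(st)) }
  if (t == "(") {
    sel_next(st)
    out <- sel_parse_or(st)
    if (!identical(sel_peek(st), ")"))
      stop(sprintf("selection parse error: missing ')' at token %d", st$pos))
    sel_next(st)
    return(out)
  }
  sel_parse_primary(st)
}

sel_parse_primary <- function(st) {
  kw <- sel_next(st)
  if (!(kw %in% sel_keywords))
    stop(sprintf("selection parse error at token %d: expected a keyword, got '%s'",
                 st$pos - 1L, kw))
  atoms <- st$atoms
  if (kw == "all") return(rep(TRUE, nrow(atoms)))
  vals <- character(0)
  while (!is.na(sel_peek(st)) && !(sel_peek(st) %in% c(sel_keywords, sel_ops)))
    vals <- c(vals, sel_next(st))
  if (length(vals) == 0L)
    stop(sprintf("selection parse error at token %d: keyword '%s' needs a value",
                 st$pos, kw))
  if (kw == "resid") {
    ids <- integer(0)
    for (v in vals) {
      if (grepl("^[0-9]+:[0-9]+$", v)) {
        rr <- as.integer(strsplit(v, ":")[[1]])
        ids <- c(ids, seq(rr[1], rr[2]))
      } else if (grepl("^[0-9]+$", v)) {
        ids <- c(ids, as.integer(v))
      } else {
        stop(sprintf("selection parse error: invalid resid '%s'", v))
      }
    }
    return(atoms$resid %in% ids)
  }
  col <- switch(kw, resname = "resname", name = "name", chain = "chain")
  as.character(atoms[[col]]) %in% vals
}
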