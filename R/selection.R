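#' Select atoms with a minimal selection grammar
#'
#' The grammar is a conjunction of clauses joined by `and`. Clauses:
#' * `all` — every atom
#' * `name CA CB ...` — atom names
#' * `resid 379-392 407 ...` — residue ids and inclusive ranges
#' * `resname ALA ATP ...` — residue names
#' * `element C N ...` — element symbols
#' * `noh` — heavy atoms only
#' * `role DFG_F ...` — atoms of a named functional role (requires `roles`)
#'
#' Resolution is deterministic: the same (topology, expression) always yields
#' the same 0-based, sorted, unique index vector. An empty match is allowed
#' but raises a warning.
#'
#' @param topology a [topology()].
#' @param expression selection string.
#' @param roles optional [residue_roles()] list, needed for `role` clauses.
#' @return a `kd_selection`: list with `expression` and 0-based `indices`.
#' @export
select_atoms <- function(topology, expression, roles = NULL) {
  expression <- trimws(expression)
  if (!nzchar(expression)) abort("empty selection expression")
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  mask <- rep(TRUE, nrow(topology))
  for (cl in clauses) {
    mask <- mask & clause_mask(topology, cl, roles, expression)
  }
  sel <- selection_from_mask(mask, expression)
  if (length(sel$indices) == 0) {
    warn(paste0("selection matched no atoms: '", expression, "'"))
  }
  sel
}

selection_from_mask <- function(mask, expression) {
  structure(list(expression = expression,
                 indices = sort(unique(which(mask) - 1L))),
            class = "kd_selection")
}

#' Build a selection directly from 0-based atom indices
#'
#' @param indices 0-based atom indices.
#' @param n_atoms atom count of the topology the indices refer to.
#' @param expression label carried in the selection.
#' @return a `kd_selection`.
#' @export
selection_from_indices <- function(indices, n_atoms, expression = "<indices>") {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) > 0 && (min(indices) < 0 || max(indices) >= n_atoms)) {
    abort("selection indices out of range [0, n_atoms)")
  }
  structure(list(expression = expression, indices = indices),
            class = "kd_selection")
}

clause_mask <- function(topology, clause, roles, full_expr) {
  toks <- strsplit(trimws(clause), "\\s+")[[1]]
  if (length(toks) == 0) {
    abort(paste0("syntax error in selection '", full_expr, "': empty clause"))
  }
  kw <- tolower(toks[1])
  args <- toks[-1]
  if (kw %in% c("name", "resid", "resname", "element", "role") &&
      length(args) == 0) {
    abort(sprintf("syntax error in selection '%s': clause '%s' needs arguments (position %d)",
                  full_expr, kw, regexpr(clause, full_expr, fixed = TRUE)[1]))
  }
  switch(kw,
    all = rep(TRUE, nrow(topology)),
    noh = topology$element != "H",
    name = topology$atom_name %in% args,
    resname = topology$residue_name %in% args,
    element = toupper(topology$element) %in% toupper(args),
    resid = topology$residue_id %in% parse_resid_args(args, full_expr),
    role = role_mask(topology, args, roles),
    abort(sprintf("syntax error in selection '%s': unknown keyword '%s' (position %d)",
                  full_expr, kw, regexpr(toks[1], full_expr, fixed = TRUE)[1]))
  )
}

parse_resid_args <- function(args, full_expr) {
  out <- integer(0)
  for (a in args) {
    if (grepl("^-?[0-9]+--?[0-9]+$", a) && grepl("-", substring(a, 2))) {
      parts <- regmatches(a, regexec("^(-?[0-9]+)-(-?[0-9]+)$", a))[[1]]
      out <- c(out, as.integer(parts[2]):as.integer(parts[3]))
    } else if (grepl("^-?[0-9]+$", a)) {
      out <- c(out, as.integer(a))
    } else {
      abort(sprintf("syntax error in selection '%s': bad resid token '%s'",
                    full_expr, a))
    }
  }
  out
}

role_mask <- function(topology, role_names, roles) {
  if (is.null(roles)) abort("selection uses 'role' but no roles were supplied")
  mask <- rep(FALSE, nrow(topology))
  for (rn in role_names) {
    if (!rn %in% names(roles)) {
      abort(paste0("unknown role name '", rn, "'; known roles: ",
                   paste(names(roles), collapse = ", ")))
    }
    role <- roles[[rn]]
    m <- topology$residue_id %in% role$resid
    if (!is.null(role$atom)) m <- m & topology$atom_name %in% role$atom
    mask <- mask | m
  }
  mask
}

#' @export
print.kd_selection <- function(x, ...) {
  cat(sprintf("<kd_selection> '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# 1-based row positions, the form used internally
sel_rows <- function(selection) selection$indices + 1L
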