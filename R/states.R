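# Character matrices ------------------------------------------------------
#
# A CharacterMatrix stores, for every (taxon, character) cell, a *set* of
# state symbols: a singleton for a fixed observation, several states for a
# polymorphism, and the full state space for missing/inapplicable ("?" or "-")
# data. Cells are held as integer bitmasks over the character's state space
# (bit i set = state i allowed), which makes the Sankoff tip-cost construction
# and set algebra cheap. State spaces are limited to 30 single-character
# symbols, comfortably above empirical morphological matrices (digits plus
# letters, e.g. 0-9 then A-H for a stratigraphic character with many states).

mask_from_states <- function(states, state_space) {
  if (length(states) == 0L) stop("empty state set")
  idx <- match(states, state_space)
  if (anyNA(idx)) {
    stop("state symbol(s) outside declared state space: ",
         paste(states[is.na(idx)], collapse = ", "))
  }
  sum(bitwShiftL(1L, idx - 1L))
}

states_from_mask <- function(mask, state_space) {
  state_space[bitwAnd(bitwShiftR(mask, seq_along(state_space) - 1L), 1L) == 1L]
}

full_mask <- function(n_states) bitwShiftL(1L, n_states) - 1L

mask_size <- function(mask) {
  n <- 0L
  while (mask > 0L) {
    n <- n + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  n
}

#' Create a character specification
#'
#' Describes how one character is scored: its state space, its transformation
#' regime and its weight (step multiplier). `"unordered"` characters cost one
#' step for any change (Fitch), `"ordered"` characters cost the number of
#' intervening states (`|i - j|` in state-order units), and `"irreversible"`
#' characters use an explicit asymmetric cost table (used for the
#' stratigraphic character, where reversals toward older states are forbidden).
#'
#' @param kind one of `"unordered"`, `"ordered"`, `"irreversible"`.
#' @param state_space character vector of single-character state symbols, in
#'   order (the order defines step distances for ordered characters).
#' @param weight positive step multiplier.
#' @param cost square numeric cost matrix (rows = from, cols = to), required
#'   for `"irreversible"`; `Inf` entries forbid a transformation.
#' @return an object of class `char_spec`.
#' @export
char_spec <- function(kind = c("unordered", "ordered", "irreversible"),
                      state_space, weight = 1, cost = NULL) {
  kind <- match.arg(kind)
  state_space <- as.character(state_space)
  if (any(nchar(state_space) != 1L)) stop("state symbols must be single characters")
  if (anyDuplicated(state_space)) stop("duplicated state symbols")
  if (length(state_space) > 30L) stop("state spaces are limited to 30 symbols")
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    stop("weight must be a single positive number")
  if (kind == "irreversible") {
    if (is.null(cost)) stop("irreversible characters require a cost table")
    cost <- as.matrix(cost)
    S <- length(state_space)
    if (!all(dim(cost) == c(S, S))) stop("cost table dimension mismatch")
    if (any(diag(cost) != 0)) stop("cost table must have a zero diagonal")
    if (any(cost < 0)) stop("cost table entries must be nonnegative")
  } else if (!is.null(cost)) {
    stop("cost tables are only used for irreversible characters")
  }
  structure(list(kind = kind, state_space = state_space,
                 weight = weight, cost = cost),
            class = "char_spec")
}

#' Construct a character matrix
#'
#' @param taxa character vector of unique taxon labels (row order).
#' @param cells list with one entry per character; each entry is a list (or
#'   vector) of length `length(taxa)` whose elements are character vectors of
#'   state symbols (singleton = fixed, several = polymorphic). Use the full
#'   state space, `"?"`, or `"-"` for missing/inapplicable.
#' @param specs list of [char_spec()] objects, one per character.
#' @return an object of class `char_matrix` with fields `taxa`, `masks` (list
#'   of per-character integer bitmask vectors) and `specs`.
#' @export
char_matrix <- function(taxa, cells, specs) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("taxon labels must be unique")
  if (length(cells) != length(specs))
    stop("cells and specs describe different numbers of characters")
  masks <- vector("list", length(specs))
  for (c_i in seq_along(specs)) {
    spec <- specs[[c_i]]
    if (!inherits(spec, "char_spec")) stop("specs must be char_spec objects")
    col <- cells[[c_i]]
    if (length(col) != length(taxa))
      stop(sprintf("character %d has %d cells for %d taxa",
                   c_i, length(col), length(taxa)))
    S <- length(spec$state_space)
    masks[[c_i]] <- vapply(col, function(st) {
      st <- as.character(unlist(st, use.names = FALSE))
      if (length(st) == 1L && st %in% c("?", "-")) return(full_mask(S))
      mask_from_states(st, spec$state_space)
    }, integer(1), USE.NAMES = FALSE)
  }
  new_char_matrix(taxa, masks, specs)
}

# Internal constructor for pre-built masks.
new_char_matrix <- function(taxa, masks, specs) {
  structure(list(taxa = as.character(taxa), masks = masks, specs = specs),
            class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat(sprintf("char_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), length(x$specs),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of characters in a matrix
#' @param m a `char_matrix`.
#' @return integer count.
#' @export
n_char <- function(m) length(m$specs)

#' Read a cell as a set of state symbols
#' @param m a `char_matrix`.
#' @param taxon taxon label.
#' @param char character index.
#' @return character vector of allowed state symbols.
#' @export
cell_states <- function(m, taxon, char) {
  i <- match(taxon, m$taxa)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  states_from_mask(m$masks[[char]][i], m$specs[[char]]$state_space)
}

# TRUE where the cell is the full state set (missing/inapplicable).
cell_is_missing <- function(m, char) {
  S <- length(m$specs[[char]]$state_space)
  m$masks[[char]] == full_mask(S)
}

# Coerce a user-facing column (named list/vector of state sets, or an integer
# mask vector) to a mask vector aligned with `taxa`.
column_masks <- function(column, spec, taxa) {
  S <- length(spec$state_space)
  if (is.numeric(column) || is.integer(column)) {
    masks <- setNames(as.integer(column), names(column))
    if (is.null(names(masks))) {
      if (length(masks) != length(taxa)) stop("column length does not match taxa")
      return(masks)
    }
  } else {
    masks <- vapply(column, function(st) {
      st <- as.character(unlist(st, use.names = FALSE))
      if (length(st) == 1L && st %in% c("?", "-")) return(full_mask(S))
      mask_from_states(st, spec$state_space)
    }, integer(1))
  }
  if (is.null(names(masks))) stop("named column required")
  idx <- match(taxa, names(masks))
  if (anyNA(idx)) stop("column lacks cells for: ",
                       paste(taxa[is.na(idx)], collapse = ", "))
  unname(masks[idx])
}

#' Validate a character matrix
#'
#' Checks the container invariants: unique taxa, one cell per (taxon,
#' character), masks within each declared state space, positive weights, and
#' well-formed cost tables.
#'
#' @param m a `char_matrix`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_char_matrix <- function(m) {
  stopifnot(inherits(m, "char_matrix"))
  if (anyDuplicated(m$taxa)) stop("taxon labels must be unique")
  if (length(m$masks) != length(m$specs)) stop("masks/specs length mismatch")
  for (c_i in seq_along(m$specs)) {
    spec <- m$specs[[c_i]]
    S <- length(spec$state_space)
    mk <- m$masks[[c_i]]
    if (length(mk) != length(m$taxa))
      stop(sprintf("character %d: %d cells for %d taxa", c_i, length(mk), length(m$taxa)))
    if (any(mk < 1L) || any(mk > full_mask(S)))
      stop(sprintf("character %d: cell outside declared state space", c_i))
    if (spec$weight <= 0) stop(sprintf("character %d: nonpositive weight", c_i))
  }
  invisible(TRUE)
}

#' Subset a character matrix
#'
#' @param m a `char_matrix`.
#' @param taxa optional taxon labels to keep (in the given order).
#' @param chars optional character indices to keep.
#' @return a `char_matrix`.
#' @export
subset_matrix <- function(m, taxa = NULL, chars = NULL) {
  if (is.null(taxa)) taxa <- m$taxa
  idx <- match(taxa, m$taxa)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  if (is.null(chars)) chars <- seq_along(m$specs)
  new_char_matrix(m$taxa[idx],
                  lapply(m$masks[chars], `[`, idx),
                  m$specs[chars])
}

#' Combine two character matrices over the same taxa
#'
#' Columns of `b` are appended to `a`; both must cover an identical taxon set
#' (rows of `b` are reordered to `a`'s order).
#'
#' @param a,b `char_matrix` objects.
#' @return a `char_matrix`.
#' @export
cbind_matrices <- function(a, b) {
  if (!setequal(a$taxa, b$taxa)) stop("matrices cover different taxon sets")
  b <- subset_matrix(b, taxa = a$taxa)
  new_char_matrix(a$taxa, c(a$masks, b$masks), c(a$specs, b$specs))
}
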