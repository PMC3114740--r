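# Trees, age tables, alignments -------------------------------------------

#' Read a Newick tree
#'
#' @param path_or_text a file path, or a Newick string (recognized by the
#'   presence of parentheses/semicolon).
#' @return a `phylo` tree, rooted as written (no automatic outgroup
#'   rerooting).
#' @export
read_newick <- function(path_or_text) {
  txt <- if (length(path_or_text) == 1 && grepl("[(;]", path_or_text)) {
    path_or_text
  } else {
    if (!file.exists(path_or_text)) stop("file not found: ", path_or_text)
    paste(readLines(path_or_text, warn = FALSE), collapse = "")
  }
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("Newick parse error")
  labs <- if (inherits(tr, "multiPhylo")) tr[[1]]$tip.label else tr$tip.label
  if (anyDuplicated(labs)) stop("duplicate tip labels")
  tr
}

#' Write a tree (or trees) as Newick
#'
#' @param tree a `phylo` or list of `phylo`.
#' @param path optional output path; when `NULL` the Newick text is returned.
#' @return the Newick string(s), invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- if (inherits(tree, "phylo")) ape::write.tree(tree) else
    vapply(tree, ape::write.tree, "")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a taxon age table
#'
#' Expects delimited text (comma or tab, sniffed from the header) with
#' columns `taxon`, `FAD`, `LAD`, `extant` (case-insensitive). Extant taxa
#' are forced to age 0 (the present day); fossil rows must satisfy
#' `FAD >= LAD >= 0`, and a missing LAD defaults to the FAD.
#'
#' @param path path to the table.
#' @return an [age_table()].
#' @export
read_age_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("taxon", "fad", "lad", "extant")
  if (!all(need %in% names(df)))
    stop("age table must have columns taxon, FAD, LAD, extant")
  extant <- df$extant
  if (!is.logical(extant))
    extant <- tolower(as.character(extant)) %in% c("true", "t", "1", "yes")
  fad <- suppressWarnings(as.numeric(df$fad))
  lad <- suppressWarnings(as.numeric(df$lad))
  fad[extant] <- 0
  lad[extant] <- 0
  age_table(df$taxon, fad, lad, extant)
}

#' Write an age table
#'
#' @param ages an [age_table()].
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_age_table <- function(ages, path) {
  write.table(data.frame(taxon = ages$taxon, FAD = ages$fad, LAD = ages$lad,
                         extant = tolower(as.character(ages$extant))),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Midpoint age of a stratigraphic interval
#'
#' First/last appearance datums are taken as the average of the oldest and
#' youngest bounds of the smallest reported stratigraphic interval.
#'
#' @param oldest,youngest interval bounds in Ma, `oldest >= youngest >= 0`.
#' @return `(oldest + youngest) / 2`, vectorized.
#' @export
interval_midpoint_age <- function(oldest, youngest) {
  if (any(youngest < 0) || any(oldest < youngest))
    stop("need oldest >= youngest >= 0")
  (oldest + youngest) / 2
}

# Gap coding ---------------------------------------------------------------

gap_runs <- function(seq_chars) {
  r <- rle(seq_chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Simple indel gap coding of an alignment
#'
#' Implements simple gap coding: every distinct gap (unique start and end
#' position) in the alignment becomes one binary character. A taxon scores 1
#' if it has exactly that gap, `?` (missing) if one of its gaps strictly
#' contains it (the smaller indel is unobservable inside the larger
#' deletion), and 0 otherwise.
#'
#' @param alignment a named character vector of equal-length aligned
#'   sequences (gap symbol `-`), or a path to a FASTA file.
#' @return a binary `char_matrix` with one unordered character per distinct
#'   gap; the character order follows (start, end). Zero characters when the
#'   alignment has no gaps.
#' @export
simple_gap_code <- function(alignment) {
  if (length(alignment) == 1 && is.character(alignment) && file.exists(alignment)) {
    bin <- ape::read.FASTA(alignment)
    alignment <- vapply(as.character(bin), function(x)
      paste(toupper(x), collapse = ""), "")
  }
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment needs unique sequence names")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("ragged alignment: unequal sequence lengths")
  taxa <- names(alignment)
  runs <- lapply(alignment, function(s) gap_runs(strsplit(s, "")[[1]]))
  all_spans <- unique(do.call(rbind, runs))
  if (is.null(all_spans) || nrow(all_spans) == 0)
    return(new_char_matrix(taxa, list(), list()))
  all_spans <- all_spans[order(all_spans[, 1], all_spans[, 2]), , drop = FALSE]
  spec <- char_spec("unordered", c("0", "1"))
  masks <- lapply(seq_len(nrow(all_spans)), function(k) {
    sp <- all_spans[k, ]
    vapply(taxa, function(tx) {
      rn <- runs[[tx]]
      if (nrow(rn) == 0) return(mask_from_states("0", c("0", "1")))
      exact <- any(rn[, 1] == sp[1] & rn[, 2] == sp[2])
      if (exact) return(mask_from_states("1", c("0", "1")))
      contains <- any(rn[, 1] <= sp[1] & rn[, 2] >= sp[2] &
                        (rn[, 2] - rn[, 1] > sp[2] - sp[1]))
      if (contains) full_mask(2L) else mask_from_states("0", c("0", "1"))
    }, integer(1), USE.NAMES = FALSE)
  })
  new_char_matrix(taxa, masks, rep(list(spec), nrow(all_spans)))
}
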