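# NEXUS character matrices -------------------------------------------------
#
# A pragmatic reader/writer for the DATA/CHARACTERS + ASSUMPTIONS dialect
# used by PAUP*/MacClade-style morphology matrices: FORMAT SYMBOLS declares a
# single matrix-wide symbol list (state symbols are single alphanumerics;
# matrices with more than ten states continue with letters), "{...}" encodes
# polymorphism, MISSING/GAP symbols map to the full state set, INTERLEAVE is
# supported, and the ASSUMPTIONS block carries TYPESET (ord/unord) and WTSET
# (per-character weights). The declared symbol list becomes every character's
# state space, which is the convention the rest of the package's generators
# follow.

strip_nexus_comments <- function(text) {
  gsub("\\[[^]]*\\]", " ", text)
}

nexus_blocks <- function(text) {
  m <- gregexpr("(?is)begin\\s+(\\w+)\\s*;(.*?)end\\s*;", text, perl = TRUE)
  starts <- m[[1]]
  if (starts[1] == -1) return(list())
  out <- list()
  caps <- regmatches(text, m)[[1]]
  for (blk in caps) {
    name <- tolower(sub("(?is)^begin\\s+(\\w+).*", "\\1", blk, perl = TRUE))
    body <- sub("(?is)^begin\\s+\\w+\\s*;", "", blk, perl = TRUE)
    body <- sub("(?is)end\\s*;\\s*$", "", body, perl = TRUE)
    out[[name]] <- body
  }
  out
}

parse_cells_string <- function(s, symbols, missing_sym, gap_sym, line_no) {
  S <- length(symbols)
  cells <- integer(0)
  i <- 1L
  chars <- strsplit(s, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      states <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        if (!(chars[j] %in% c(" ", ","))) states <- c(states, chars[j])
        j <- j + 1L
      }
      if (j > length(chars))
        stop("NEXUS parse error at line ", line_no, ": unclosed polymorphism")
      cells <- c(cells, mask_from_states(states, symbols))
      i <- j + 1L
    } else if (ch == missing_sym || ch == gap_sym) {
      cells <- c(cells, full_mask(S))
      i <- i + 1L
    } else {
      if (!(ch %in% symbols))
        stop("NEXUS parse error at line ", line_no, ": symbol '", ch,
             "' not in declared SYMBOLS")
      cells <- c(cells, mask_from_states(ch, symbols))
      i <- i + 1L
    }
  }
  cells
}

# "2 4-6 9" -> integer vector
parse_char_list <- function(s, n_char) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  out <- integer(0)
  for (t in toks) {
    if (grepl("^\\d+-\\d+$", t)) {
      ab <- as.integer(strsplit(t, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (t == ".") {
      out <- c(out, n_char)
    } else {
      out <- c(out, as.integer(t))
    }
  }
  out
}

#' Read a NEXUS character matrix
#'
#' Parses a DATA or CHARACTERS block (interleaved or not) into a
#' [char_matrix()]; polymorphic cells `{01}` become multi-state sets and the
#' MISSING/GAP symbols the full state set. TYPESET (`ord`/`unord`) and WTSET
#' entries in an ASSUMPTIONS block are applied to the character specs; the
#' defaults are unordered with weight 1.
#'
#' @param path path to a NEXUS file.
#' @return a `char_matrix`.
#' @export
read_nexus <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  text <- strip_nexus_comments(paste(readLines(path, warn = FALSE), collapse = "\n"))
  blocks <- nexus_blocks(text)
  data_blk <- blocks[["data"]] %||% blocks[["characters"]]
  if (is.null(data_blk)) stop("no DATA or CHARACTERS block found")

  dim_m <- regmatches(data_blk, regexpr("(?is)dimensions[^;]*;", data_blk, perl = TRUE))
  if (!length(dim_m)) stop("DIMENSIONS statement missing")
  ntax <- as.integer(sub("(?is).*ntax\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  nchar_ <- as.integer(sub("(?is).*nchar\\s*=\\s*(\\d+).*", "\\1", dim_m, perl = TRUE))
  if (is.na(ntax) || is.na(nchar_)) stop("could not parse NTAX/NCHAR")

  fmt <- regmatches(data_blk, regexpr("(?is)format[^;]*;", data_blk, perl = TRUE))
  symbols <- c("0", "1")
  missing_sym <- "?"; gap_sym <- "-"
  if (length(fmt)) {
    sm <- regmatches(fmt, regexpr('(?is)symbols\\s*=\\s*"[^"]*"', fmt, perl = TRUE))
    if (length(sm)) {
      sym_str <- sub('(?is).*"([^"]*)".*', "\\1", sm, perl = TRUE)
      symbols <- strsplit(gsub("\\s", "", sym_str), "")[[1]]
    }
    mm <- regmatches(fmt, regexpr("(?is)missing\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(mm)) missing_sym <- substr(mm, nchar(mm), nchar(mm))
    gm <- regmatches(fmt, regexpr("(?is)gap\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(gm)) gap_sym <- substr(gm, nchar(gm), nchar(gm))
  }

  mat_m <- regmatches(data_blk,
                      regexpr("(?is)matrix(.*?);", data_blk, perl = TRUE))
  if (!length(mat_m)) stop("MATRIX statement missing")
  body <- sub("(?is)^matrix", "", mat_m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- strsplit(body, "\n")[[1]]
  taxa <- character(0)
  rows <- list()
  for (li in seq_along(lines)) {
    ln <- trimws(lines[li])
    if (!nzchar(ln)) next
    lm <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s*(.*)$", ln))[[1]]
    if (length(lm) < 3) stop("NEXUS parse error at matrix line ", li, ": '", ln, "'")
    tax <- gsub("^['\"]|['\"]$", "", lm[2])
    cells <- parse_cells_string(lm[3], symbols, missing_sym, gap_sym, li)
    if (!(tax %in% taxa)) { taxa <- c(taxa, tax); rows[[tax]] <- integer(0) }
    rows[[tax]] <- c(rows[[tax]], cells)
  }
  if (length(taxa) != ntax)
    stop(sprintf("dimension error: %d taxa in MATRIX, NTAX=%d", length(taxa), ntax))
  lens <- vapply(rows, length, 1L)
  if (any(lens != nchar_))
    stop(sprintf("dimension error: taxon '%s' has %d characters, NCHAR=%d",
                 taxa[which(lens != nchar_)[1]], lens[which(lens != nchar_)[1]], nchar_))

  kinds <- rep("unordered", nchar_)
  weights <- rep(1, nchar_)
  assump <- blocks[["assumptions"]]
  if (!is.null(assump)) {
    for (ts in regmatches(assump, gregexpr("(?is)typeset[^;]*;", assump, perl = TRUE))[[1]]) {
      spec_str <- sub("(?is).*?=", "", ts, perl = TRUE)
      spec_str <- sub(";\\s*$", "", spec_str)
      for (grp in strsplit(spec_str, ",")[[1]]) {
        kv <- strsplit(grp, ":")[[1]]
        if (length(kv) != 2) next
        kind <- tolower(trimws(kv[1]))
        ids <- parse_char_list(kv[2], nchar_)
        if (kind %in% c("ord", "ordered")) kinds[ids] <- "ordered"
        if (kind %in% c("unord", "unordered")) kinds[ids] <- "unordered"
      }
    }
    for (ws in regmatches(assump, gregexpr("(?is)wtset[^;]*;", assump, perl = TRUE))[[1]]) {
      spec_str <- sub("(?is).*?=", "", ws, perl = TRUE)
      spec_str <- sub(";\\s*$", "", spec_str)
      for (grp in strsplit(spec_str, ",")[[1]]) {
        kv <- strsplit(grp, ":")[[1]]
        if (length(kv) != 2) next
        w <- as.numeric(trimws(kv[1]))
        ids <- parse_char_list(kv[2], nchar_)
        weights[ids] <- w
      }
    }
  }
  specs <- lapply(seq_len(nchar_), function(c_i)
    char_spec(kinds[c_i], symbols, weight = weights[c_i]))
  masks <- lapply(seq_len(nchar_), function(c_i)
    vapply(taxa, function(tx) rows[[tx]][c_i], integer(1), USE.NAMES = FALSE))
  new_char_matrix(taxa, masks, specs)
}

cell_to_string <- function(mask, symbols, S) {
  if (mask == full_mask(S)) return("?")
  st <- states_from_mask(mask, symbols)
  if (length(st) == 1) st else paste0("{", paste(st, collapse = ""), "}")
}

compress_char_list <- function(ids) {
  ids <- sort(ids)
  runs <- split(ids, cumsum(c(1, diff(ids) != 1)))
  paste(vapply(runs, function(r)
    if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)]),
    ""), collapse = " ")
}

#' Write a character matrix to NEXUS
#'
#' Emits a DATA block (symbols are the union of all character state spaces)
#' and an ASSUMPTIONS block recording ordered characters (TYPESET) and
#' non-unit weights (WTSET) so that [read_nexus()] reproduces the matrix.
#'
#' @param m a `char_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  validate_char_matrix(m)
  if (any(vapply(m$specs, `[[`, "", "kind") == "irreversible"))
    stop("irreversible characters have no standard NEXUS representation")
  symbols <- unique(unlist(lapply(m$specs, `[[`, "state_space")))
  nc <- n_char(m)
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), nc),
             sprintf('FORMAT SYMBOLS="%s" MISSING=? GAP=-;',
                     paste(symbols, collapse = "")),
             "MATRIX")
  S_all <- length(symbols)
  pad <- max(nchar(m$taxa)) + 2L
  for (t_i in seq_along(m$taxa)) {
    row <- vapply(seq_len(nc), function(c_i) {
      spec <- m$specs[[c_i]]
      mask <- m$masks[[c_i]][t_i]
      S <- length(spec$state_space)
      if (mask == full_mask(S)) return("?")
      st <- states_from_mask(mask, spec$state_space)
      if (length(st) == 1) st else paste0("{", paste(st, collapse = ""), "}")
    }, "")
    lines <- c(lines, paste0(formatC(m$taxa[t_i], width = -pad),
                             paste(row, collapse = "")))
  }
  lines <- c(lines, ";", "END;")
  ordered_ids <- which(vapply(m$specs, `[[`, "", "kind") == "ordered")
  w <- vapply(m$specs, `[[`, 1, "weight")
  assump <- character(0)
  if (length(ordered_ids) || nc == 0 || any(w != 1)) {
    assump <- c("BEGIN ASSUMPTIONS;")
    if (length(ordered_ids)) {
      unord <- setdiff(seq_len(nc), ordered_ids)
      entry <- paste0("ord: ", compress_char_list(ordered_ids))
      if (length(unord)) entry <- paste0(entry, ", unord: ", compress_char_list(unord))
      assump <- c(assump, sprintf("TYPESET * kinds = %s;", entry))
    }
    if (any(w != 1)) {
      groups <- split(seq_len(nc), w)
      entries <- vapply(names(groups), function(g)
        paste0(format(as.numeric(g), digits = 10), ": ",
               compress_char_list(groups[[g]])), "")
      assump <- c(assump, sprintf("WTSET * weights = %s;",
                                  paste(entries, collapse = ", ")))
    }
    assump <- c(assump, "END;")
  }
  writeLines(c(lines, assump), path)
  invisible(path)
}
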