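# Selection expression grammar:
#
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | primary
#   primary := 'resid' ranges | 'resname' names | 'name' names | keyword
#   ranges  := A[-B][,C[-D]...]          (inclusive at both ends)
#   names   := X[,Y...]
#   keyword := 'ca' | 'backbone' | 'heavy' | 'protein' | 'water' | 'all'
#
# `heavy` is every atom whose element is not H or D; `ca` is the CA atom of
# amino-acid residues; `backbone` is N, CA, C, O of amino-acid residues.

.tokenize_selection <- function(expression) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expression, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("empty selection expression")
  data.frame(
    text = regmatches(expression, gregexpr(pat, expression, perl = TRUE))[[1]],
    pos = as.integer(m),
    stringsAsFactors = FALSE
  )
}

.parse_ranges <- function(token, pos) {
  parts <- strsplit(token, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts)))
    stop("malformed residue range at position ", pos)
  out <- integer(0)
  for (p in parts) {
    if (grepl("^-?\\d+--?\\d+$", p)) {
      # split on the dash separating the two bounds (first dash after digit)
      ab <- regmatches(p, regexec("^(-?\\d+)-(-?\\d+)$", p))[[1]]
      a <- as.integer(ab[2]); b <- as.integer(ab[3])
      if (a > b) stop("descending residue range '", p, "' at position ", pos)
      out <- c(out, a:b)
    } else if (grepl("^-?\\d+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("malformed residue range '", p, "' at position ", pos)
    }
  }
  out
}

.selection_masks <- function(atoms) {
  is_aa <- atoms$residue_name %in% .STANDARD_AA
  list(
    ca = is_aa & atoms$atom_name == "CA",
    backbone = is_aa & atoms$atom_name %in% c("N", "CA", "C", "O"),
    heavy = !(atoms$element %in% c("H", "D")),
    protein = is_aa,
    water = atoms$residue_name %in% .WATER_RESNAMES,
    all = rep(TRUE, nrow(atoms))
  )
}

.parse_selection <- function(tokens, atoms) {
  masks <- .selection_masks(atoms)
  i <- 0L
  peek <- function() if (i < nrow(tokens)) tolower(tokens$text[i + 1L]) else NA_character_
  advance <- function() {
    i <<- i + 1L
    tokens[i, ]
  }
  expect_more <- function(what) {
    if (i >= nrow(tokens))
      stop("expected ", what, " at end of expression")
  }

  parse_primary <- function() {
    expect_more("a selection term")
    tok <- advance()
    word <- tolower(tok$text)
    if (word == "(") {
      res <- parse_expr()
      expect_more("')'")
      closing <- advance()
      if (closing$text != ")")
        stop("expected ')' at position ", closing$pos)
      return(res)
    }
    if (word %in% names(masks)) return(masks[[word]])
    if (word == "resid") {
      expect_more("residue ranges after 'resid'")
      rtok <- advance()
      ids <- .parse_ranges(rtok$text, rtok$pos)
      return(atoms$residue_id %in% ids)
    }
    if (word %in% c("resname", "name")) {
      expect_more(paste0("names after '", word, "'"))
      ntok <- advance()
      vals <- toupper(strsplit(ntok$text, ",", fixed = TRUE)[[1]])
      col <- if (word == "resname") atoms$residue_name else atoms$atom_name
      return(toupper(col) %in% vals)
    }
    stop("unexpected token '", tok$text, "' at position ", tok$pos)
  }

  parse_factor <- function() {
    if (!is.na(peek()) && peek() == "not") {
      advance()
      return(!parse_factor())
    }
    parse_primary()
  }

  parse_term <- function() {
    res <- parse_factor()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      res <- res & parse_factor()
    }
    res
  }

  parse_expr <- function() {
    res <- parse_term()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      res <- res | parse_term()
    }
    res
  }

  out <- parse_expr()
  if (i < nrow(tokens))
    stop("unexpected token '", tokens$text[i + 1L], "' at position ",
         tokens$pos[i + 1L])
  out
}

#' Resolve a selection expression on a topology
#'
#' Returns the ordered set of 1-based atom indices matched by `expression`
#' on the atom table of `topology`. Residue ranges are inclusive at both
#' ends and refer to file residue numbering verbatim. A syntactically valid
#' expression matching zero atoms yields an empty selection, not an error.
#'
#' @param topology a [Structure()] or [Ensemble()]
#' @param expression selection text, e.g. `"resid 113-116 and ca"`,
#'   `"heavy and not water"`
#' @return an object of class `Selection`: list with `indices` (sorted,
#'   unique, 1-based) and `expression`
#' @export
select <- function(topology, expression) {
  atoms <- if (inherits(topology, "Ensemble")) topology$topology$atoms
           else topology$atoms
  mask <- .parse_selection(.tokenize_selection(expression), atoms)
  structure(list(indices = which(mask), expression = expression),
            class = "Selection")
}

#' @export
print.Selection <- function(x, ...) {
  cat(sprintf("Selection '%s': %d atoms\n", x$expression, length(x$indices)))
  invisible(x)
}

# Accept a Selection, an integer vector of indices, or an expression string;
# used by every geometry/contact operation so callers can pass any of the
# three.
resolve_selection <- function(topology, sel, allow_empty = FALSE) {
  idx <- if (inherits(sel, "Selection")) sel$indices
         else if (is.character(sel)) select(topology, sel)$indices
         else as.integer(sel)
  N <- if (inherits(topology, "Ensemble")) n_atoms(topology) else nrow(topology$atoms)
  if (any(idx < 1L | idx > N)) stop("selection index out of range")
  idx <- sort(unique(idx))
  if (!allow_empty && length(idx) == 0L) stop("empty selection")
  idx
}
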