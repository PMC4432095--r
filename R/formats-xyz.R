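# XYZ reading/writing.  Multiple concatenated blocks are read as frames of
# one molecule; an optional fifth column carries per-atom point charges.
# Coordinates are serialized as "%.6f" angstrom so that write/read/write
# cycles are byte-stable.

#' Read an XYZ file
#'
#' @param path file path.
#' @return a molecule; concatenated blocks become `frames` (the first
#'   block defines elements and current coordinates).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parse_xyz_lines(lines, path)$molecule
}

parse_xyz_lines <- function(lines, what = "<xyz>") {
  i <- 1L
  blocks <- list()
  elements <- NULL
  charges <- NULL
  title <- NULL
  repeat {
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L)
      stop(sprintf("%s line %d: expected an atom count", what, i),
           call. = FALSE)
    if (i + 1L + n > length(lines) + 0L && n > 0L)
      stop(sprintf("%s: atom count %d exceeds remaining lines", what, n),
           call. = FALSE)
    if (is.null(title) && i + 1L <= length(lines)) title <- lines[i + 1L]
    el <- character(n); xyz <- matrix(0, n, 3); q <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
      if (length(tok) < 4L)
        stop(sprintf("%s line %d: expected 'Symbol x y z [charge]'",
                     what, ln), call. = FALSE)
      co <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(co))
        stop(sprintf("%s line %d: unparseable coordinate", what, ln),
             call. = FALSE)
      el[k] <- normalize_symbol(tok[1])
      xyz[k, ] <- co
      if (length(tok) >= 5L) {
        qq <- suppressWarnings(as.numeric(tok[5]))
        if (is.na(qq))
          stop(sprintf("%s line %d: unparseable charge", what, ln),
               call. = FALSE)
        q[k] <- qq
      }
    }
    if (is.null(elements)) { elements <- el; charges <- q }
    else if (!identical(el, elements))
      stop(sprintf("%s: frame %d has different atoms", what,
                   length(blocks) + 1L), call. = FALSE)
    blocks[[length(blocks) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (length(blocks) == 0L)
    stop(sprintf("%s: empty file", what), call. = FALSE)
  meta <- list()
  if (!is.null(title) && nzchar(trimws(title))) meta$title <- trimws(title)
  mol <- molecule(elements, blocks[[1]], charge = charges,
                  frames = if (length(blocks) > 1L) blocks else NULL,
                  metadata = meta)
  list(molecule = mol, lines_used = i - 1L)
}

normalize_symbol <- function(s) {
  s <- trimws(s)
  if (toupper(s) == DUMMY) return(DUMMY)
  paste0(toupper(substr(s, 1, 1)), tolower(substring(s, 2)))
}

format_xyz_block <- function(el, xyz, charge = NULL, title = "") {
  has_q <- !is.null(charge) && any(!is.na(charge))
  body <- vapply(seq_along(el), function(k) {
    base <- sprintf("%-3s %13.6f %13.6f %13.6f", el[k],
                    xyz[k, 1], xyz[k, 2], xyz[k, 3])
    if (has_q)
      base <- sprintf("%s %13.6f", base,
                      if (is.na(charge[k])) 0 else charge[k])
    base
  }, "")
  c(sprintf("%d", length(el)), title, body)
}

#' Write an XYZ file
#'
#' Multi-frame molecules are written as concatenated blocks; charges are
#' written as a fifth column when any atom carries one.
#'
#' @param mol a molecule.
#' @param path output path.
#' @export
write_xyz <- function(mol, path) {
  title <- if (!is.null(mol$metadata$title)) mol$metadata$title else ""
  frames <- if (!is.null(mol$frames)) mol$frames else list(mol$xyz)
  out <- unlist(lapply(frames, function(f)
    format_xyz_block(mol$element, f, mol$charge, title)))
  writeLines(out, path)
  invisible(path)
}
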