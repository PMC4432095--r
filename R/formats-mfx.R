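# The native document format (.mfx): a plain XYZ header followed by an
# optional XML root carrying the non-geometric payload in sections
# (dipole, metadata, extra frames, grids, orbitals, objects, view).  Any
# valid XYZ file is therefore a valid document, and any program that
# understands XYZ can read the first 2+n lines of an .mfx file.  Unknown
# XML sections are preserved verbatim on round-trip.  The writer is
# deterministic ("%.6f" coordinates, "%.10e" grid values), so
# write-read-write cycles are byte-identical.

MFX_VERSION <- "1.0"

#' Construct a document
#'
#' @param molecule a molecule.
#' @param grids list of [scalar_grid()]s.
#' @param orbitals data frame of orbital records (see [orbital_records()]),
#'   whose `grid` column indexes into `grids`.
#' @param objects list of [geom_object()]s.
#' @param view optional list with `orientation` (3 x 3 matrix) and `scale`.
#' @param extra character vector of verbatim XML sections kept from
#'   parsing.
#' @return an object of class `"mfx_doc"`.
#' @export
mfx_doc <- function(molecule, grids = list(), orbitals = NULL,
                    objects = list(), view = NULL, extra = character()) {
  structure(list(molecule = molecule, grids = grids, orbitals = orbitals,
                 objects = objects, view = view, extra = extra),
            class = "mfx_doc")
}

#' @export
print.mfx_doc <- function(x, ...) {
  cat(sprintf("document: %d atoms, %d grids, %d orbitals, %d objects\n",
              n_atoms(x$molecule), length(x$grids),
              if (is.null(x$orbitals)) 0L else nrow(x$orbitals),
              length(x$objects)))
  invisible(x)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

num10 <- function(x) paste(sprintf("%.10g", x), collapse = " ")

#' Read a document
#'
#' @param path file path (`.mfx`, or any XYZ file).
#' @return an [mfx_doc()].
#' @export
read_mfx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  xml_start <- which(startsWith(trimws(lines), "<"))
  xml_start <- if (length(xml_start) > 0L) xml_start[1] else NA_integer_
  head_lines <- if (is.na(xml_start)) lines else lines[seq_len(xml_start - 1L)]
  if (length(head_lines) == 0L)
    stop("document must start with an XYZ header", call. = FALSE)
  parsed <- tryCatch(parse_xyz_lines(head_lines, path),
                     error = function(e)
                       stop("invalid XYZ header: ", conditionMessage(e),
                            call. = FALSE))
  doc <- mfx_doc(parsed$molecule)
  if (is.na(xml_start)) return(doc)
  xml_text <- paste(lines[xml_start:length(lines)], collapse = "\n")
  root <- tryCatch(xml2::read_xml(xml_text), error = function(e)
    stop("malformed XML section after XYZ header: ",
         conditionMessage(e), call. = FALSE))
  parse_mfx_xml(doc, root)
}

parse_mfx_xml <- function(doc, root) {
  mol <- doc$molecule
  for (node in xml2::xml_children(root)) {
    nm <- xml2::xml_name(node)
    if (nm == "dipole") {
      mol$metadata$dipole <- as.numeric(
        strsplit(trimws(xml2::xml_text(node)), "[[:space:]]+")[[1]])
    } else if (nm == "meta") {
      key <- xml2::xml_attr(node, "key")
      val <- trimws(xml2::xml_text(node))
      num <- suppressWarnings(as.numeric(
        strsplit(val, "[[:space:]]+")[[1]]))
      mol$metadata[[key]] <- if (!anyNA(num)) num else val
    } else if (nm == "frames") {
      fr <- lapply(xml2::xml_find_all(node, "./frame"), function(f)
        matrix(as.numeric(
          strsplit(trimws(xml2::xml_text(f)), "[[:space:]]+")[[1]]),
          ncol = 3, byrow = TRUE))
      mol$frames <- c(list(mol$xyz), fr)
    } else if (nm == "grid") {
      doc$grids[[length(doc$grids) + 1L]] <- parse_grid_node(node)
    } else if (nm == "orbitals") {
      doc$orbitals <- parse_orbitals_node(node)
    } else if (nm == "object") {
      doc$objects[[length(doc$objects) + 1L]] <- parse_object_node(node)
    } else if (nm == "view") {
      doc$view <- list(
        orientation = matrix(as.numeric(strsplit(trimws(
          xml2::xml_text(xml2::xml_find_first(node, "./orientation"))),
          "[[:space:]]+")[[1]]), 3, 3, byrow = TRUE),
        scale = as.numeric(xml2::xml_text(
          xml2::xml_find_first(node, "./scale"))))
    } else {
      doc$extra <- c(doc$extra, as.character(node))
    }
  }
  doc$molecule <- mol
  doc
}

node_nums <- function(node, xpath) {
  as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(node, xpath))), "[[:space:]]+")[[1]])
}

parse_grid_node <- function(node) {
  shape <- as.integer(node_nums(node, "./shape"))
  axes <- do.call(rbind, lapply(xml2::xml_find_all(node, "./axis"),
                                function(a) as.numeric(strsplit(
                                  trimws(xml2::xml_text(a)),
                                  "[[:space:]]+")[[1]])))
  vals <- node_nums(node, "./values")
  scalar_grid(node_nums(node, "./origin"), axes, vals, shape = shape,
              label = xml2::xml_attr(node, "label"))
}

parse_orbitals_node <- function(node) {
  orbs <- xml2::xml_find_all(node, "./orbital")
  recs <- lapply(orbs, function(o) {
    g <- xml2::xml_attr(o, "grid")
    data.frame(
      index = as.integer(xml2::xml_attr(o, "index")),
      symmetry = xml2::xml_attr(o, "symmetry"),
      energy = as.numeric(xml2::xml_attr(o, "energy")),
      occupation = as.numeric(xml2::xml_attr(o, "occupation")),
      subspace = xml2::xml_attr(o, "subspace"),
      hidden = identical(xml2::xml_attr(o, "hidden"), "true"),
      grid = if (is.na(g)) NA_integer_ else as.integer(g),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

parse_object_node <- function(node) {
  pts <- matrix(node_nums(node, "./points"), ncol = 3, byrow = TRUE)
  mg <- xml2::xml_attr(node, "magnitude")
  geom_object(kind = xml2::xml_attr(node, "kind"), points = pts,
              rgba = node_nums(node, "./rgba"),
              opacity = as.numeric(xml2::xml_attr(node, "opacity")),
              magnitude = if (is.na(mg)) NULL else as.numeric(mg))
}

#' Write a document
#'
#' @param doc an [mfx_doc()] (a bare molecule is promoted).
#' @param path output path.
#' @export
write_mfx <- function(doc, path) {
  if (inherits(doc, "molecule")) doc <- mfx_doc(doc)
  mol <- doc$molecule
  title <- if (!is.null(mol$metadata$title)) mol$metadata$title else ""
  out <- format_xyz_block(mol$element, mol$xyz, mol$charge, title)
  body <- mfx_xml_lines(doc)
  if (length(body) > 0L)
    out <- c(out, sprintf("<mfx version=\"%s\">", MFX_VERSION), body,
             "</mfx>")
  writeLines(out, path)
  invisible(path)
}

mfx_xml_lines <- function(doc) {
  mol <- doc$molecule
  ln <- character(0)
  md <- mol$metadata
  if (!is.null(md$dipole))
    ln <- c(ln, sprintf("  <dipole unit=\"debye\">%s</dipole>",
                        num10(md$dipole)))
  for (key in setdiff(names(md), c("title", "dipole"))) {
    v <- md[[key]]
    txt <- if (is.numeric(v)) num10(v) else xml_escape(as.character(v)[1])
    ln <- c(ln, sprintf("  <meta key=\"%s\">%s</meta>", xml_escape(key),
                        txt))
  }
  if (!is.null(mol$frames) && length(mol$frames) > 1L) {
    ln <- c(ln, sprintf("  <frames count=\"%d\">", length(mol$frames)))
    for (f in mol$frames[-1])
      ln <- c(ln, sprintf("    <frame>%s</frame>",
                          paste(sprintf("%.6f", t(f)), collapse = " ")))
    ln <- c(ln, "  </frames>")
  }
  for (g in doc$grids) {
    ln <- c(ln,
            sprintf("  <grid label=\"%s\">", xml_escape(g$label)),
            sprintf("    <origin>%s</origin>", num10(g$origin)),
            sprintf("    <axis>%s</axis>", num10(g$axes[1, ])),
            sprintf("    <axis>%s</axis>", num10(g$axes[2, ])),
            sprintf("    <axis>%s</axis>", num10(g$axes[3, ])),
            sprintf("    <shape>%d %d %d</shape>", g$shape[1], g$shape[2],
                    g$shape[3]),
            sprintf("    <values>%s</values>",
                    paste(sprintf("%.10e", g$values), collapse = " ")),
            "  </grid>")
  }
  if (!is.null(doc$orbitals) && nrow(doc$orbitals) > 0L) {
    ln <- c(ln, "  <orbitals>")
    for (i in seq_len(nrow(doc$orbitals))) {
      r <- doc$orbitals[i, ]
      gattr <- if (is.na(r$grid)) "" else sprintf(" grid=\"%d\"", r$grid)
      ln <- c(ln, sprintf(
        paste0("    <orbital index=\"%d\" symmetry=\"%s\" energy=\"%s\"",
               " occupation=\"%s\" subspace=\"%s\" hidden=\"%s\"%s/>"),
        r$index, xml_escape(r$symmetry), sprintf("%.10g", r$energy),
        sprintf("%.10g", r$occupation), r$subspace,
        if (r$hidden) "true" else "false", gattr))
    }
    ln <- c(ln, "  </orbitals>")
  }
  for (ob in doc$objects) {
    mg <- if (is.null(ob$magnitude)) "" else
      sprintf(" magnitude=\"%s\"", sprintf("%.10g", ob$magnitude))
    ln <- c(ln,
            sprintf("  <object kind=\"%s\" opacity=\"%s\"%s>", ob$kind,
                    sprintf("%.10g", ob$opacity), mg),
            sprintf("    <points>%s</points>",
                    paste(sprintf("%.6f", t(ob$points)), collapse = " ")),
            sprintf("    <rgba>%s</rgba>", num10(ob$rgba)),
            "  </object>")
  }
  if (!is.null(doc$view)) {
    ln <- c(ln, "  <view>",
            sprintf("    <orientation>%s</orientation>",
                    num10(t(doc$view$orientation))),
            sprintf("    <scale>%s</scale>",
                    sprintf("%.10g", doc$view$scale)),
            "  </view>")
  }
  if (length(doc$extra) > 0L) ln <- c(ln, paste0("  ", doc$extra))
  ln
}
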