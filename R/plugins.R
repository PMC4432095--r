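# External converter plug-ins.  A plug-in is an external executable that
# converts between a foreign format and the native dialect; the registry
# (a user-editable YAML file) stores format name, command template,
# filename extensions and direction (import / export / compute).
# Commands communicate via files: the {in} and {out} placeholders are
# substituted with real paths before execution.

#' Construct a plug-in spec
#'
#' @param format format name (e.g. `"pdb"`).
#' @param command executable template containing both `{in}` and `{out}`
#'   placeholders.
#' @param extensions character vector of filename suffixes (without dot).
#' @param direction `"import"`, `"export"` or `"compute"`.
#' @return an object of class `"plugin_spec"`.
#' @export
plugin_spec <- function(format, command, extensions,
                        direction = c("import", "export", "compute")) {
  direction <- match.arg(direction)
  if (!grepl("{in}", command, fixed = TRUE) ||
      !grepl("{out}", command, fixed = TRUE))
    stop("command template must contain both {in} and {out}",
         call. = FALSE)
  structure(list(format = format, command = command,
                 extensions = tolower(extensions), direction = direction),
            class = "plugin_spec")
}

#' Load a plug-in registry from a YAML config file
#'
#' The file holds a list of records with fields `format`, `command`,
#' `extensions`, `direction`.  Extensions must be unique across the
#' registry so files can be auto-detected by suffix.
#'
#' @param path YAML file path.
#' @return list of [plugin_spec()]s, class `"plugin_registry"`.
#' @export
load_plugin_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  regs <- lapply(raw, function(r)
    plugin_spec(r$format, r$command, unlist(r$extensions), r$direction))
  exts <- unlist(lapply(regs, `[[`, "extensions"))
  if (anyDuplicated(exts))
    stop("duplicate extensions in plug-in registry: ",
         paste(unique(exts[duplicated(exts)]), collapse = ", "),
         call. = FALSE)
  structure(regs, class = "plugin_registry")
}

NATIVE_EXTENSIONS <- c("xyz", "mfx", "cube")

#' Resolve which plug-in (if any) handles a file
#'
#' An explicitly requested format always wins; otherwise the longest
#' registered suffix matching the filename is chosen.  Native suffixes
#' (.xyz, .mfx, .cube) bypass plug-ins and return `NULL`.
#'
#' @param registry a [load_plugin_registry()] registry (or list of specs).
#' @param path filename whose suffix selects the plug-in.
#' @param explicit_format optional format name overriding detection.
#' @return a [plugin_spec()], or `NULL` for native formats.
#' @export
resolve_plugin <- function(registry, path, explicit_format = NULL) {
  if (!is.null(explicit_format)) {
    if (tolower(explicit_format) %in% NATIVE_EXTENSIONS) return(NULL)
    for (sp in registry) if (sp$format == explicit_format) return(sp)
    stop(sprintf("no plug-in for format '%s'", explicit_format),
         call. = FALSE)
  }
  fname <- tolower(basename(path))
  ext <- tools::file_ext(fname)
  if (ext %in% NATIVE_EXTENSIONS) return(NULL)
  best <- NULL; best_len <- -1L
  for (sp in registry) {
    for (e in sp$extensions) {
      if (endsWith(fname, paste0(".", e)) && nchar(e) > best_len) {
        best <- sp; best_len <- nchar(e)
      }
    }
  }
  if (is.null(best)) {
    known <- unlist(lapply(registry, `[[`, "extensions"))
    stop(sprintf("no plug-in for extension '.%s' (known: %s)", ext,
                 paste(c(NATIVE_EXTENSIONS, known), collapse = ", ")),
         call. = FALSE)
  }
  best
}

#' Run a converter plug-in
#'
#' For `import` and `compute` plug-ins the command is executed with
#' `{in}` = the input path and `{out}` = a temporary file, which is then
#' parsed as a native document and deleted.  For `export` plug-ins the
#' document is first written to a temporary native file ( `{in}` ) and the
#' plug-in produces `out_path`.
#'
#' @param spec a [plugin_spec()].
#' @param input input file path (import/compute) or an [mfx_doc()] /
#'   molecule (export).
#' @param out_path output path (export only).
#' @param timeout seconds before the external command is killed.
#' @return an [mfx_doc()] (import/compute) or `out_path` (export).
#' @export
convert_via_plugin <- function(spec, input, out_path = NULL, timeout = 60) {
  run <- function(cmd) {
    res <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)),
                                    stdout = TRUE, stderr = TRUE,
                                    timeout = timeout))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stop(sprintf("plug-in '%s' failed (exit %d): %s", spec$format,
                   status, paste(res, collapse = "; ")), call. = FALSE)
    invisible(res)
  }
  fill <- function(cmd, inp, outp) {
    cmd <- gsub("{in}", shQuote(inp), cmd, fixed = TRUE)
    gsub("{out}", shQuote(outp), cmd, fixed = TRUE)
  }
  if (spec$direction == "export") {
    if (is.null(out_path)) stop("export needs out_path", call. = FALSE)
    tmp <- tempfile(fileext = ".mfx")
    on.exit(unlink(tmp), add = TRUE)
    write_mfx(input, tmp)
    run(fill(spec$command, tmp, out_path))
    return(invisible(out_path))
  }
  tmp <- tempfile(fileext = ".mfx")
  on.exit(unlink(tmp), add = TRUE)
  run(fill(spec$command, input, tmp))
  if (!file.exists(tmp))
    stop(sprintf("plug-in '%s' produced no output", spec$format),
         call. = FALSE)
  read_mfx(tmp)
}
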