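# Headless edit scripts: one operation per line, so multi-step symmetry
# builds are reproducible without a GUI.
#
# Grammar (one op per line, '#' starts a comment):
#   delete ID...
#   distance I J VALUE            | angle I J K VALUE
#   torsion I J K L VALUE [group side I J [SIDE]]
#   cartesian I X Y Z
#   dummy X Y Z                   | dummy mid ID...
#   rotate I J ANGLE [targets ID...|all] [threshold T]
#   invert I [targets ...] [threshold T]
#   reflect I J K [targets ...] [threshold T]
#   translate I J [MULT] [targets ...] [threshold T]
#   symmetrize (invert I | reflect I J K | rotate I J) [targets ...]
#   attach FRAGMENT_NAME SITE_ID

#' Run an edit script
#'
#' @param mol starting molecule.
#' @param script character vector of script lines, or a file path.
#' @param threshold default merge threshold for symmetry operations,
#'   angstrom.
#' @return the edited molecule.
#' @export
run_edit_script <- function(mol, script, threshold = 0.3) {
  if (length(script) == 1L && file.exists(script))
    script <- readLines(script, warn = FALSE)
  for (ln in seq_along(script)) {
    line <- sub("#.*$", "", script[ln])
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 0L || !nzchar(tok[1])) next
    mol <- tryCatch(
      apply_script_op(mol, tok, threshold),
      error = function(e)
        stop(sprintf("script line %d ('%s'): %s", ln, trimws(line),
                     conditionMessage(e)), call. = FALSE))
  }
  mol
}

apply_script_op <- function(mol, tok, threshold) {
  op <- tok[1]; args <- tok[-1]
  num <- function(i) as.numeric(args[i])
  int <- function(i) as.integer(args[i])
  # optional trailing "targets ..." / "threshold T" clauses
  grab_clauses <- function(args) {
    targets <- "all"; thr <- threshold
    ti <- which(args == "targets")
    if (length(ti) == 1L) {
      stop_at <- which(args == "threshold")
      stop_at <- if (length(stop_at) > 0 && stop_at > ti) stop_at else
        length(args) + 1L
      tv <- args[seq(ti + 1L, stop_at - 1L)]
      targets <- if (identical(tv, "all")) "all" else as.integer(tv)
      args <- args[-seq(ti, stop_at - 1L)]
    }
    hi <- which(args == "threshold")
    if (length(hi) == 1L) {
      thr <- as.numeric(args[hi + 1L])
      args <- args[-c(hi, hi + 1L)]
    }
    list(args = args, targets = targets, threshold = thr)
  }
  switch(op,
    delete = delete_atoms(mol, as.integer(args)),
    distance = set_internal(mol, int(1:2), num(3)),
    angle = set_internal(mol, int(1:3), num(4)),
    torsion = {
      if (length(args) > 5L && args[6] == "group" && args[7] == "side") {
        side <- if (length(args) >= 10L) int(10) else int(8)
        g <- mark_group(mol, "side_of_bond", bond = int(8:9), side = side)
        set_internal(mol, int(1:4), num(5), group = g)
      } else set_internal(mol, int(1:4), num(5))
    },
    cartesian = set_cartesian(mol, int(1), num(2:4)),
    dummy = if (identical(args[1], "mid"))
      add_dummy(mol, midpoint_of = as.integer(args[-1]))
    else add_dummy(mol, position = num(1:3)),
    rotate = {
      cl <- grab_clauses(args)
      so <- make_operation(mol, as.integer(cl$args[1:2]), "rotation",
                           angle = as.numeric(cl$args[3]))
      apply_replicate(mol, so, cl$targets, cl$threshold)
    },
    invert = {
      cl <- grab_clauses(args)
      so <- make_operation(mol, as.integer(cl$args[1]), "inversion")
      apply_replicate(mol, so, cl$targets, cl$threshold)
    },
    reflect = {
      cl <- grab_clauses(args)
      so <- make_operation(mol, as.integer(cl$args[1:3]), "reflection")
      apply_replicate(mol, so, cl$targets, cl$threshold)
    },
    translate = {
      cl <- grab_clauses(args)
      mult <- if (length(cl$args) >= 3L) as.numeric(cl$args[3]) else 1
      so <- make_operation(mol, as.integer(cl$args[1:2]), "translation",
                           multiple = mult)
      apply_replicate(mol, so, cl$targets, cl$threshold)
    },
    symmetrize = {
      cl <- grab_clauses(args[-1])
      so <- switch(args[1],
        invert = make_operation(mol, as.integer(cl$args[1]), "inversion"),
        reflect = make_operation(mol, as.integer(cl$args[1:3]),
                                 "reflection"),
        rotate = make_operation(mol, as.integer(cl$args[1:2]), "rotation",
                                angle = 180),
        stop("symmetrize needs invert/reflect/rotate", call. = FALSE))
      symmetrize(mol, so, cl$targets, cl$threshold)
    },
    attach = attach_fragment(mol, as.integer(args[2]),
                             builtin_fragment(args[1])),
    stop("unknown operation: ", op, call. = FALSE))
}
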