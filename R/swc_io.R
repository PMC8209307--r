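# SWC type codes used throughout: 1 soma, 2 axon, 3 basal dendrite,
# 4 apical dendrite.  Anything else is carried through unchanged and
# treated as dendrite-like ("generic") downstream.
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_BASAL <- 3L
SWC_APICAL <- 4L

#' Construct a morphology object
#'
#' A morphology is an ordered collection of reconstruction nodes forming a
#' single tree rooted at a soma node.  Radii are stored as given in the SWC
#' file; user-facing diameters are always `2 * radius`.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.  Coordinates and radii in micrometres.
#' @param metadata named list of free-form source tags (archive, cell type,
#'   repository id, ...).
#' @param validate logical; run [validate_morphology()] and fail on
#'   structural errors.
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes, metadata = list(), validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes)))
    stop("`nodes` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  nodes <- nodes[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  m <- structure(list(nodes = nodes, metadata = metadata),
                 class = "morphology")
  if (validate) {
    v <- validate_morphology(m)
    if (length(v$errors))
      stop("invalid morphology: ", paste(v$errors, collapse = "; "))
  }
  m
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat("<morphology> ", nrow(nd), " nodes (",
      sum(nd$type == SWC_SOMA), " soma, ",
      sum(dendritic_mask(x)), " dendritic)\n", sep = "")
  md <- Filter(function(v) is.atomic(v) && length(v) == 1, x$metadata)
  if (length(md)) {
    tags <- vapply(md, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  ", paste(names(tags), tags, sep = "=", collapse = " "), "\n",
        sep = "")
  }
  invisible(x)
}

# logical mask over node rows: dendritic = neither soma nor axon
dendritic_mask <- function(m) {
  !(m$nodes$type %in% c(SWC_SOMA, SWC_AXON))
}

# row index of each node's parent (NA for roots), resolved by id
parent_index <- function(m) {
  match(m$nodes$parent, m$nodes$id)
}

#' Node diameters of a morphology
#'
#' @param m a `morphology`.
#' @return Numeric vector, `2 * radius` per node, in file order (micrometres).
#' @export
diameters <- function(m) 2 * m$nodes$radius

#' Validate the structure of a morphology
#'
#' Checks the SWC tree invariants: unique ids, parents that exist, a single
#' root, no cycles, positive radii, and a soma root.  Structural violations
#' are returned as errors; suspicious-but-usable findings (non-positive
#' radii, large z-steps between connected nodes) as warnings.
#'
#' @param m a `morphology`.
#' @return List with character vectors `errors` and `warnings`, plus
#'   `max_z_step`, the largest |z| difference between connected nodes
#'   (reported, never acted on).
#' @export
validate_morphology <- function(m) {
  nd <- m$nodes
  errors <- character(0)
  warnings <- character(0)
  if (nrow(nd) == 0) {
    return(list(errors = "empty node list", warnings = character(0),
                max_z_step = NA_real_))
  }
  if (anyDuplicated(nd$id))
    errors <- c(errors, paste("duplicate node ids:",
                              paste(unique(nd$id[duplicated(nd$id)]),
                                    collapse = ", ")))
  pidx <- match(nd$parent, nd$id)
  dangling <- which(nd$parent != -1L & is.na(pidx))
  if (length(dangling))
    errors <- c(errors, paste0("node ", nd$id[dangling],
                               " references missing parent ",
                               nd$parent[dangling]))
  roots <- which(nd$parent == -1L)
  if (length(roots) == 0)
    errors <- c(errors, "no root node (parent -1)")
  if (length(roots) > 1)
    errors <- c(errors, paste("multiple roots:",
                              paste(nd$id[roots], collapse = ", ")))
  # cycle detection: walk parent links, bounded by node count
  if (!length(errors)) {
    n <- nrow(nd)
    depth <- rep.int(NA_integer_, n)
    depth[roots] <- 0L
    for (pass in seq_len(n)) {
      todo <- which(is.na(depth) & !is.na(pidx) & !is.na(depth[pidx]))
      if (!length(todo)) break
      depth[todo] <- depth[pidx[todo]] + 1L
    }
    stuck <- which(is.na(depth))
    if (length(stuck))
      errors <- c(errors,
                  paste("cycle or disconnected component involving node(s):",
                        paste(nd$id[stuck], collapse = ", ")))
  }
  if (length(roots) == 1 && nd$type[roots] != SWC_SOMA)
    warnings <- c(warnings, "root node is not a soma node")
  bad_r <- which(!(nd$radius > 0))
  if (length(bad_r))
    warnings <- c(warnings, paste0("non-positive radius at node ",
                                   nd$id[bad_r]))
  # soma descendants of dendritic nodes break the soma-rooted layout
  if (!length(errors)) {
    soma_child <- which(nd$type == SWC_SOMA & !is.na(pidx) &
                          nd$type[pidx] != SWC_SOMA)
    if (length(soma_child))
      errors <- c(errors, paste0("soma node ", nd$id[soma_child],
                                 " has a non-soma parent"))
  }
  zstep <- abs(nd$z - nd$z[pidx])
  max_z <- if (all(is.na(zstep))) NA_real_ else max(zstep, na.rm = TRUE)
  list(errors = errors, warnings = warnings, max_z_step = max_z)
}

#' Read an SWC morphology file
#'
#' Accepts the standard 7-column whitespace-delimited SWC format
#' (`id type x y z radius parent`), with `#` comment lines.  Node ids may
#' be unsorted; parents are resolved after the whole file is read.
#'
#' @param path path to an SWC file.
#' @param metadata optional named list of source tags to attach.
#' @return A validated `morphology`.  Non-positive radii are reported as a
#'   warning, not an error.
#' @export
read_swc <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  body <- trimws(lines[keep])
  if (!length(body)) stop("no data lines in SWC file: ", path)
  fields <- strsplit(body, "\\s+")
  nfield <- lengths(fields)
  bad <- which(nfield != 7L)
  if (length(bad))
    stop("malformed SWC line ", lineno[bad[1]], " in ", path,
         ": expected 7 fields, found ", nfield[bad[1]])
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  nonnum <- which(apply(is.na(vals), 1, any))
  if (length(nonnum))
    stop("malformed SWC line ", lineno[nonnum[1]], " in ", path,
         ": non-numeric field")
  nodes <- data.frame(id = as.integer(vals[, 1]),
                      type = as.integer(vals[, 2]),
                      x = vals[, 3], y = vals[, 4], z = vals[, 5],
                      radius = vals[, 6],
                      parent = as.integer(vals[, 7]))
  md <- metadata
  if (is.null(md$source)) md$source <- basename(path)
  m <- morphology(nodes, md, validate = FALSE)
  v <- validate_morphology(m)
  if (length(v$errors))
    stop("structural error in ", path, ": ",
         paste(v$errors, collapse = "; "))
  for (w in v$warnings) warning(path, ": ", w, call. = FALSE)
  m
}

#' Write a morphology to an SWC file
#'
#' @param m a `morphology` with at least one node.
#' @param path output path.
#' @param digits decimal places for coordinates and radii (default 4);
#'   re-reading reproduces all fields exactly at this precision.
#' @param header extra character lines recorded as `#` comments (e.g. the
#'   provenance of predicted diameters and the model set used).
#' @export
write_swc <- function(m, path, digits = 4, header = character(0)) {
  if (!inherits(m, "morphology")) stop("`m` must be a morphology")
  if (nrow(m$nodes) == 0) stop("refusing to write an empty morphology")
  nd <- m$nodes
  fmt <- paste0("%d %d %.", digits, "f %.", digits, "f %.", digits,
                "f %.", digits, "f %d")
  body <- sprintf(fmt, nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius,
                  nd$parent)
  md <- Filter(function(v) is.atomic(v) && length(v) == 1, m$metadata)
  hdr <- c("# SWC written by dendiam",
           if (length(md))
             paste0("# ", names(md), ": ",
                    vapply(md, function(v) paste(format(v), collapse = ","),
                           character(1))),
           paste0("# ", header))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write SWC file ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

# lateral (slant) surface area of the frustum between two nodes, um^2
frustum_area <- function(r1, r2, L) {
  pi * (r1 + r2) * sqrt((r2 - r1)^2 + L^2)
}

# surface area represented by the soma nodes: one node -> sphere;
# several nodes -> slant areas of the frusta along the soma path plus
# spherical caps are ignored (contour somas are approximate anyway)
soma_surface_area <- function(m) {
  nd <- m$nodes
  soma <- which(nd$type == SWC_SOMA)
  if (!length(soma)) stop("morphology has no soma node")
  if (length(soma) == 1) return(4 * pi * nd$radius[soma]^2)
  pidx <- parent_index(m)
  segs <- soma[!is.na(pidx[soma]) & nd$type[pidx[soma]] == SWC_SOMA]
  if (!length(segs)) return(4 * pi * nd$radius[soma[1]]^2)
  p <- pidx[segs]
  L <- sqrt((nd$x[segs] - nd$x[p])^2 + (nd$y[segs] - nd$y[p])^2 +
              (nd$z[segs] - nd$z[p])^2)
  sum(frustum_area(nd$radius[p], nd$radius[segs], L))
}

#' Normalise the soma representation of a morphology
#'
#' Rewrites the soma either as a canonical 3-point soma (a centre node plus
#' two flanking nodes at +/- r along the y axis, the convention used by
#' compartmental simulators) or as a single sphere-equivalent point.  The
#' sphere-equivalent radius is chosen so that the soma surface area
#' (`4 pi r^2`, equal to `pi d^2` for the cylinder the 3-point soma
#' represents) matches the area of the original soma within 1%.  All
#' dendritic (and axonal) processes are re-parented to the centre node.
#'
#' @param m a `morphology` with at least one soma node.
#' @param mode `"three_point"` (default) or `"single_point"`.
#' @return A `morphology`; idempotent when the soma is already in the
#'   requested form.  The dendritic subtree is untouched.
#' @export
normalize_soma <- function(m, mode = c("three_point", "single_point")) {
  mode <- match.arg(mode)
  nd <- m$nodes
  soma <- which(nd$type == SWC_SOMA)
  if (!length(soma)) stop("structural error: morphology has no soma node")
  root <- which(nd$parent == -1L)
  if (!nd$type[root[1]] %in% SWC_SOMA)
    stop("structural error: root node is not a soma node")
  pidx <- parent_index(m)

  already_three <- length(soma) == 3 &&
    sum(soma %in% root) == 1 &&
    all(nd$parent[setdiff(soma, root)] == nd$id[intersect(soma, root)]) &&
    length(unique(round(nd$radius[soma], 9))) == 1
  if (mode == "three_point" && already_three) return(m)
  if (mode == "single_point" && length(soma) == 1) return(m)

  area <- soma_surface_area(m)
  r_eq <- sqrt(area / (4 * pi))
  w <- nd$radius[soma]^2
  cx <- sum(nd$x[soma] * w) / sum(w)
  cy <- sum(nd$y[soma] * w) / sum(w)
  cz <- sum(nd$z[soma] * w) / sum(w)

  keep <- setdiff(seq_len(nrow(nd)), soma)
  out <- nd[keep, , drop = FALSE]
  # re-parent processes that hung off any soma node
  att <- out$parent %in% nd$id[soma]
  cid <- nd$id[root[1]]
  out$parent[att] <- cid
  centre <- data.frame(id = cid, type = SWC_SOMA, x = cx, y = cy, z = cz,
                       radius = r_eq, parent = -1L)
  if (mode == "three_point") {
    nid <- max(nd$id) + 1:2
    flank <- data.frame(id = nid, type = SWC_SOMA,
                        x = cx, y = cy + c(-r_eq, r_eq), z = cz,
                        radius = r_eq, parent = cid)
    out <- rbind(centre, flank, out)
  } else {
    out <- rbind(centre, out)
  }
  morphology(out, m$metadata, validate = TRUE)
}
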