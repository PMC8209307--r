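# Per-node morphometric features and node classification.
#
# Every dendritic node is described by seven features:
#   D  diameter (2 x radius, um)
#   PD parent diameter (soma diameter for initial nodes, um)
#   IB initial branch order: 1 at initial nodes, +1 below each branch point
#   TD terminal degree: number of terminal tips in the node's subtree
#   PS path length from the soma to the node (um)
#   LP longest downstream path from the node to a terminal tip (um)
#   TL total downstream arbor length rooted at the node (um)
# and belongs to exactly one of three classes: initial (parent is soma),
# branching_child (non-soma parent has >= 2 children), continuing (rest).

FEATURE_NAMES <- c("PD", "IB", "TD", "PS", "LP", "TL")

#' Soma-outward traversal order
#'
#' Row indices of all nodes ordered so that every node appears after its
#' parent; deterministic given the input row order (children are visited
#' in file order).
#'
#' @param m a `morphology`.
#' @return Integer vector of row indices into `m$nodes`.
#' @export
traversal_order <- function(m) {
  nd <- m$nodes
  n <- nrow(nd)
  pidx <- parent_index(m)
  kids <- children_index(pidx, n)
  roots <- which(is.na(pidx) | nd$parent == -1L)
  ord <- integer(n)
  ord[seq_along(roots)] <- roots
  filled <- length(roots)
  k <- 1L
  while (k <= filled) {
    ch <- kids[[ord[k]]]
    if (length(ch)) {
      ord[filled + seq_along(ch)] <- ch
      filled <- filled + length(ch)
    }
    k <- k + 1L
  }
  if (filled < n)
    stop("structural error: cycle detected, no parent-first order exists")
  ord
}

# list of child row indices per node, children kept in file order
children_index <- function(pidx, n) {
  has_p <- which(!is.na(pidx))
  kids <- vector("list", n)
  if (length(has_p)) {
    sp <- split(has_p, pidx[has_p])
    kids[as.integer(names(sp))] <- sp
  }
  kids
}

#' Classify dendritic nodes
#'
#' Assigns each dendritic node (SWC types other than soma and axon) to one
#' of three mutually exclusive classes: `initial` nodes stem directly from
#' the soma; `branching_child` nodes have a non-soma parent with two or
#' more children; all remaining nodes are `continuing`.  Soma parentage
#' takes precedence: a soma child is initial regardless of how many
#' siblings it has.  Multifurcations count as branch points.
#'
#' @param m a `morphology`.
#' @return data.frame with columns `id`, `node_class` (factor), and logical
#'   flags `is_terminal` and `is_branch_point`, one row per dendritic node.
#' @export
classify_nodes <- function(m) {
  nd <- m$nodes
  pidx <- parent_index(m)
  dend <- dendritic_mask(m)
  if (any(nd$type == SWC_SOMA & !is.na(pidx) & dend[pidx]))
    stop("structural error: soma node descends from a dendritic node")
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = nrow(nd))
  parent_is_soma <- !is.na(pidx) & nd$type[pidx] == SWC_SOMA
  cls <- ifelse(parent_is_soma, "initial",
                ifelse(nchild[pidx] >= 2, "branching_child", "continuing"))
  out <- data.frame(id = nd$id[dend],
                    node_class = factor(cls[dend],
                                        levels = c("initial",
                                                   "branching_child",
                                                   "continuing")),
                    is_terminal = nchild[dend] == 0,
                    is_branch_point = nchild[dend] >= 2)
  if (anyNA(out$node_class))
    stop("structural error: dendritic node not connected through the soma")
  rownames(out) <- NULL
  out
}

# tree label from SWC type codes: 4 -> apical, 3 -> basal, else generic
tree_label_of <- function(type) {
  ifelse(type == SWC_APICAL, "apical",
         ifelse(type == SWC_BASAL, "basal", "generic"))
}

#' Compute per-node morphometric features
#'
#' Computes D, PD, IB, TD, PS, LP and TL (see the feature glossary in the
#' package vignette) for every dendritic node.  Distances are sums of 3D
#' Euclidean steps between consecutive nodes.  The soma's own extent
#' contributes 0 to PS: the initial segment length is the Euclidean
#' distance from the attached soma point to the initial node.  PD of an
#' initial node is the soma diameter (diameter of the root soma node).
#' LP and TL of terminal nodes are 0.
#'
#' @param m a `morphology` with positive radii.
#' @return data.frame with one row per dendritic node, in file order:
#'   `id`, `tree_label`, `node_class`, `is_terminal`, `is_branch_point`,
#'   `D`, `PD`, `IB`, `TD`, `PS`, `LP`, `TL`.
#' @export
compute_features <- function(m) {
  nd <- m$nodes
  pidx <- parent_index(m)
  dend <- dendritic_mask(m)
  cls <- classify_nodes(m)
  n <- nrow(nd)

  # segment length parent -> node
  seg <- sqrt((nd$x - nd$x[pidx])^2 + (nd$y - nd$y[pidx])^2 +
                (nd$z - nd$z[pidx])^2)
  seg[is.na(seg)] <- 0

  root <- which(nd$parent == -1L)
  soma_d <- 2 * nd$radius[root[1]]

  ord <- traversal_order(m)
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = n)
  parent_is_soma <- !is.na(pidx) & nd$type[pidx] == SWC_SOMA

  PS <- numeric(n); IB <- integer(n)
  for (i in ord) {
    p <- pidx[i]
    if (is.na(p) || nd$type[i] == SWC_SOMA) { PS[i] <- 0; IB[i] <- 0L; next }
    if (parent_is_soma[i]) {
      PS[i] <- seg[i]
      IB[i] <- 1L
    } else {
      PS[i] <- PS[p] + seg[i]
      IB[i] <- IB[p] + if (nchild[p] >= 2) 1L else 0L
    }
  }

  kids <- children_index(pidx, n)
  TD <- integer(n); LP <- numeric(n); TL <- numeric(n)
  for (i in rev(ord)) {
    ch <- kids[[i]]
    if (!length(ch)) { TD[i] <- 1L; LP[i] <- 0; TL[i] <- 0; next }
    TD[i] <- sum(TD[ch])
    LP[i] <- max(seg[ch] + LP[ch])
    TL[i] <- sum(seg[ch] + TL[ch])
  }

  PD <- 2 * nd$radius[pidx]
  PD[parent_is_soma] <- soma_d

  out <- data.frame(id = nd$id[dend],
                    tree_label = tree_label_of(nd$type[dend]),
                    D = 2 * nd$radius[dend],
                    PD = PD[dend],
                    IB = IB[dend],
                    TD = TD[dend],
                    PS = PS[dend],
                    LP = LP[dend],
                    TL = TL[dend])
  out <- merge(cls, out, by = "id", sort = FALSE)
  out <- out[match(nd$id[dend], out$id), ]
  rownames(out) <- NULL
  out
}

#' Total dendritic length of a morphology
#'
#' Sum of all dendritic segment lengths (micrometres), including the
#' soma-to-initial-node segments.
#'
#' @param m a `morphology`.
#' @return A length-one numeric.
#' @export
total_dendritic_length <- function(m) {
  nd <- m$nodes
  pidx <- parent_index(m)
  dend <- dendritic_mask(m)
  seg <- sqrt((nd$x - nd$x[pidx])^2 + (nd$y - nd$y[pidx])^2 +
                (nd$z - nd$z[pidx])^2)
  sum(seg[dend], na.rm = TRUE)
}

#' Assemble a per-node feature table for a collection of morphologies
#'
#' @param ms a list of `morphology` objects (or a single one).
#' @return data.frame: one row per dendritic node with `morph` (the
#'   morphology's `source`/`name` tag or list index), `archive` tag if
#'   present, then the [compute_features()] columns.  This flat table is
#'   the input to the regression module.
#' @export
feature_table <- function(ms) {
  if (inherits(ms, "morphology")) ms <- list(ms)
  rows <- lapply(seq_along(ms), function(i) {
    m <- ms[[i]]
    ft <- compute_features(m)
    nm <- m$metadata$name
    if (is.null(nm)) nm <- m$metadata$source
    if (is.null(nm)) nm <- paste0("morph", i)
    arch <- m$metadata$archive
    if (is.null(arch)) arch <- NA_character_
    cbind(data.frame(morph = nm, archive = arch,
                     stringsAsFactors = FALSE), ft)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as tab-separated values
#'
#' Column order is fixed and documented: morph, archive, id, node_class,
#' is_terminal, is_branch_point, tree_label, D, PD, IB, TD, PS, LP, TL.
#'
#' @param tbl a feature table from [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(tbl, path) {
  cols <- c("morph", "archive", "id", "node_class", "is_terminal",
            "is_branch_point", "tree_label", "D", "PD", "IB", "TD",
            "PS", "LP", "TL")
  utils::write.table(tbl[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
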