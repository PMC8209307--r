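# Soma-outward diameter prediction: apply a model_set to a morphology,
# chaining the predicted parent diameter instead of the original one, plus
# the uniform-diameter control variant.  Model sets serialize to a
# human-readable key/value text format; the published equation sets for
# hippocampal pyramidal, cerebellar Purkinje and striatal spiny projection
# neurons ship with the package as such files.

#' Prediction options
#'
#' @param keep_original_initial keep the reconstruction's own diameter at
#'   initial nodes and only predict branching children and continuing
#'   nodes (recommended when initial diameters are trusted).
#' @param min_diameter floor (um) applied to every predicted diameter;
#'   some initial-node equations can go non-positive for short proximal
#'   paths, and a positive floor keeps the result simulable.
#' @param uniform_diameter if set, skip the models entirely and assign
#'   this diameter (um) to every dendritic node - the standard corrective
#'   control for archives submitted without diameters.
#' @return List of class `prediction_options`.
#' @export
prediction_options <- function(keep_original_initial = FALSE,
                               min_diameter = 0.05,
                               uniform_diameter = NULL) {
  stopifnot(min_diameter > 0)
  structure(list(keep_original_initial = keep_original_initial,
                 min_diameter = min_diameter,
                 uniform_diameter = uniform_diameter),
            class = "prediction_options")
}

# find the model for a (tree_label, node_class); falls back to the
# generic, then basal, model with a warning for unexpected labels
lookup_model <- function(models, tree_label, node_class, warned_env) {
  key <- paste(tree_label, node_class, sep = "/")
  if (!is.null(models$models[[key]])) return(models$models[[key]])
  # a generic model is meant for every tree label: silent fallback;
  # borrowing the basal model for an unexpected label is warned about
  for (fb in c("generic", "basal")) {
    k2 <- paste(fb, node_class, sep = "/")
    if (!is.null(models$models[[k2]])) {
      if (fb != "generic" && !isTRUE(warned_env[[key]])) {
        warned_env[[key]] <- TRUE
        warning("no ", tree_label, " model for ", node_class,
                " nodes; falling back to the ", fb, " model",
                call. = FALSE)
      }
      return(models$models[[k2]])
    }
  }
  stop("configuration error: model set '", models$cell_type,
       "' has no model for ", key, " and no generic fallback")
}

#' Predict diameters of a morphology by soma-outward traversal
#'
#' Starting at the initial nodes, each node's diameter is predicted from
#' its class-specific linear model.  Geometry-only features (IB, TD, PS,
#' LP, TL) are computed once from the original morphology - they do not
#' depend on diameter - while the parent-diameter feature PD chains: the
#' initial node sees the soma diameter, and every node further out sees
#' its parent's *predicted* diameter in place of the original one.
#'
#' @param m a `morphology` (soma representation is used as-is; PD of
#'   initial nodes is the root soma node's diameter).
#' @param models a `model_set` covering the classes and tree labels
#'   present.
#' @param opts a [prediction_options()] object.
#' @return A new `morphology`: topology, coordinates and type codes
#'   identical to the input, only the radius column changed (soma and
#'   axon nodes untouched).
#' @export
predict_diameters <- function(m, models, opts = prediction_options()) {
  nd <- m$nodes
  dend <- dendritic_mask(m)
  out <- nd
  if (!is.null(opts$uniform_diameter)) {
    out$radius[dend] <- opts$uniform_diameter / 2
    return(morphology(out, c(m$metadata, list(diameters = "uniform")),
                      validate = FALSE))
  }
  if (!inherits(models, "model_set"))
    stop("configuration error: `models` must be a model_set")
  ft <- compute_features(m)
  frow <- match(nd$id, ft$id)          # NA for soma/axon rows
  cls_v <- as.character(ft$node_class)[frow]
  lab_v <- ft$tree_label[frow]
  fPD <- ft$PD[frow]; fIB <- ft$IB[frow]; fTD <- ft$TD[frow]
  fPS <- ft$PS[frow]; fLP <- ft$LP[frow]; fTL <- ft$TL[frow]
  pidx <- parent_index(m)
  ord <- traversal_order(m)
  pred_d <- 2 * nd$radius              # updated in traversal order
  warned <- new.env()
  for (i in ord) {
    if (!dend[i]) next
    cls <- cls_v[i]
    if (cls == "initial" && opts$keep_original_initial) next
    model <- lookup_model(models, lab_v[i], cls, warned)
    feats <- c(PD = if (cls == "initial") fPD[i] else pred_d[pidx[i]],
               IB = fIB[i], TD = fTD[i], PS = fPS[i], LP = fLP[i],
               TL = fTL[i])
    dhat <- evaluate_model(model, feats)
    if (!is.finite(dhat))
      stop("numerical error: non-finite prediction at node ", nd$id[i])
    pred_d[i] <- max(dhat, opts$min_diameter)
  }
  out$radius <- pred_d / 2
  out$radius[!dend] <- nd$radius[!dend]
  morphology(out, c(m$metadata,
                    list(diameters = paste0("predicted:",
                                            models$cell_type))),
             validate = FALSE)
}

#' Write a model set to a human-readable text file
#'
#' The format is line-oriented key/value text: header keys (`cell_type`,
#' `train`, `seed`, `improvement`), then one `[model]` block per equation
#' with `tree_label`, `node_class`, `features` (space separated),
#' `coefficients` (space separated, same order), `adj_r2`, `n_train` and
#' an optional `note`.
#'
#' @param ms a `model_set`.
#' @param path output path.
#' @export
write_model_set <- function(ms, path) {
  lines <- c("# dendiam model set",
             paste0("cell_type: ", ms$cell_type))
  if (!is.null(ms$provenance)) {
    if (!is.null(ms$provenance$train))
      lines <- c(lines, paste0("train: ",
                               paste(ms$provenance$train, collapse = " ")))
    if (!is.na(ms$provenance$seed %||% NA))
      lines <- c(lines, paste0("seed: ", ms$provenance$seed))
    if (!is.null(ms$provenance$improvement))
      lines <- c(lines, paste0("improvement: ", ms$provenance$improvement))
  }
  for (m in ms$models) {
    lines <- c(lines, "[model]",
               paste0("tree_label: ", m$tree_label),
               paste0("node_class: ", m$node_class),
               paste0("features: ", paste(m$features, collapse = " ")),
               paste0("coefficients: ",
                      paste(format(m$coefficients, digits = 15),
                            collapse = " ")),
               paste0("adj_r2: ", format(m$adj_r2, digits = 15)),
               paste0("n_train: ", m$n_train),
               if (!is.null(m$note)) paste0("note: ", m$note))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model set from its text serialization
#'
#' @param path path to a file written by [write_model_set()] (or a
#'   packaged model file, see [packaged_model_set()]).
#' @return A `model_set`.
#' @export
read_model_set <- function(path) {
  if (!file.exists(path)) stop("model set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  blocks <- split(lines, cumsum(lines == "[model]"))
  hdr <- blocks[["0"]] %||% character(0)
  kv <- function(ls) {
    mt <- regmatches(ls, regexec("^([a-z_0-9]+):\\s*(.*)$", ls))
    vals <- lapply(mt, function(x) if (length(x) == 3) x[3] else NULL)
    names(vals) <- vapply(mt, function(x)
      if (length(x) == 3) x[2] else NA_character_, character(1))
    vals[!is.na(names(vals))]
  }
  h <- kv(hdr)
  models <- list()
  for (b in blocks[names(blocks) != "0"]) {
    f <- kv(b[-1])
    feats <- strsplit(trimws(f$features), "\\s+")[[1]]
    coefs <- as.numeric(strsplit(trimws(f$coefficients), "\\s+")[[1]])
    dm <- diameter_model(f$node_class, f$tree_label, feats, coefs,
                         as.numeric(f$adj_r2 %||% NA),
                         suppressWarnings(as.integer(f$n_train %||% NA)),
                         note = f$note)
    models[[paste(dm$tree_label, dm$node_class, sep = "/")]] <- dm
  }
  prov <- list(train = if (!is.null(h$train))
    strsplit(h$train, "\\s+")[[1]] else NULL,
    seed = suppressWarnings(as.integer(h$seed %||% NA)),
    improvement = as.numeric(h$improvement %||% NA))
  structure(list(cell_type = h$cell_type %||% "unspecified",
                 models = models, provenance = prov),
            class = "model_set")
}

#' List the packaged predictive model sets
#'
#' @return Character vector of preset names accepted by
#'   [packaged_model_set()].
#' @export
list_packaged_models <- function() {
  files <- list.files(system.file("extdata", "models", package = "dendiam"),
                      pattern = "\\.txt$")
  sub("\\.txt$", "", files)
}

#' Load a packaged predictive model set by name
#'
#' The package ships the published node-class-specific diameter equations
#' for hippocampal pyramidal cells (apical and basal dendrites),
#' cerebellar Purkinje cells, and striatal spiny projection neurons
#' (pooled, plus the two single-archive variants), each annotated with
#' its training adjusted R^2.
#'
#' The cerebellar branching-children equation is shipped verbatim from its
#' source; its TL coefficient (0.6842 um per um of arbor length) produces
#' implausibly large diameters on arbors of realistic size, so applying it
#' emits a prominent warning.  Refit that model from your own data if the
#' cerebellar branch-children predictions matter.
#'
#' @param name one of [list_packaged_models()], e.g.
#'   `"table4-hippocampal"`, `"table4-cerebellar"`, `"table4-striatal"`,
#'   `"table4-striatal-lai"`, `"table4-striatal-luebke"`.
#' @return A `model_set`.
#' @export
packaged_model_set <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".txt"),
                      package = "dendiam")
  if (!nzchar(path))
    stop("unknown packaged model set '", name, "'; available: ",
         paste(list_packaged_models(), collapse = ", "))
  ms <- read_model_set(path)
  for (m in ms$models)
    if (!is.null(m$note)) warning(ms$cell_type, " ", m$node_class,
                                  " model: ", m$note, call. = FALSE)
  ms
}
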