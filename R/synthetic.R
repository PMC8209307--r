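# Synthetic dendritic morphologies with controlled topology and
# ground-truth diameter rules, so the feature extraction, regression,
# prediction and simulation stages are all testable without any external
# reconstruction archive.

#' Specification for a synthetic morphology
#'
#' Topology is grown stochastically from a 3-point soma: `n_initial`
#' stems, each node branching into two children with probability
#' `branch_prob` (otherwise continuing with one child) until `max_depth`
#' nodes from the soma.  Segment lengths are Gaussian; growth directions
#' drift with a small angular jitter whose z component is kept small so
#' path lengths are genuinely 3D without extreme z-steps.  Diameters are
#' then assigned soma-outward by `diameter_rule` exactly as the predictor
#' chains them - the predicted (noisy) parent diameter feeds the child's
#' PD - plus truncated Gaussian noise floored at `min_diameter`.
#'
#' @param n_initial number of dendritic stems leaving the soma.
#' @param branch_prob per-node bifurcation probability, in \[0, 1\].
#' @param segment_length `c(mean, sd)` of inter-node distances, um.
#' @param max_depth maximum node depth below the soma.
#' @param soma_diameter `c(mean, sd)` soma diameter, um (sd may be 0).
#' @param diameter_rule a `model_set`, or a function
#'   `f(node_class, features)` returning a diameter in um.
#' @param noise_sd Gaussian diameter noise, um.
#' @param min_diameter floor applied after noise, um.
#' @param chain_noise if `TRUE` (default) a child's PD is the parent's
#'   noisy stored diameter, mimicking how reconstruction noise propagates;
#'   `FALSE` chains the noise-free rule value (for exact-recovery tests).
#' @param tree_type SWC type code given to dendritic nodes (3 basal,
#'   4 apical).
#' @param seed integer seed (mandatory; every draw is reproducible).
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_initial = 4, branch_prob = 0.22,
                       segment_length = c(8, 2), max_depth = 18,
                       soma_diameter = c(10, 1),
                       diameter_rule = NULL,
                       noise_sd = 0.05, min_diameter = 0.05,
                       chain_noise = TRUE, tree_type = SWC_BASAL,
                       seed) {
  if (missing(seed)) stop("synth_spec requires an explicit seed")
  stopifnot(branch_prob >= 0, branch_prob <= 1, n_initial >= 1,
            max_depth >= 1, min_diameter > 0)
  if (length(soma_diameter) == 1) soma_diameter <- c(soma_diameter, 0)
  if (is.null(diameter_rule))
    diameter_rule <- suppressWarnings(packaged_model_set("table4-striatal"))
  structure(list(n_initial = n_initial, branch_prob = branch_prob,
                 segment_length = segment_length, max_depth = max_depth,
                 soma_diameter = soma_diameter,
                 diameter_rule = diameter_rule, noise_sd = noise_sd,
                 min_diameter = min_diameter, chain_noise = chain_noise,
                 tree_type = as.integer(tree_type),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# evaluate the ground-truth rule for one node
rule_diameter <- function(rule, node_class, tree_label, feats, warned) {
  if (is.function(rule)) return(rule(node_class, feats))
  model <- lookup_model(rule, tree_label, node_class, warned)
  evaluate_model(model, feats)
}

#' Generate one synthetic morphology
#'
#' @param spec a [synth_spec()].
#' @param name morphology name recorded in the metadata.
#' @return A validated `morphology` carrying `metadata$truth` with the
#'   rule's noise-free diameters, the planted PD-equality count, and the
#'   spec seed.
#' @export
generate_morphology <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  rs <- max(stats::rnorm(1, spec$soma_diameter[1],
                         spec$soma_diameter[2]), 2) / 2
  cap <- 256L
  id <- integer(cap); type <- integer(cap)
  x <- numeric(cap); y <- numeric(cap); z <- numeric(cap)
  parent <- integer(cap); depth <- integer(cap)
  grow <- function(n_extra) {
    while (n + n_extra > cap) {
      cap <<- cap * 2L
      length(id) <<- cap; length(type) <<- cap
      length(x) <<- cap; length(y) <<- cap; length(z) <<- cap
      length(parent) <<- cap; length(depth) <<- cap
    }
  }
  # 3-point soma
  n <- 3L
  id[1:3] <- 1:3; type[1:3] <- SWC_SOMA
  x[1:3] <- 0; y[1:3] <- c(0, -rs, rs); z[1:3] <- 0
  parent[1:3] <- c(-1L, 1L, 1L); depth[1:3] <- 0L

  slen <- function() max(stats::rnorm(1, spec$segment_length[1],
                                      spec$segment_length[2]), 0.5)
  # queue of rows still to be extended, with their growth direction
  qrow <- integer(0); qdir <- list()
  for (k in seq_len(spec$n_initial)) {
    th <- 2 * pi * (k - 1) / spec$n_initial + stats::runif(1, -0.2, 0.2)
    dir <- c(cos(th), sin(th), stats::rnorm(1, 0, 0.05))
    dir <- dir / sqrt(sum(dir^2))
    L <- slen()
    grow(1L); n <- n + 1L
    id[n] <- n; type[n] <- spec$tree_type
    x[n] <- x[1] + dir[1] * L; y[n] <- y[1] + dir[2] * L
    z[n] <- z[1] + dir[3] * L
    parent[n] <- 1L; depth[n] <- 1L
    qrow <- c(qrow, n); qdir <- c(qdir, list(dir))
  }
  qi <- 1L
  while (qi <= length(qrow)) {
    pr <- qrow[qi]; pdir <- qdir[[qi]]; qi <- qi + 1L
    if (depth[pr] >= spec$max_depth) next
    nchild <- if (stats::runif(1) < spec$branch_prob) 2L else 1L
    for (cidx in seq_len(nchild)) {
      jit <- stats::rnorm(3, 0, c(0.25, 0.25, 0.06))
      if (nchild == 2) jit[1:2] <- jit[1:2] +
          c(-0.5, 0.5)[cidx] * rev(abs(pdir[1:2]))
      dir <- pdir + jit
      dir <- dir / sqrt(sum(dir^2))
      L <- slen()
      grow(1L); n <- n + 1L
      id[n] <- n; type[n] <- spec$tree_type
      x[n] <- x[pr] + dir[1] * L; y[n] <- y[pr] + dir[2] * L
      z[n] <- z[pr] + dir[3] * L
      parent[n] <- pr; depth[n] <- depth[pr] + 1L
      qrow <- c(qrow, n); qdir <- c(qdir, list(dir))
    }
  }
  nodes <- data.frame(id = id[1:n], type = type[1:n], x = x[1:n],
                      y = y[1:n], z = z[1:n],
                      radius = c(rs, rs, rs, rep(0.5, n - 3)),
                      parent = parent[1:n])
  m <- morphology(nodes, list(name = name, archive = "synthetic",
                              seed = spec$seed), validate = FALSE)

  # assign diameters soma-outward with PD chaining
  ft <- compute_features(m)
  frow <- match(m$nodes$id, ft$id)
  cls_v <- as.character(ft$node_class)[frow]
  lab_v <- ft$tree_label[frow]
  fIB <- ft$IB[frow]; fTD <- ft$TD[frow]; fPS <- ft$PS[frow]
  fLP <- ft$LP[frow]; fTL <- ft$TL[frow]
  pidx <- parent_index(m)
  ord <- traversal_order(m)
  dend <- dendritic_mask(m)
  warned <- new.env()
  d_store <- 2 * m$nodes$radius      # stored (noisy) diameters
  d_chain <- d_store                 # diameters fed to children as PD
  d_clean <- rep(NA_real_, n)
  n_nonpos <- 0L
  for (i in ord) {
    if (!dend[i]) next
    cls <- cls_v[i]
    feats <- c(PD = if (cls == "initial") 2 * rs else d_chain[pidx[i]],
               IB = fIB[i], TD = fTD[i], PS = fPS[i], LP = fLP[i],
               TL = fTL[i])
    dc <- rule_diameter(spec$diameter_rule, cls, lab_v[i], feats,
                        warned)
    if (dc <= 0) n_nonpos <- n_nonpos + 1L
    d_clean[i] <- dc
    noisy <- dc + if (spec$noise_sd > 0)
      stats::rnorm(1, 0, spec$noise_sd) else 0
    d_store[i] <- max(noisy, spec$min_diameter)
    d_chain[i] <- if (spec$chain_noise) d_store[i]
      else max(dc, spec$min_diameter)
  }
  n_dend <- sum(dend)
  if (n_nonpos > 0.5 * n_dend)
    stop("spec error: diameter rule non-positive on ",
         n_nonpos, "/", n_dend, " nodes before flooring")
  out <- m$nodes
  out$radius <- d_store / 2
  morphology(out, c(m$metadata,
                    list(truth = list(clean_diameters = d_clean,
                                      noise_sd = spec$noise_sd,
                                      chain_noise = spec$chain_noise))),
             validate = TRUE)
}

#' Generate an archive of independent synthetic morphologies
#'
#' Per-cell sub-seeds are drawn deterministically from the master seed, so
#' the archive is reproducible as a whole and each cell individually.
#'
#' @param spec a [synth_spec()] (its `seed` is the master seed).
#' @param n_cells number of morphologies (>= 2).
#' @return List of `morphology` objects named `synth1..synthN`.
#' @export
generate_archive <- function(spec, n_cells) {
  stopifnot(n_cells >= 2)
  set.seed(spec$seed)
  subs <- sample.int(.Machine$integer.max - 1L, n_cells)
  out <- lapply(seq_len(n_cells), function(i) {
    s <- spec
    s$seed <- subs[i]
    generate_morphology(s, name = paste0("synth", i))
  })
  names(out) <- paste0("synth", seq_len(n_cells))
  out
}
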