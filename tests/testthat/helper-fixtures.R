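# Fixtures are built in code: tiny hand-checkable morphologies, a chain
# builder, and brute-force oracles that recompute subtree features by
# exhaustive enumeration (independent of the package's recursions).

# soma(0,0,0) -> a(10,0,0) -> b(20,0,0) -> {c(20,5,0), d(20,-5,0)}
# Hand arithmetic: PS(a)=10 PS(b)=20 PS(c)=PS(d)=25; LP(a)=15 LP(b)=5
# LP(c)=0; TL(a)=20 TL(b)=10 TL(c)=0; TD(a)=TD(b)=2 TD(c)=1;
# IB(a)=IB(b)=1 IB(c)=IB(d)=2.
five_node_fixture <- function(type = 3, soma_radius = 2,
                              dend_radius = 0.5) {
  morphology(data.frame(
    id = 1:5,
    type = c(1, type, type, type, type),
    x = c(0, 10, 20, 20, 20),
    y = c(0, 0, 0, 5, -5),
    z = 0,
    radius = c(soma_radius, rep(dend_radius, 4)),
    parent = c(-1, 1, 2, 3, 3)))
}

# soma + single unbranched dendritic chain with the given diameters,
# nodes spaced `step` um apart along x
chain_morphology <- function(diams, step = 10, type = 3,
                             soma_radius = 5) {
  n <- length(diams)
  morphology(data.frame(
    id = seq_len(n + 1),
    type = c(1, rep(type, n)),
    x = seq(0, by = step, length.out = n + 1),
    y = 0, z = 0,
    radius = c(soma_radius, diams / 2),
    parent = c(-1, seq_len(n))))
}

write_swc_text <- function(lines, path = tempfile(fileext = ".swc")) {
  writeLines(lines, path)
  path
}

# --- brute-force oracle: exhaustive subtree walks, no shared recursion ---
bf_features <- function(m) {
  nd <- m$nodes
  pid <- match(nd$parent, nd$id)
  seg <- sqrt((nd$x - nd$x[pid])^2 + (nd$y - nd$y[pid])^2 +
                (nd$z - nd$z[pid])^2)
  kids <- function(i) which(pid == i & !is.na(pid))
  td <- function(i) {
    ch <- kids(i)
    if (!length(ch)) 1L else sum(vapply(ch, td, integer(1)))
  }
  lp <- function(i) {
    ch <- kids(i)
    if (!length(ch)) 0
    else max(vapply(ch, function(c) seg[c] + lp(c), numeric(1)))
  }
  tl <- function(i) {
    ch <- kids(i)
    if (!length(ch)) 0
    else sum(vapply(ch, function(c) seg[c] + tl(c), numeric(1)))
  }
  ps <- function(i) {
    p <- pid[i]
    if (nd$type[p] == 1) seg[i] else seg[i] + ps(p)
  }
  dend <- which(!(nd$type %in% c(1, 2)))
  data.frame(id = nd$id[dend],
             TD = vapply(dend, td, integer(1)),
             LP = vapply(dend, lp, numeric(1)),
             TL = vapply(dend, tl, numeric(1)),
             PS = vapply(dend, ps, numeric(1)))
}

striatal_set <- function() suppressWarnings(
  packaged_model_set("table4-striatal"))
hippocampal_set <- function() suppressWarnings(
  packaged_model_set("table4-hippocampal"))
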