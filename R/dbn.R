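#' @keywords internal
NODE_FAMILIES <- c("discrete", "multinomial", "poisson",
                   "gaussian_uni", "gaussian_multi",
                   "vonmises_uni", "vonmises_bi", "kent")

## Number of stored components per slice for a node value.
value_width <- function(family, size) {
  switch(family,
         discrete = 1L, poisson = 1L,
         gaussian_uni = 1L, vonmises_uni = 1L,
         gaussian_multi = as.integer(size),
         multinomial = as.integer(size),
         vonmises_bi = 2L,
         kent = 3L,
         stop("unknown family: ", family))
}

#' Declare one node of a DBN slice
#'
#' @param name identifier, unique within the slice.
#' @param family one of `"discrete"`, `"multinomial"`, `"poisson"`,
#'   `"gaussian_uni"`, `"gaussian_multi"`, `"vonmises_uni"`,
#'   `"vonmises_bi"`, `"kent"`.
#' @param size state count (discrete), vector length (`gaussian_multi`,
#'   `multinomial`); fixed at 2 for `vonmises_bi` (an angle pair) and 3 for
#'   `kent` (a 3D unit vector); 1 for the remaining scalar families.
#' @param hidden may entries of this node be hidden?  Only discrete nodes
#'   can be hidden: the Gibbs conditional is then a finite enumeration.
#' @return a `node_spec` list.
#' @export
node_spec <- function(name, family, size = 1L, hidden = FALSE) {
  family <- match.arg(family, NODE_FAMILIES)
  size <- as.integer(size)
  if (is.na(size) || size < 1L) stop("size must be >= 1")
  if (family == "kent" && size != 3L) stop("kent nodes have size 3")
  if (family == "vonmises_bi" && size != 2L) stop("vonmises_bi nodes have size 2")
  if (family %in% c("poisson", "gaussian_uni", "vonmises_uni") && size != 1L)
    stop(family, " nodes have size 1")
  if (family == "multinomial" && size < 2L)
    stop("multinomial nodes need size >= 2 categories")
  if (hidden && family != "discrete")
    stop("only discrete nodes may be hidden")
  structure(list(name = as.character(name), family = family, size = size,
                 hidden = isTRUE(hidden), width = value_width(family, size)),
            class = "node_spec")
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L)
    return(matrix(integer(), ncol = 2L))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- matrix(as.integer(edges), ncol = 2L)
  edges
}

#' Specify a dynamic Bayesian network
#'
#' A DBN is a slice of nodes replicated along the sequence: `intra_edges`
#' connect nodes within a slice, `inter_edges` connect a parent in slice
#' `t` to a child in slice `t + 1`.  Parameters are tied across slices; a
#' node with inter-slice parents additionally owns an initial-slice
#' parameter set conditioned only on its intra-slice parents.
#'
#' Node order must be a topological order of the intra-slice edges (parents
#' precede children); every parent must be a discrete node, whose state
#' selects the child's parameter component.
#'
#' @param nodes list of [node_spec()]s (one slice).
#' @param intra_edges,inter_edges two-column matrices (or lists of pairs) of
#'   1-based `(parent, child)` node indices.
#' @return an object of class `dbn_spec`.
#' @examples
#' hmm <- dbn_spec(
#'   list(node_spec("h", "discrete", 5, hidden = TRUE),
#'        node_spec("o", "discrete", 5)),
#'   intra_edges = rbind(c(1, 2)),
#'   inter_edges = rbind(c(1, 1)))
#' @export
dbn_spec <- function(nodes, intra_edges = NULL, inter_edges = NULL) {
  if (!length(nodes)) stop("need at least one node")
  if (!all(vapply(nodes, inherits, TRUE, "node_spec")))
    stop("nodes must be node_spec objects")
  nm <- vapply(nodes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("node names must be unique")
  n <- length(nodes)
  intra <- as_edge_matrix(intra_edges)
  inter <- as_edge_matrix(inter_edges)
  for (e in list(intra, inter)) {
    if (nrow(e) && (anyNA(e) || any(e < 1L) || any(e > n)))
      stop("edge endpoint out of range")
  }
  if (nrow(intra) && any(intra[, 1L] >= intra[, 2L]))
    stop("intra edges must respect node order (parent index < child index); ",
         "reorder the slice topologically")
  all_edges <- rbind(if (nrow(intra)) cbind(intra, 0L),
                     if (nrow(inter)) cbind(inter, 1L))
  if (!is.null(all_edges) && anyDuplicated(all_edges))
    stop("duplicate edges")
  fam <- vapply(nodes, `[[`, "", "family")
  parents_all <- c(intra[, 1L], inter[, 1L])
  if (length(parents_all) && any(fam[parents_all] != "discrete"))
    stop("every parent must be a discrete node (parent states index the ",
         "child's parameter components)")

  spec <- structure(list(nodes = nodes, intra_edges = intra,
                         inter_edges = inter), class = "dbn_spec")
  spec$meta <- build_meta(spec)
  spec
}

## Per-node wiring tables used throughout inference and learning.
## Parent order convention: intra parents (increasing node index), then
## inter parents (increasing node index).
build_meta <- function(spec) {
  n <- length(spec$nodes)
  sizes <- vapply(spec$nodes, `[[`, 1L, "size")
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    intra_pa <- sort(spec$intra_edges[spec$intra_edges[, 2L] == i, 1L])
    inter_pa <- sort(spec$inter_edges[spec$inter_edges[, 2L] == i, 1L])
    intra_ch <- sort(spec$intra_edges[spec$intra_edges[, 1L] == i, 2L])
    inter_ch <- sort(spec$inter_edges[spec$inter_edges[, 1L] == i, 2L])
    meta[[i]] <- list(
      intra_parents = intra_pa, inter_parents = inter_pa,
      intra_children = intra_ch, inter_children = inter_ch,
      psz = sizes[c(intra_pa, inter_pa)],       # full parent sizes
      psz0 = sizes[intra_pa],                   # initial-slice parent sizes
      has_init = length(inter_pa) > 0L)
  }
  meta
}

n_nodes <- function(spec) length(spec$nodes)

node_sizes <- function(spec) vapply(spec$nodes, `[[`, 1L, "size")

node_families <- function(spec) vapply(spec$nodes, `[[`, "", "family")

node_names <- function(spec) vapply(spec$nodes, `[[`, "", "name")

#' @export
print.dbn_spec <- function(x, ...) {
  cat("<dbn_spec> ", length(x$nodes), " nodes/slice, ",
      nrow(x$intra_edges), " intra, ", nrow(x$inter_edges), " inter edges\n",
      sep = "")
  for (nd in x$nodes)
    cat("  ", nd$name, " (", nd$family, ", size ", nd$size,
        if (nd$hidden) ", hidden" else "", ")\n", sep = "")
  invisible(x)
}

## Parent sites of node i in slice t (1-based slices), honouring the
## initial-slice convention: slice-1 nodes drop their inter parents and use
## the initial parameter set instead.
parent_sites <- function(spec, t, i) {
  m <- spec$meta[[i]]
  if (t == 1L) {
    if (length(m$intra_parents))
      cbind(slice = rep(1L, length(m$intra_parents)), node = m$intra_parents)
    else cbind(slice = integer(), node = integer())
  } else {
    rbind(
      if (length(m$intra_parents))
        cbind(slice = rep(t, length(m$intra_parents)), node = m$intra_parents),
      if (length(m$inter_parents))
        cbind(slice = rep(t - 1L, length(m$inter_parents)), node = m$inter_parents),
      cbind(slice = integer(), node = integer()))
  }
}

#' Unroll a DBN over a number of slices
#'
#' Instantiates the slice template along the sequence: for every
#' `(slice, node)` the list of `(slice, node)` parents — intra parents in
#' the same slice, inter parents in the previous one.  Slice-1 nodes with
#' inter parents are flagged `initial = TRUE`: they use the node's
#' unconditional-on-inter-parents initial parameter set.  Parameters are
#' tied across slices per node.
#'
#' @param spec a [dbn_spec()].
#' @param n_slices number of slices (>= 1).
#' @return list with one element per slice; each a list over nodes of
#'   `list(parents = <matrix slice,node>, initial = <flag>)`.
#' @export
unroll <- function(spec, n_slices) {
  n_slices <- as.integer(n_slices)
  if (is.na(n_slices) || n_slices < 1L) stop("n_slices must be >= 1")
  lapply(seq_len(n_slices), function(t) {
    lapply(seq_len(n_nodes(spec)), function(i) {
      list(parents = parent_sites(spec, t, i),
           initial = t == 1L && spec$meta[[i]]$has_init)
    })
  })
}

#' Markov blanket of a node in the unrolled network
#'
#' Parents, children (intra and inter, both directions across slice
#' boundaries) and co-parents of the children, truncated correctly at the
#' sequence boundaries.  Conditioning on the blanket renders the node
#' independent of the rest of the unrolled network.
#'
#' @param spec a [dbn_spec()].
#' @param n_slices length of the unrolled network.
#' @param t,i slice (1-based) and node index of the target site.
#' @return matrix with columns `slice`, `node`, one row per blanket member.
#' @export
markov_blanket <- function(spec, n_slices, t, i) {
  stopifnot(t >= 1L, t <= n_slices, i >= 1L, i <= n_nodes(spec))
  m <- spec$meta[[i]]
  sites <- parent_sites(spec, t, i)
  ch <- list()
  for (c_ in m$intra_children) ch[[length(ch) + 1L]] <- c(t, c_)
  if (t < n_slices)
    for (c_ in m$inter_children) ch[[length(ch) + 1L]] <- c(t + 1L, c_)
  for (s in ch) {
    sites <- rbind(sites, matrix(s, ncol = 2L,
                                 dimnames = list(NULL, c("slice", "node"))))
    sites <- rbind(sites, parent_sites(spec, s[1L], s[2L]))
  }
  if (!nrow(sites)) return(sites)
  sites <- unique(sites)
  sites <- sites[!(sites[, 1L] == t & sites[, 2L] == i), , drop = FALSE]
  sites[order(sites[, 1L], sites[, 2L]), , drop = FALSE]
}
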