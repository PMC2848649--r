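#' Run-time-dimensioned dense arrays
#'
#' `mdarray` is a dense multidimensional array whose rank is fixed only at
#' run time.  Values are stored flat in row-major order (the last axis varies
#' fastest), which is the natural layout for conditional probability tables
#' (CPTs): the leading axes index parent states and the final axis indexes
#' the node's own states.
#'
#' @param shape integer vector of positive extents.
#' @param values optional numeric vector of length `prod(shape)`, row-major.
#'   Defaults to all zeros.
#' @return an object of class `mdarray` with fields `shape` and `values`.
#' @examples
#' a <- mdarray(c(3, 4, 2))      # a CPT-shaped array with 24 cells
#' md_set(a, c(1, 2, 2), 0.5)
#' @export
mdarray <- function(shape, values = NULL) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || anyNA(shape) || any(shape < 1L))
    stop("invalid shape: every extent must be a positive integer")
  n <- prod(shape)
  if (is.null(values)) {
    values <- numeric(n)
  } else {
    if (length(values) != n)
      stop("values length ", length(values), " does not match shape product ", n)
    values <- as.numeric(values)
  }
  structure(list(shape = shape, values = values), class = "mdarray")
}

#' @export
print.mdarray <- function(x, ...) {
  cat("<mdarray ", paste(x$shape, collapse = " x "), ">\n", sep = "")
  invisible(x)
}

md_strides <- function(shape) {
  k <- length(shape)
  if (k == 1L) return(1L)
  s <- rev(cumprod(rev(shape)))[-1L]
  c(s, 1L)
}

md_offset <- function(a, idx) {
  idx <- as.integer(idx)
  if (length(idx) != length(a$shape))
    stop("index length must equal rank ", length(a$shape))
  if (anyNA(idx) || any(idx < 1L) || any(idx > a$shape))
    stop("index out of bounds")
  sum((idx - 1L) * md_strides(a$shape)) + 1L
}

#' Read one cell of an mdarray
#' @param a an [mdarray()].
#' @param idx full 1-based index vector.
#' @return the stored value.
#' @export
md_get <- function(a, idx) a$values[md_offset(a, idx)]

#' Write one cell of an mdarray
#' @inheritParams md_get
#' @param value replacement value.
#' @return the modified array.
#' @export
md_set <- function(a, idx, value) {
  a$values[md_offset(a, idx)] <- value
  a
}

#' Slice an mdarray along a prefix of its axes
#'
#' Fixing the first `length(prefix)` indices yields a sub-array over the
#' remaining axes; an empty prefix returns the array unchanged.
#'
#' @param a an [mdarray()].
#' @param prefix 1-based indices for a proper prefix of the axes
#'   (`length(prefix) < rank`).
#' @return an `mdarray` with shape `shape[-(1:length(prefix))]`.
#' @examples
#' a <- mdarray(c(3, 4, 2), seq_len(24))
#' mdarray_slice(a, c(2, 3))   # length-2 vector slice
#' @export
mdarray_slice <- function(a, prefix) {
  k <- length(prefix)
  if (k == 0L) return(a)
  if (k >= length(a$shape))
    stop("prefix length must be smaller than the rank")
  prefix <- as.integer(prefix)
  if (anyNA(prefix) || any(prefix < 1L) || any(prefix > a$shape[seq_len(k)]))
    stop("prefix index out of bounds")
  strides <- md_strides(a$shape)
  off <- sum((prefix - 1L) * strides[seq_len(k)])
  block <- strides[k]
  mdarray(a$shape[-seq_len(k)], a$values[off + seq_len(block)])
}

#' Shape of a conditional probability table
#'
#' A discrete node with parents of sizes `parent_sizes` and `node_size` own
#' states stores its CPT as an array of shape `c(parent_sizes, node_size)`;
#' the last axis indexes the node's own states.
#'
#' @param parent_sizes integer vector of parent state counts (possibly empty).
#' @param node_size the node's own state count.
#' @return integer extent vector.
#' @examples
#' cpt_shape(c(3, 4), 2)  # c(3, 4, 2): 24 conditional probabilities
#' @export
cpt_shape <- function(parent_sizes, node_size) {
  node_size <- as.integer(node_size)
  parent_sizes <- as.integer(parent_sizes)
  if (length(node_size) != 1L || is.na(node_size) || node_size < 1L)
    stop("node_size must be a positive integer")
  if (anyNA(parent_sizes) || any(parent_sizes < 1L))
    stop("parent sizes must be positive integers")
  c(parent_sizes, node_size)
}

## Convert a CPT-shaped mdarray to the internal configuration-major matrix
## (n_config x node_size) and back.  Row-major flat storage means the last
## axis is contiguous, so the matrix is filled by row.
md_as_config_matrix <- function(a, node_size) {
  stopifnot(a$shape[length(a$shape)] == node_size)
  matrix(a$values, ncol = node_size, byrow = TRUE)
}

config_matrix_as_md <- function(m, parent_sizes, node_size) {
  mdarray(cpt_shape(parent_sizes, node_size), as.vector(t(m)))
}
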