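#' Sequence batches with observed/hidden masking
#'
#' A batch holds a set of (possibly ragged) sequences over a DBN slice.
#' Internally values are stacked per node into `n_seq x max_len x width`
#' arrays; a parallel logical mask marks hidden entries (`TRUE` = hidden).
#' Hidden entries are permitted only on discrete nodes flagged
#' `hidden = TRUE` in the spec; their values start as `NA` until a Gibbs
#' assignment fills them.
#'
#' Observed angles are wrapped into `[0, 2*pi)`; observed Kent vectors are
#' renormalized when within `1e-6` of unit norm and rejected otherwise.
#'
#' @param spec a [dbn_spec()].
#' @param sequences list; each element is one sequence: a list with one
#'   element per node, a `length x width` matrix (or vector for width-1
#'   nodes) of values with `NA` marking hidden entries, plus an optional
#'   `mask` attribute.  Alternatively pass `values` / `mask` / `lengths`
#'   directly (internal use).
#' @param values,mask,lengths stacked representation (internal use).
#' @return an object of class `seq_batch`.
#' @export
seq_batch <- function(spec, sequences = NULL, values = NULL, mask = NULL,
                      lengths = NULL) {
  nn <- n_nodes(spec)
  if (is.null(sequences)) {
    stopifnot(!is.null(values), !is.null(mask), !is.null(lengths))
  } else {
    lengths <- vapply(sequences, function(s) {
      v1 <- s[[1L]]
      if (is.matrix(v1)) nrow(v1) else length(v1)
    }, 1L)
    Lmax <- max(lengths)
    ns <- length(sequences)
    values <- vector("list", nn)
    mask <- vector("list", nn)
    for (i in seq_len(nn)) {
      w <- spec$nodes[[i]]$width
      values[[i]] <- array(NA_real_, c(ns, Lmax, w))
      mask[[i]] <- matrix(FALSE, ns, Lmax)
      for (s in seq_len(ns)) {
        v <- sequences[[s]][[i]]
        if (!is.matrix(v)) v <- matrix(v, ncol = w)
        if (ncol(v) != w)
          stop("sequence ", s, " node ", i, ": expected width ", w)
        L <- lengths[s]
        hid <- apply(is.na(v), 1L, any)
        m <- attr(sequences[[s]], "mask")
        if (!is.null(m)) hid <- hid | m[, i]
        v[hid, ] <- NA_real_
        values[[i]][s, seq_len(L), ] <- v
        mask[[i]][s, seq_len(L)] <- hid
      }
    }
  }
  b <- structure(list(spec = spec, n_seq = length(lengths),
                      lengths = as.integer(lengths),
                      Lmax = if (length(lengths)) max(lengths) else 1L,
                      values = values, mask = mask),
                 class = "seq_batch")
  validate_batch(b)
}

validate_batch <- function(b) {
  spec <- b$spec
  for (i in seq_len(n_nodes(spec))) {
    nd <- spec$nodes[[i]]
    if (any(b$mask[[i]]) && !nd$hidden)
      stop("node ", nd$name, " has hidden entries but is not flagged hidden")
    valid <- outer(b$lengths, seq_len(b$Lmax), ">=") & !b$mask[[i]]
    v <- b$values[[i]]
    if (nd$family == "discrete") {
      x <- v[, , 1L][valid]
      if (any(is.na(x)) || any(x < 1 | x > nd$size | x != round(x)))
        stop("node ", nd$name, ": observed states must be integers in 1..",
             nd$size)
    } else if (nd$family %in% c("vonmises_uni", "vonmises_bi")) {
      for (k in seq_len(nd$width)) {
        x <- v[, , k]
        x[valid] <- wrap_angle(x[valid])
        v[, , k] <- x
      }
      b$values[[i]] <- v
    } else if (nd$family == "kent") {
      nrm2 <- v[, , 1L]^2 + v[, , 2L]^2 + v[, , 3L]^2
      bad <- valid & abs(sqrt(nrm2) - 1) > 1e-6
      if (any(bad, na.rm = TRUE))
        stop("node ", nd$name, ": observed values must be unit vectors ",
             "(within 1e-6)")
      nf <- sqrt(nrm2); nf[!valid | nf == 0] <- 1
      for (k in 1:3) v[, , k] <- v[, , k] / nf
      b$values[[i]] <- v
    } else if (nd$family %in% c("poisson", "multinomial")) {
      x <- v[, , , drop = FALSE]
      xv <- x[rep(valid, nd$width)]
      if (any(is.na(xv)) || any(xv < 0 | xv != round(xv)))
        stop("node ", nd$name, ": counts must be nonnegative integers")
    }
  }
  b
}

#' @export
print.seq_batch <- function(x, ...) {
  cat("<seq_batch> ", x$n_seq, " sequences, slices ",
      min(x$lengths), "..", x$Lmax, ", ",
      sum(vapply(x$mask, sum, 1)), " hidden entries\n", sep = "")
  invisible(x)
}

## TRUE where (seq, slice) exists.
valid_grid <- function(b) outer(b$lengths, seq_len(b$Lmax), ">=")

fmt_num <- function(x) {
  out <- vapply(x, function(v) formatC(v, format = "g", digits = 17), "")
  out
}

## ---- sequence file format ----------------------------------------------
## One record per (sequence, slice); tab-separated per-node fields; vector
## components comma-joined; hidden entries written as "?".

#' Write a sequence batch to a delimited text file
#'
#' Format: `#gibbsdbn-seq v1` header, a `#nodes` line naming each node as
#' `name:family:size`, then one tab-separated row per `(sequence, slice)`
#' with one field per node.  Vector-valued fields are comma-joined; hidden
#' entries are the literal token `?`.
#' @param batch a [seq_batch()].
#' @param path output file path.
#' @export
write_sequences <- function(batch, path) {
  spec <- batch$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gibbsdbn-seq v1", con)
  writeLines(paste0("#nodes\t", paste(vapply(spec$nodes, function(nd)
    paste(nd$name, nd$family, nd$size, sep = ":"), ""), collapse = "\t")), con)
  nn <- n_nodes(spec)
  rows <- character(0)
  for (s in seq_len(batch$n_seq)) {
    for (t in seq_len(batch$lengths[s])) {
      fields <- character(nn)
      for (i in seq_len(nn)) {
        if (batch$mask[[i]][s, t]) {
          fields[i] <- "?"
        } else {
          fields[i] <- paste(fmt_num(batch$values[[i]][s, t, ]),
                             collapse = ",")
        }
      }
      rows <- c(rows, paste(c(s, t, fields), collapse = "\t"))
    }
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read a sequence batch written by [write_sequences()]
#' @param path input file path.
#' @param spec the [dbn_spec()] the data belong to; checked against the
#'   file's node header.
#' @return a [seq_batch()].
#' @export
read_sequences <- function(path, spec) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "#gibbsdbn-seq v1")
    stop("not a gibbsdbn sequence file (missing version header)")
  hdr <- lines[startsWith(lines, "#nodes")]
  if (length(hdr) != 1L) stop("malformed sequence file: missing #nodes line")
  decl <- strsplit(hdr, "\t")[[1L]][-1L]
  want <- vapply(spec$nodes, function(nd)
    paste(nd$name, nd$family, nd$size, sep = ":"), "")
  if (!identical(decl, want))
    stop("sequence file node header does not match the spec")
  body <- lines[!startsWith(lines, "#")]
  nn <- n_nodes(spec)
  if (!length(body))
    return(seq_batch(spec, values = lapply(spec$nodes, function(nd)
      array(NA_real_, c(0, 1, nd$width))),
      mask = lapply(spec$nodes, function(nd) matrix(FALSE, 0, 1)),
      lengths = integer()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != nn + 2L)
  if (length(bad)) stop("malformed record at data line ", bad[1L])
  sq <- as.integer(vapply(parts, `[[`, "", 1L))
  sl <- as.integer(vapply(parts, `[[`, "", 2L))
  ns <- max(sq); Lmax <- max(sl)
  lens <- vapply(seq_len(ns), function(s) max(sl[sq == s]), 1L)
  values <- lapply(spec$nodes, function(nd)
    array(NA_real_, c(ns, Lmax, nd$width)))
  mask <- lapply(spec$nodes, function(nd) matrix(FALSE, ns, Lmax))
  for (r in seq_along(parts)) {
    for (i in seq_len(nn)) {
      f <- parts[[r]][i + 2L]
      if (f == "?") {
        mask[[i]][sq[r], sl[r]] <- TRUE
      } else {
        x <- as.numeric(strsplit(f, ",", fixed = TRUE)[[1L]])
        if (length(x) != spec$nodes[[i]]$width || anyNA(x))
          stop("malformed value field at data line ", r)
        values[[i]][sq[r], sl[r], ] <- x
      }
    }
  }
  seq_batch(spec, values = values, mask = mask, lengths = lens)
}

## ---- DBN spec file format ----------------------------------------------

#' Write a DBN specification file
#'
#' Plain-text key-value document: `node <name> <family> <size>
#' [hidden]` lines in slice order, then `intra <parent> <child>` and
#' `inter <parent> <child>` lines with 0-based node indices.
#' @param spec a [dbn_spec()].
#' @param path output file path.
#' @export
write_dbn_spec <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gibbsdbn-dbn v1", con)
  for (nd in spec$nodes)
    writeLines(paste("node", nd$name, nd$family, nd$size,
                     if (nd$hidden) "hidden" else "observed"), con)
  for (r in seq_len(nrow(spec$intra_edges)))
    writeLines(paste("intra", spec$intra_edges[r, 1L] - 1L,
                     spec$intra_edges[r, 2L] - 1L), con)
  for (r in seq_len(nrow(spec$inter_edges)))
    writeLines(paste("inter", spec$inter_edges[r, 1L] - 1L,
                     spec$inter_edges[r, 2L] - 1L), con)
  invisible(path)
}

#' Read a DBN specification file written by [write_dbn_spec()]
#' @param path input file path.
#' @return a [dbn_spec()].
#' @export
read_dbn_spec <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1L] != "#gibbsdbn-dbn v1")
    stop("not a gibbsdbn DBN spec file (missing version header)")
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nodes <- list(); intra <- list(); inter <- list()
  for (tk in toks) {
    switch(tk[1L],
      node = {
        if (length(tk) < 4L) stop("malformed node line")
        nodes[[length(nodes) + 1L]] <-
          node_spec(tk[2L], tk[3L], as.integer(tk[4L]),
                    hidden = length(tk) >= 5L && tk[5L] == "hidden")
      },
      intra = intra[[length(intra) + 1L]] <- as.integer(tk[2:3]) + 1L,
      inter = inter[[length(inter) + 1L]] <- as.integer(tk[2:3]) + 1L,
      stop("unknown directive in DBN spec file: ", tk[1L]))
  }
  dbn_spec(nodes, intra_edges = intra, inter_edges = inter)
}
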