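## Suspend/resume serialization of training state as structured JSON text.
## Every numeric array is stored with explicit shape metadata; doubles are
## written at full precision so a loaded state continues bit-identically.

STATE_VERSION <- "gibbsdbn-state-1"

## Doubles are serialized as %.17g strings: JSON numbers lose the last two
## significant digits through jsonlite, and resume must be bit-identical.
pack_array <- function(x) {
  if (is.null(x)) return(NULL)
  type <- if (is.logical(x)) "logical"
          else if (is.integer(x)) "integer" else "double"
  data <- if (type == "double") fmt_num(as.vector(x)) else as.vector(x)
  list(dim = as.integer(dim(x) %||% length(x)), type = type, data = data)
}

unpack_array <- function(p) {
  if (is.null(p)) return(NULL)
  x <- switch(p$type %||% "double",
              logical = as.logical(p$data),
              integer = as.integer(p$data),
              suppressWarnings(as.numeric(p$data)))
  if (length(p$dim) > 1L) dim(x) <- p$dim
  x
}

pack_family <- function(fp) {
  if (is.null(fp)) return(NULL)
  base <- list(family = fp$family, psz = as.integer(fp$psz))
  extra <- switch(fp$family,
    discrete = ,
    multinomial = list(size = fp$size, prob = pack_array(fp$prob)),
    poisson = list(rates = pack_array(fp$rates)),
    gaussian = list(d = fp$d, means = pack_array(fp$means),
                    covs = pack_array(fp$covs)),
    vonmises_uni = list(mu = pack_array(fp$mu), kappa = pack_array(fp$kappa)),
    vonmises_bi = list(mu = pack_array(fp$mu), nu = pack_array(fp$nu),
                       kappa1 = pack_array(fp$kappa1),
                       kappa2 = pack_array(fp$kappa2),
                       kappa3 = pack_array(fp$kappa3)),
    kent = list(kappa = pack_array(fp$kappa), beta = pack_array(fp$beta),
                gammas = pack_array(fp$gammas)))
  c(base, extra)
}

unpack_family <- function(p) {
  if (is.null(p) || is.null(p$family)) return(NULL)
  psz <- as.integer(p$psz)
  switch(p$family,
    discrete = {
      prob <- rbind(unpack_array(p$prob))
      new_family_params("discrete", psz,
                        list(size = as.integer(p$size), prob = prob,
                             logp = log(prob)))
    },
    multinomial = {
      prob <- rbind(unpack_array(p$prob))
      new_family_params("multinomial", psz,
                        list(size = as.integer(p$size), prob = prob,
                             logp = log(prob)))
    },
    poisson = poisson_params(unpack_array(p$rates), psz),
    gaussian = {
      covs <- unpack_array(p$covs)
      if (length(dim(covs)) == 2L) covs <- array(covs, c(dim(covs), 1L))
      gaussian_params(rbind(unpack_array(p$means)), covs, psz)
    },
    vonmises_uni = vm_params(unpack_array(p$mu), unpack_array(p$kappa), psz),
    vonmises_bi = bvm_params(unpack_array(p$mu), unpack_array(p$nu),
                             unpack_array(p$kappa1), unpack_array(p$kappa2),
                             unpack_array(p$kappa3), psz),
    kent = {
      g <- unpack_array(p$gammas)
      if (length(dim(g)) == 2L) g <- array(g, c(3L, 3L, 1L))
      kent_params(unpack_array(p$kappa), unpack_array(p$beta), g, psz)
    },
    stop("unsupported family in state file: ", p$family))
}

pack_spec <- function(spec) {
  list(nodes = lapply(spec$nodes, function(nd)
    list(name = nd$name, family = nd$family, size = nd$size,
         hidden = nd$hidden)),
    intra = pack_array(spec$intra_edges), inter = pack_array(spec$inter_edges))
}

unpack_spec <- function(p) {
  nodes <- lapply(p$nodes, function(nd)
    node_spec(nd$name, nd$family, nd$size, hidden = isTRUE(nd$hidden)))
  to_edges <- function(a) {
    e <- unpack_array(a)
    if (is.null(e) || !length(e)) NULL else matrix(as.integer(e), ncol = 2L)
  }
  dbn_spec(nodes, intra_edges = to_edges(p$intra),
           inter_edges = to_edges(p$inter))
}

pack_params <- function(params) {
  lapply(unclass(params), function(np)
    list(name = np$name, family = np$family, size = np$size,
         p = pack_family(np$p), p0 = pack_family(np$p0)))
}

unpack_params <- function(p, spec) {
  per_node <- lapply(p, function(np)
    list(p = unpack_family(np$p), p0 = unpack_family(np$p0)))
  dbn_params(spec, per_node)
}

pack_batch <- function(b) {
  list(lengths = as.integer(b$lengths),
       values = lapply(b$values, pack_array),
       mask = lapply(b$mask, pack_array))
}

unpack_batch <- function(p, spec) {
  values <- lapply(p$values, unpack_array)
  mask <- lapply(p$mask, function(m) {
    x <- unpack_array(m)
    storage.mode(x) <- "logical"
    x
  })
  structure(list(spec = spec, n_seq = length(p$lengths),
                 lengths = as.integer(p$lengths),
                 Lmax = max(as.integer(p$lengths)), values = values,
                 mask = mask), class = "seq_batch")
}

pack_stats <- function(sw) {
  lapply(sw, function(st) lapply(st, function(node_st)
    lapply(node_st, function(set_st)
      if (is.null(set_st)) NULL else lapply(set_st, pack_array))))
}

unpack_stats <- function(p) {
  lapply(p, function(st) {
    out <- lapply(st, function(node_st)
      lapply(node_st, function(set_st) {
        if (is.null(set_st) || !length(set_st)) return(NULL)
        lapply(set_st, unpack_array)
      }))
    class(out) <- "dbn_suffstats"
    out
  })
}

#' Save a training state to a JSON text file
#'
#' The file carries a format version and full-precision numbers; loading
#' it and continuing (more sweeps, more EM iterations) is bit-identical to
#' never having stopped.
#' @param state a `dbn_training_state` from [train()].
#' @param path output file path.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "dbn_training_state"))
  obj <- list(
    version = STATE_VERSION,
    spec = pack_spec(state$spec),
    config = state$config[setdiff(names(state$config), "")],
    iteration = state$iteration,
    params = pack_params(state$params),
    params_avg = pack_params(state$params_avg),
    batch = pack_batch(state$batch),
    trace = as.list(state$trace),
    stats_window = pack_stats(state$stats_window),
    rng_state = state$rng_state)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a training state saved by [save_state()]
#' @param path input file path.
#' @return a `dbn_training_state`.
#' @export
load_state <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                        simplifyDataFrame = FALSE),
    error = function(e) stop("state file parse error: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(obj$version) || !identical(obj$version, STATE_VERSION))
    stop("unsupported state file version: ",
         obj$version %||% "<missing>", " (expected ", STATE_VERSION, ")")
  spec <- unpack_spec(obj$spec)
  params <- unpack_params(obj$params, spec)
  attr(params, "spec") <- spec
  params_avg <- unpack_params(obj$params_avg, spec)
  cfgl <- obj$config
  config <- em_config(flavour = cfgl$flavour,
                      n_iterations = cfgl$n_iterations,
                      mcem_samples = cfgl$mcem_samples,
                      burn_in = cfgl$burn_in, pseudocount = cfgl$pseudocount,
                      ridge = cfgl$ridge, seed = cfgl$seed,
                      window = cfgl$window, tolerance = cfgl$tolerance,
                      estimate = cfgl$estimate,
                      avg_window = cfgl$avg_window,
                      compute_forward = isTRUE(cfgl$compute_forward),
                      n_starts = cfgl$n_starts %||% 1L)
  trace <- as.data.frame(lapply(obj$trace, function(col) {
    col[vapply(col, is.null, TRUE)] <- NA
    unlist(col) %||% numeric()
  }))
  if (!nrow(trace))
    trace <- data.frame(iteration = integer(), completed_loglik = numeric(),
                        forward_loglik = numeric())
  final <- if (config$estimate == "average") params_avg else params
  structure(list(version = obj$version, spec = spec, config = config,
                 iteration = as.integer(obj$iteration),
                 params = params, params_avg = params_avg,
                 params_final = final,
                 batch = unpack_batch(obj$batch, spec),
                 trace = trace,
                 stats_window = unpack_stats(obj$stats_window),
                 rng_state = as.integer(obj$rng_state)),
            class = "dbn_training_state")
}
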