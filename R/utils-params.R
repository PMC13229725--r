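# Model parameters live in a nested list whose leaves are numeric arrays
# (matrices / vectors).  The helpers below apply functions leaf-wise, pair
# two parameter trees of identical shape, and flatten/unflatten for the
# optimizer, gradient clipping and finite-difference checks.

is_param_leaf <- function(x) is.numeric(x)

param_map <- function(p, f) {
  if (is_param_leaf(p)) return(f(p))
  lapply(p, param_map, f = f)
}

param_map2 <- function(a, b, f) {
  if (is_param_leaf(a)) return(f(a, b))
  stopifnot(length(a) == length(b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- param_map2(a[[i]], b[[i]], f)
  out
}

param_zeros_like <- function(p) param_map(p, function(x) x * 0)

param_flatten <- function(p) {
  leaves <- list()
  rec <- function(x) {
    if (is_param_leaf(x)) leaves[[length(leaves) + 1L]] <<- as.vector(x)
    else for (el in x) rec(el)
    invisible(NULL)
  }
  rec(p)
  if (length(leaves) == 0) numeric(0) else unlist(leaves, use.names = FALSE)
}

param_unflatten <- function(vec, skeleton) {
  pos <- 0L
  rec <- function(x) {
    if (is_param_leaf(x)) {
      n <- length(x)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(x))) dim(out) <- dim(x)
      return(out)
    }
    lapply(x, rec)
  }
  out <- rec(skeleton)
  stopifnot(pos == length(vec))
  out
}

param_sumsq <- function(p) {
  s <- 0
  rec <- function(x) {
    if (is_param_leaf(x)) s <<- s + sum(x^2) else for (el in x) rec(el)
    invisible(NULL)
  }
  rec(p)
  s
}

#' Seed every source of randomness in the package
#'
#' All stochastic operations (synthetic data generation, parameter
#' initialization, batch shuffling, dropout masks, Monte-Carlo probes) draw
#' from R's global random number generator, so a single call makes a whole
#' generate/train/evaluate pipeline reproducible bit for bit.
#'
#' @param seed Integer seed.
#' @return Invisibly, the seed.
#' @export
set_global_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(as.integer(seed))
}

# Short stable digest of an arbitrary (jsonlite-serializable) object; used to
# stamp evaluation reports with the configuration they came from.
config_digest <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
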