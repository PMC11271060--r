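#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_config <- function(...) {
  stop(structure(class = c("plnmrad_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_config(sprintf("'%s' must be a single finite number in [%s, %s]",
                        name, format(lower), format(upper)))
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name, lower = min)
  if (x != round(x)) stop_config(sprintf("'%s' must be an integer count", name))
  invisible(as.integer(x))
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of a single master seed to per-stage seeds via a
#' Lehmer-style multiplicative congruential step modulo the Mersenne prime
#' 2^31 - 1. Every source of randomness in the pipeline draws its seed from
#' the master seed through this function so that one integer reproduces a
#' whole run.
#'
#' @param master master seed, a single integer.
#' @param stage stage counter (non-negative integer); distinct stages of a
#'   pipeline use distinct counters.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
#' @export
derive_seed <- function(master, stage = 0L) {
  assert_count(master, "master")
  assert_count(stage, "stage")
  m <- 2147483647
  s <- (abs(master) %% m) + 1
  for (i in seq_len(stage + 1L)) s <- (s * 48271) %% m
  as.integer(ifelse(s == 0, 1, s))
}

# Shift a 3D array by an integer offset, exposing NA outside --------------

shift3d <- function(a, off, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) {
      if (o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] - o)
      dst[[k]] <- seq_len(d[k] - o) + o
    } else {
      if (-o >= d[k]) return(out)
      src[[k]] <- seq_len(d[k] + o) - o
      dst[[k]] <- seq_len(d[k] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# The 13 unique direction offsets of a 26-neighbourhood (one per +/- pair)
offsets13 <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  keep <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
  as.matrix(offs[keep, , drop = FALSE])
}

# All 26 neighbour offsets
offsets26 <- function() {
  o13 <- offsets13()
  rbind(o13, -o13)
}
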