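#' @import methods
#' @importFrom stats convolve rnorm runif sd setNames dgamma
NULL

# Attention classes in canonical order; CENTER last so the three
# command-generating directions come first.
DIRECTIONS <- c("RIGHT", "LEFT", "UP", "CENTER")
COMMANDS <- c(RIGHT = "TURN_RIGHT", LEFT = "TURN_LEFT", UP = "FORWARD")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded package internals never disturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# wrap an angle in degrees to [0, 360)
wrapHeading <- function(deg) {
  ((deg %% 360) + 360) %% 360
}

# signed smallest difference a - b in degrees, in [-180, 180)
angleDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d >= 180, d - 360, d)
}

# linear index <-> (i, j, k) 1-based voxel coordinates
linearToIjk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijkToLinear <- function(ijk, dims) {
  as.integer((ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dims[1] +
               (ijk[, 3] - 1L) * dims[1] * dims[2] + 1L)
}

assertScalarNumeric <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower) {
    stop(sprintf("'%s' must be a finite numeric scalar >= %s", name, lower),
         call. = FALSE)
  }
  invisible(x)
}
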