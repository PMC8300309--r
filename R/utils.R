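#' @keywords internal
"_PACKAGE"

# Stage logging. Every pipeline stage reports the parameters it used and the
# counts it produced; silenced with options(circumnut.verbose = FALSE).
cn_log <- function(...) {
  if (isTRUE(getOption("circumnut.verbose", TRUE))) {
    message("[circumnut] ", sprintf(...))
  }
  invisible(NULL)
}

# Wrap an angle (radians) into [0, 2*pi).
wrap_2pi <- function(theta) {
  theta %% (2 * pi)
}

# Wrap an angle difference into (-pi, pi].
wrap_pi <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

# Euclidean norm of the rows of a matrix (or of a single vector).
row_norms <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  sqrt(rowSums(m^2))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
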