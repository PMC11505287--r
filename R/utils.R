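#' @useDynLib dentseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Stage-prefixed logging to stderr; level gate via options(dentseg.log_level=).
log_msg <- function(stage, fmt, ..., level = "info") {
  lvls <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  gate <- getOption("dentseg.log_level", "info")
  if (lvls[[level]] >= lvls[[gate]]) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# uniform point on the unit sphere
runif_sphere <- function(n = 1L) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  unname(cbind(r * cos(phi), r * sin(phi), z))
}

# Rotation matrix about an arbitrary unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
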