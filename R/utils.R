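#' @useDynLib limbscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm quantile
#' @importFrom grDevices rgb2hsv
NULL

# Signal a classed error so callers can distinguish failure modes
# (invalid_argument, degenerate_configuration, empty_segmentation, ...).
ls_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("limbscan_", class), "limbscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_that <- function(ok, msg, class = "invalid_argument") {
  if (!isTRUE(ok)) ls_stop(msg, class)
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# A NULL seed runs `expr` as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_point_matrix <- function(x, arg = "points") {
  if (is.null(dim(x))) {
    check_that(length(x) == 3, sprintf("%s must be a 3-vector or an N x 3 matrix", arg))
    x <- matrix(as.numeric(x), 1, 3)
  }
  x <- as.matrix(x)
  check_that(ncol(x) == 3, sprintf("%s must have 3 columns", arg))
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
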