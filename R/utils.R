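# internal helpers shared across modules

#' @noRd
um_to_px <- function(um, pixel_size_um) um / pixel_size_um

#' @noRd
um2_to_px2 <- function(um2, pixel_size_um) um2 / pixel_size_um^2

#' @noRd
px2_to_um2 <- function(px2, pixel_size_um) px2 * pixel_size_um^2

# Evaluate expr under a private RNG stream, restoring the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# odd-sized disc brush for morphology, radius in pixels (>= 1 px)
#' @noRd
disc_brush <- function(radius_px) {
  size <- 2L * max(1L, as.integer(round(radius_px))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# stop() with a classed condition so callers can discriminate error kinds
#' @noRd
ns_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "netscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
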