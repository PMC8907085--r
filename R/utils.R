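#' Marker panel
#'
#' Internal column-safe names of the four first-trimester screening markers
#' used throughout the package, in canonical panel order.
#'
#' @return Character vector `c("papp_a", "free_bhcg", "nt", "afp_l2")`.
#' @export
marker_panel <- function() MARKER_PANEL

MARKER_PANEL <- c("papp_a", "free_bhcg", "nt", "afp_l2")

MARKER_LABELS <- c(
  papp_a    = "PAPP-A",
  free_bhcg = "free beta-hCG",
  nt        = "NT",
  afp_l2    = "AFP-L2"
)

# Phi^{-1}(0.975): converts a 2.5th/97.5th percentile half-width to a
# normal scale parameter.
Z_P975 <- 1.959964

GROUP_LEVELS <- c("affected", "control")

mom_col <- function(marker) paste0(marker, "_mom")
raw_col <- function(marker) paste0(marker, "_raw")

# stop() with the calling function's name prefixed, no call in message
abort <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive", name))
  }
  invisible(x)
}

check_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

# evaluate expr with the RNG seeded locally, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# labels -> logical is-affected vector; accepts factor/character with the
# canonical group levels or a logical vector
as_affected <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), GROUP_LEVELS)
  if (length(bad)) {
    abort("unknown group labels: ", paste(bad, collapse = ", "),
          " (expected 'affected'/'control')")
  }
  labels == "affected"
}
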