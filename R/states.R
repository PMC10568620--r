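#' Tumor composition states
#'
#' A tumor state records the (continuous, deterministic) cell counts of the
#' four genotypes at one time point: `w` (sensitive to both drugs), `x`
#' (T790M), `y` (C797S), `z` (doubly resistant), plus the `time` in days at
#' which the state holds.
#'
#' @param w,x,y,z Non-negative cell counts.
#' @param time Time in days (default 0).
#' @return A one-row tibble with columns `time`, `w`, `x`, `y`, `z`.
#' @examples
#' tumor_state(1e9, 0, 0, 0)
#' @export
tumor_state <- function(w, x, y, z, time = 0) {
  counts <- c(w = w, x = x, y = y, z = z)
  if (!all(is.finite(counts)) || any(counts < 0)) {
    abort("Cell counts must be finite and >= 0.", class = "tki_error_state")
  }
  tibble(time = time, w = w, x = x, y = y, z = z)
}

#' Standard initial tumor composition
#'
#' Builds the initial state used throughout the analyses: a clinically
#' detectable tumor of `total` cells (default 1e9, roughly a 1 cm nodule)
#' carrying small resistant subclones `x0`, `y0`, `z0`, with the sensitive
#' Type-W population making up the remainder.
#'
#' @param total Total initial cell number (default 1e9).
#' @param x0,y0,z0 Initial counts of Type-X, Type-Y and Type-Z (defaults
#'   1e4, 1e4 and 10).
#' @return A one-row tibble (see [tumor_state()]) at `time = 0`.
#' @examples
#' standard_initial_state()
#' @export
standard_initial_state <- function(total = 1e9, x0 = 1e4, y0 = 1e4, z0 = 10) {
  if (any(c(x0, y0, z0) < 0)) {
    abort("Resistant-type counts must be >= 0.", class = "tki_error_composition")
  }
  w0 <- total - x0 - y0 - z0
  if (w0 <= 0) {
    abort(
      "Invalid composition: `total` must exceed x0 + y0 + z0.",
      class = "tki_error_composition"
    )
  }
  tumor_state(w0, x0, y0, z0)
}

#' Total cell number of a state (or per-row totals of a trajectory)
#'
#' @param state A data frame with columns `w`, `x`, `y`, `z`.
#' @return Numeric vector of row totals.
#' @export
state_total <- function(state) {
  state$w + state$x + state$y + state$z
}

# internal: one-row state tibble -> named numeric c(w, x, y, z)
as_state_vector <- function(state) {
  if (is.numeric(state) && length(state) == 4) {
    return(setNames(as.numeric(state), c("w", "x", "y", "z")))
  }
  stopifnot(is.data.frame(state), nrow(state) == 1)
  c(w = state$w, x = state$x, y = state$y, z = state$z)
}
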