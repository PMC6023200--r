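#' Run code with a private, explicitly seeded RNG stream
#'
#' Evaluates `code` after seeding the RNG with `seed`, then restores the
#' caller's RNG state, so generators are deterministic without touching
#' global randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Disk structuring element
#'
#' Binary disk kernel containing offsets (dx, dy) with dx^2 + dy^2 <= r^2;
#' the kernel used for every morphological dilation/erosion in the mask
#' pipeline.
#'
#' @param r non-negative integer radius in pixels.
#' @return (2r+1) x (2r+1) integer 0/1 matrix.
#' @export
disk_kernel <- function(r) {
  stopifnot(length(r) == 1, r >= 0)
  r <- as.integer(round(r))
  d <- -r:r
  k <- outer(d^2, d^2, "+") <= r^2
  storage.mode(k) <- "integer"
  k
}

#' Well names for a 384-well plate
#'
#' @param row integer row index 1..16 (A..P) or row letter.
#' @param col integer column index 1..24.
#' @return character well id such as "A01".
#' @export
well_name <- function(row, col) {
  if (is.character(row)) row <- match(toupper(row), LETTERS)
  stopifnot(all(row >= 1 & row <= 16), all(col >= 1 & col <= 24))
  sprintf("%s%02d", LETTERS[row], as.integer(col))
}

# derive a per-field seed from a plate seed, well index and site; kept
# strictly below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, well_index, site) {
  as.integer((as.numeric(seed) * 48271 + well_index * 9973 + site * 131) %%
               2147483629)
}

# round to 2 significant figures for reporting (potency tables)
signif2 <- function(x) signif(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a
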