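# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_proportion <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1)
    stopf("`%s` must be a single number in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

# Deterministic half-up rounding (base round() ties to even).
round_half_up <- function(x) floor(x + 0.5)

# Scoped seeding: restores the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Map a DNA string to integer codes 1:4 (A,C,G,T); anything else (incl. N) -> NA.
encode_dna <- function(seq) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt(seq)]
}

#' Reverse complement of a DNA string
#'
#' @param seq A single character string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return The reverse complement as an upper-case string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}
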