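#' Screen feature names
#'
#' The per-nucleus features carried through the scoring chain: circularity,
#' cross-sectional area, major/minor axis lengths, and mean lamin A/C and
#' lamin B1 immunofluorescence intensities. Cell count is scored through the
#' same chain under the name `"cellcount"`.
#'
#' @return Character vector of feature names.
#' @export
#' @examples
#' screenFeatures()
screenFeatures <- function() {
  c("circularity", "area", "length", "width", "laminAC_mean", "laminB1_mean")
}

#' Well name helpers
#'
#' 384-well plates are addressed as `A01`..`P24` (row letter, zero-padded
#' column). These helpers convert between names and (row, col) indices.
#'
#' @param row,col 1-based row and column indices.
#' @param x character vector of well names.
#' @param n_rows,n_cols plate format (defaults 16 x 24).
#' @return `wellName` a character vector; `parseWell` a data.frame with
#'   columns `row` and `col`.
#' @export
#' @examples
#' wellName(1, 1)
#' parseWell(c("A01", "P24"))
wellName <- function(row, col) {
  stopifnot(all(row >= 1), all(col >= 1), all(row <= 26))
  paste0(LETTERS[row], formatC(col, width = 2, flag = "0"))
}

#' @rdname wellName
#' @export
parseWell <- function(x, n_rows = 16L, n_cols = 24L) {
  ok <- grepl("^[A-Z][0-9]{2,}$", x)
  row <- match(substr(x, 1, 1), LETTERS)
  col <- suppressWarnings(as.integer(substring(x, 2)))
  bad <- !ok | is.na(row) | is.na(col) | row > n_rows | col < 1 | col > n_cols
  if (any(bad)) {
    stop("malformed well name(s) at position(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "))
  }
  data.frame(row = row, col = col)
}

## Deterministic child seed for a named random stream. A master seed plus a
## key (replicate/plate/well, ...) is hashed to a 31-bit integer so any well
## can be re-simulated in isolation. Horner hash mod (2^31 - 1): every
## intermediate stays below 2^53, so doubles are exact.
childSeed <- function(master, ...) {
  key <- paste(master, ..., sep = "\r")
  codes <- utf8ToInt(key)
  h <- 0
  m <- 2147483647
  for (cc in codes) h <- (h * 127 + cc) %% m
  as.integer(h)
}

## Evaluate expr with a private RNG stream seeded from (master, key...),
## restoring the caller's RNG state afterwards.
withChildSeed <- function(master, ..., expr) {
  seed <- childSeed(master, ...)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## internal: stop() with a consistent prefix for validation failures
.checkTrue <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}
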