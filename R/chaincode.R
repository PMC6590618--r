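# Freeman 8-connect chain coding of single-width pixel paths.
#
# Directions follow the standard counterclockwise numbering with code 0 along
# +x: 0 = (+1,0), 1 = (+1,+1), 2 = (0,+1), 3 = (-1,+1), 4 = (-1,0),
# 5 = (-1,-1), 6 = (0,-1), 7 = (+1,-1).  Coordinates are (x, y) with y
# increasing upward; image rows are flipped on read so that code 2 is "up".

code_dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
code_dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' Coerce to a chain code
#'
#' Accepts an integer vector of codes in 0--7 or a single digit string such
#' as `"07107565"` and returns a validated integer vector.
#'
#' @param x Integer (or numeric) vector of codes, or a digit string.
#' @return Integer vector with values in 0--7.
#' @export
#' @examples
#' as_chain_code("07107565")
as_chain_code <- function(x) {
  if (is.character(x)) {
    x <- as.integer(unlist(strsplit(x, ""), use.names = FALSE))
  }
  if (is.double(x)) {
    if (any(x != trunc(x), na.rm = TRUE)) {
      abort("chain codes must be whole numbers", class = "shapelength_bad_code")
    }
    x <- as.integer(x)
  }
  if (length(x) && (anyNA(x) || any(x < 0L | x > 7L))) {
    abort("chain codes must be integers in 0..7", class = "shapelength_bad_code")
  }
  x
}

path_xy <- function(path) {
  if (is.matrix(path)) {
    stopifnot(ncol(path) >= 2)
    return(list(x = path[, 1], y = path[, 2]))
  }
  if (is.data.frame(path)) {
    stopifnot(all(c("x", "y") %in% names(path)))
    return(list(x = path$x, y = path$y))
  }
  abort("a pixel path must be a matrix or data frame with x and y columns",
        class = "shapelength_invalid_path")
}

#' Trace the chain code of a pixel path
#'
#' Encodes each displacement between consecutive pixels of an 8-connected
#' path as a Freeman code in 0--7.
#'
#' @param path Matrix or data frame with integer `x`, `y` columns, ordered
#'   from one endpoint to the other.
#' @return Integer vector of length `nrow(path) - 1`.
#' @export
#' @examples
#' trace_chain_code(data.frame(x = c(0, 1, 1), y = c(0, 1, 2)))
trace_chain_code <- function(path) {
  p <- path_xy(path)
  n <- length(p$x)
  if (n < 2) return(integer(0))
  dx <- diff(p$x)
  dy <- diff(p$y)
  bad <- which(abs(dx) > 1 | abs(dy) > 1 | (dx == 0 & dy == 0))
  if (length(bad)) {
    abort(
      paste0("pixels ", bad[1], " and ", bad[1] + 1, " are not 8-adjacent"),
      class = "shapelength_invalid_path"
    )
  }
  # lookup over (dx, dy) in {-1,0,1}^2
  lut <- matrix(NA_integer_, 3, 3)
  for (code in 0:7) lut[code_dx[code + 1] + 2, code_dy[code + 1] + 2] <- code
  lut[cbind(dx + 2, dy + 2)]
}

#' Reconstruct a pixel path from a chain code
#'
#' @param codes Chain code (integer vector or digit string).
#' @param origin Length-2 integer vector, the starting pixel `p_0`.
#' @return Tibble with columns `index` (0-based), `x`, `y`.
#' @export
follow_chain_code <- function(codes, origin = c(0L, 0L)) {
  codes <- as_chain_code(codes)
  tibble(
    index = 0:length(codes),
    x = origin[1] + cumsum(c(0L, code_dx[codes + 1L])),
    y = origin[2] + cumsum(c(0L, code_dy[codes + 1L]))
  )
}

#' Reverse a chain code
#'
#' Traversing the same path from the opposite end reverses the code order
#' and replaces every code by its opposite direction, `(c + 4) mod 8`.
#' The head-to-tail code `"07107565"` becomes `"12134534"`.
#'
#' @param codes Chain code (integer vector or digit string).
#' @return Same representation as the input (string in, string out).
#' @export
#' @examples
#' reverse_chain_code("07107565")
reverse_chain_code <- function(codes) {
  chr <- is.character(codes)
  cc <- as_chain_code(codes)
  if (!length(cc)) abort("empty chain code", class = "shapelength_bad_code")
  out <- rev((cc + 4L) %% 8L)
  if (chr) paste(out, collapse = "") else out
}

#' Tally even, odd and corner code counts
#'
#' Even codes are horizontal/vertical unit steps, odd codes diagonal
#' `sqrt(2)` steps; a corner is any position where consecutive codes differ.
#'
#' @param codes Chain code (integer vector or digit string).
#' @return One-row tibble with `n_even`, `n_odd`, `n_corner`, `n_codes`.
#' @export
code_tallies <- function(codes) {
  cc <- as_chain_code(codes)
  tibble(
    n_even = sum(cc %% 2L == 0L),
    n_odd = sum(cc %% 2L == 1L),
    n_corner = if (length(cc) < 2) 0L else sum(diff(cc) != 0L),
    n_codes = length(cc)
  )
}

#' Validate the single-width property of a pixel path
#'
#' A backbone path is single-width when consecutive pixels are 8-adjacent,
#' all pixels are distinct, no two non-consecutive pixels are 8-adjacent
#' (Chebyshev distance >= 2), and each endpoint touches exactly one path
#' pixel.  Returns a diagnostic report rather than raising.
#'
#' @param path Matrix or data frame with `x`, `y` columns.
#' @return Tibble with columns `check`, `pass` and a list-column
#'   `offending` of 1-based pixel indices; the overall verdict is in
#'   attribute `"valid"` (see [is_single_width()]).
#' @export
validate_single_width <- function(path) {
  p <- path_xy(path)
  n <- length(p$x)
  cheb <- function(i, j) pmax(abs(p$x[i] - p$x[j]), abs(p$y[i] - p$y[j]))

  adj_bad <- if (n >= 2) which(cheb(1:(n - 1), 2:n) != 1) else integer(0)
  dup_bad <- which(duplicated(paste(p$x, p$y)))

  sep_bad <- integer(0)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      j <- (i + 2):n
      hit <- j[cheb(rep(i, length(j)), j) < 2]
      sep_bad <- c(sep_bad, hit)
    }
    sep_bad <- sort(unique(sep_bad))
  }

  end_bad <- integer(0)
  if (n >= 2) {
    for (e in c(1L, n)) {
      deg <- sum(cheb(rep(e, n), seq_len(n)) == 1)
      if (deg != 1) end_bad <- c(end_bad, e)
    }
  }

  out <- tibble(
    check = c("adjacency", "distinctness", "separation", "endpoint_degree"),
    pass = c(!length(adj_bad), !length(dup_bad), !length(sep_bad), !length(end_bad)),
    offending = list(adj_bad, dup_bad, sep_bad, end_bad)
  )
  attr(out, "valid") <- all(out$pass)
  out
}

#' @rdname validate_single_width
#' @return `is_single_width()` returns a single logical.
#' @export
is_single_width <- function(path) {
  isTRUE(attr(validate_single_width(path), "valid"))
}
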