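# Shape numbers and the 12-class taxonomy of single-width 4-pixel segments.
#
# Each rolling 4-pixel segment of a backbone is described by three
# consecutive chain codes (c_prev, c_mid, c_next).  Its shape number is the
# triple of cyclic code differences (mod 8), and a two-step canonicalization
# (complement all digits when the first exceeds 4, then order the last two
# ascending) makes the identifier invariant to traversal direction, 90-degree
# rotation and mirroring.  The canonical identifier plus the parity of the
# middle code (even = direct, odd = diagonal connection) selects one of the
# twelve shape classes k1..k12.

shape_labels <- paste0("k", 1:12)

# canonical id -> class for the unique ids; pairs resolved by middle parity
canon_unique <- c("026" = 5L, "116" = 8L, "206" = 9L, "367" = 12L)
canon_pairs <- c("000" = 1L, "017" = 3L, "107" = 6L, "277" = 10L)  # even member

#' Rolling 4-pixel segments of a chain code
#'
#' Slides a window over the chain and returns one segment per interior code
#' position `i = 2..n-1`; each segment is the code triple
#' `(c[i-1], c[i], c[i+1])` describing 4 consecutive pixels.  The head
#' (`i = 1`) and tail (`i = n`) connections have no full segment and are
#' handled separately by the estimators.
#'
#' @param codes Chain code (integer vector or digit string) of length >= 3.
#' @return Tibble with columns `i`, `c_prev`, `c_mid`, `c_next`.
#' @export
rolling_segments <- function(codes) {
  cc <- as_chain_code(codes)
  n <- length(cc)
  if (n < 3) {
    abort("a chain of fewer than 3 codes has no full 4-pixel segment",
          class = "shapelength_too_short")
  }
  i <- 2:(n - 1)
  tibble(i = i, c_prev = cc[i - 1L], c_mid = cc[i], c_next = cc[i + 1L])
}

#' Shape number of a 4-pixel segment
#'
#' The shape number of the code triple `(c_prev, c_mid, c_next)` is the digit
#' triple `s1 = (c_prev - c_next) mod 8`, `s2 = (c_mid - c_prev) mod 8`,
#' `s3 = (c_next - c_mid) mod 8` (negative differences are brought back into
#' 0..7 by the eight's complement).
#'
#' @param c_prev,c_mid,c_next Integer code vectors, or pass a segment tibble
#'   from [rolling_segments()] as the single first argument.
#' @return Character vector of three-digit shape numbers.
#' @export
#' @examples
#' shape_number(2, 3, 1)  # "116"
shape_number <- function(c_prev, c_mid, c_next) {
  if (is.data.frame(c_prev)) {
    seg <- c_prev
    c_prev <- seg$c_prev
    c_mid <- seg$c_mid
    c_next <- seg$c_next
  }
  c_prev <- as_chain_code(c_prev)
  c_mid <- as_chain_code(c_mid)
  c_next <- as_chain_code(c_next)
  s1 <- (c_prev - c_next) %% 8L
  s2 <- (c_mid - c_prev) %% 8L
  s3 <- (c_next - c_mid) %% 8L
  paste0(s1, s2, s3)
}

sn_digits <- function(sn) {
  if (is.numeric(sn)) sn <- formatC(sn, width = 3, flag = "0")
  if (!all(grepl("^[0-7]{3}$", sn))) {
    abort("a shape number is three digits, each in 0..7",
          class = "shapelength_bad_shape_number")
  }
  matrix(as.integer(unlist(strsplit(sn, ""), use.names = FALSE)),
         ncol = 3, byrow = TRUE)
}

#' Canonical identifier of a shape number
#'
#' Two reordering steps map every coding of the same geometric segment
#' (either traversal direction, any rotation or mirror) to one identifier:
#' if the first digit exceeds 4, replace every digit `d` by `(8 - d) mod 8`;
#' then swap the last two digits when the second exceeds the third.  On
#' valid single-width segments the result is one of
#' `000, 017, 026, 107, 116, 206, 277, 367`.
#'
#' @param sn Character vector of three-digit shape numbers (or numbers).
#' @return Character vector of canonical identifiers.
#' @export
#' @examples
#' canonical_id(c("772", "727", "161"))  # all "116"
canonical_id <- function(sn) {
  d <- sn_digits(sn)
  flip <- d[, 1] > 4L
  d[flip, ] <- (8L - d[flip, , drop = FALSE]) %% 8L
  swap <- d[, 2] > d[, 3]
  tmp <- d[swap, 2]
  d[swap, 2] <- d[swap, 3]
  d[swap, 3] <- tmp
  paste0(d[, 1], d[, 2], d[, 3])
}

# ---------------------------------------------------------------------------
# geometric validity and class lookup table over all 512 code triples
# ---------------------------------------------------------------------------

triple_pixels <- function(cd) {
  cbind(
    x = cumsum(c(0L, code_dx[cd + 1L])),
    y = cumsum(c(0L, code_dy[cd + 1L]))
  )
}

triple_valid <- function(cd) {
  p <- triple_pixels(cd)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      d <- max(abs(p[i, ] - p[j, ]))
      if (j - i == 1L) {
        if (d != 1L) return(FALSE)
      } else if (d < 2L) {
        return(FALSE)
      }
    }
  }
  TRUE
}

class_from_canonical <- function(canon, c_mid) {
  cls <- rep(NA_integer_, length(canon))
  uniq <- canon_unique[canon]
  cls[!is.na(uniq)] <- uniq[!is.na(uniq)]
  pair <- canon_pairs[canon]
  hit <- !is.na(pair)
  cls[hit] <- pair[hit] + ifelse(c_mid[hit] %% 2L == 0L, 0L, 1L)
  cls
}

shape_tables <- function() {
  if (!is.null(the$class_lut)) {
    return(list(lut = the$class_lut, valid = the$valid_lut))
  }
  grid <- expand.grid(c3 = 0:7, c2 = 0:7, c1 = 0:7)[, 3:1]
  valid <- vapply(
    seq_len(nrow(grid)),
    function(i) triple_valid(as.integer(grid[i, ])),
    logical(1)
  )
  canon <- canonical_id(shape_number(grid$c1, grid$c2, grid$c3))
  lut <- rep(NA_integer_, 512L)
  key <- grid$c1 * 64L + grid$c2 * 8L + grid$c3 + 1L
  lut[key[valid]] <- class_from_canonical(canon[valid], grid$c2[valid])
  vlut <- logical(512L)
  vlut[key[valid]] <- TRUE
  the$class_lut <- lut
  the$valid_lut <- vlut
  list(lut = lut, valid = vlut)
}

#' Classify a 4-pixel segment into one of the twelve shapes
#'
#' Canonicalizes the segment's shape number and resolves the
#' `{k1,k2}`, `{k3,k4}`, `{k6,k7}`, `{k10,k11}` pairs by the parity of the
#' middle code (even = direct, odd = diagonal centre connection).  Segments
#' whose code triple cannot arise on a single-width path raise an
#' invalid-segment error.
#'
#' @inheritParams shape_number
#' @return Integer vector of class indices in 1..12.
#' @export
#' @examples
#' classify_segment(2, 3, 1)  # 8
classify_segment <- function(c_prev, c_mid, c_next) {
  if (is.data.frame(c_prev)) {
    seg <- c_prev
    c_prev <- seg$c_prev
    c_mid <- seg$c_mid
    c_next <- seg$c_next
  }
  c_prev <- as_chain_code(c_prev)
  c_mid <- as_chain_code(c_mid)
  c_next <- as_chain_code(c_next)
  lut <- shape_tables()$lut
  cls <- lut[c_prev * 64L + c_mid * 8L + c_next + 1L]
  if (anyNA(cls)) {
    at <- which(is.na(cls))[1]
    abort(
      paste0(
        "segment (", c_prev[at], ",", c_mid[at], ",", c_next[at],
        ") is not a single-width 4-pixel arrangement"
      ),
      class = "shapelength_invalid_segment",
      position = at
    )
  }
  cls
}

#' Tally shape-class occurrences along a chain code
#'
#' Counts how often each of the twelve shapes occurs among the rolling
#' segments `i = 2..n-1`, and records the head and tail boundary codes,
#' which carry uncorrected connection lengths in the length estimate.
#' The counts always sum to `max(n - 2, 0)`.
#'
#' @param codes Chain code (integer vector or digit string).
#' @return One-row tibble with columns `k1`..`k12`, `head_code`,
#'   `tail_code`, `n_codes`.
#' @export
shape_tally <- function(codes) {
  cc <- as_chain_code(codes)
  n <- length(cc)
  if (n < 1) abort("empty chain code", class = "shapelength_bad_code")
  counts <- integer(12L)
  if (n >= 3) {
    cls <- classify_segment(cc[1:(n - 2)], cc[2:(n - 1)], cc[3:n])
    counts <- tabulate(cls, nbins = 12L)
  }
  out <- as_tibble(as.list(stats::setNames(counts, shape_labels)))
  out$head_code <- cc[1]
  out$tail_code <- cc[n]
  out$n_codes <- n
  out
}

#' Enumerate all valid single-width 4-pixel segments
#'
#' Brute-forces the 512 directed code triples, keeps those whose four pixels
#' form a single-width arrangement (128 directed codings), and merges the
#' two traversal directions of each geometric segment by its translated
#' pixel set, yielding the 64 distinct segments.
#'
#' @return Tibble with one row per undirected segment: representative codes
#'   `c1`, `c2`, `c3`, both directed `codings`, the `canonical` identifier,
#'   `middle_parity`, and the shape `class` with its `label`.
#' @export
enumerate_valid_segments <- function() {
  grid <- expand.grid(c3 = 0:7, c2 = 0:7, c1 = 0:7)[, 3:1]
  keep <- vapply(
    seq_len(nrow(grid)),
    function(i) triple_valid(as.integer(grid[i, ])),
    logical(1)
  )
  grid <- grid[keep, ]

  pix_key <- vapply(seq_len(nrow(grid)), function(i) {
    p <- triple_pixels(as.integer(grid[i, ]))
    p[, 1] <- p[, 1] - min(p[, 1])
    p[, 2] <- p[, 2] - min(p[, 2])
    o <- order(p[, 1], p[, 2])
    paste(p[o, 1], p[o, 2], sep = ",", collapse = ";")
  }, character(1))

  coding <- paste0(grid$c1, grid$c2, grid$c3)
  canon <- canonical_id(shape_number(grid$c1, grid$c2, grid$c3))
  cls <- class_from_canonical(canon, grid$c2)

  first <- !duplicated(pix_key)
  codings <- split(coding, factor(pix_key, levels = pix_key[first]))
  out <- tibble(
    c1 = grid$c1[first],
    c2 = grid$c2[first],
    c3 = grid$c3[first],
    codings = unname(codings),
    canonical = canon[first],
    middle_parity = ifelse(grid$c2[first] %% 2L == 0L, "even", "odd"),
    class = cls[first],
    label = shape_labels[cls[first]]
  )
  dplyr::arrange(out, .data$class, .data$c1, .data$c2, .data$c3)
}

#' Partition the 64 segments into the twelve shape classes
#'
#' Groups the enumeration by canonical identifier and middle-code parity --
#' which coincides with grouping by geometric orbit under rotations, mirrors
#' and traversal reversal -- and reports class sizes and the centre
#' connection length of each class.
#'
#' @param segments Output of [enumerate_valid_segments()].
#' @return Tibble with 12 rows: `class`, `label`, `canonical`,
#'   `middle_parity`, `n_members`, `connection_length`.
#' @export
partition_into_classes <- function(segments = enumerate_valid_segments()) {
  known <- c(names(canon_unique), names(canon_pairs))
  if (!all(segments$canonical %in% known)) {
    abort("segment outside the twelve-shape taxonomy",
          class = "shapelength_taxonomy_violation")
  }
  out <- segments |>
    dplyr::group_by(.data$class, .data$label, .data$canonical, .data$middle_parity) |>
    dplyr::summarise(n_members = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$class)
  if (nrow(out) != 12L || sum(out$n_members) != 64L) {
    abort("segment outside the twelve-shape taxonomy",
          class = "shapelength_taxonomy_violation")
  }
  out$connection_length <- segment_lengths()[out$class]
  out
}

#' Centre connection lengths of the twelve shapes
#'
#' The middle two-pixel connection of a segment is direct (length 1 pixel)
#' for k1, k3, k6, k10 and diagonal (length `sqrt(2)`) for the rest.
#'
#' @return Named numeric vector `k1`..`k12`.
#' @export
segment_lengths <- function() {
  stats::setNames(
    ifelse(1:12 %in% c(1L, 3L, 6L, 10L), 1, sqrt(2)),
    shape_labels
  )
}

#' Per-sample chain features of skeleton backbones
#'
#' Computes, for each pixel path, the even/odd/corner code tallies, the
#' twelve shape-class counts and the head/tail boundary connection length
#' that enter the length estimators and the calibration system.
#'
#' @param paths A single path (matrix or data frame with `x`, `y`), a list
#'   of such paths, or a samples tibble from [simulate_skeletons()] /
#'   [generate_dataset()] (its `path` list-column is used, and `true_length`
#'   / `resolution` columns are carried through).
#' @return Tibble with one row per path: `n_codes`, `n_even`, `n_odd`,
#'   `n_corner`, `k1`..`k12`, `head_code`, `tail_code`, `boundary_length`.
#' @export
skeleton_features <- function(paths) {
  carry <- NULL
  if (is.data.frame(paths) && "path" %in% names(paths)) {
    carry <- paths[intersect(c("case", "l_c", "true_length", "resolution", "sample"),
                             names(paths))]
    paths <- paths$path
  } else if (!is.list(paths) || is.data.frame(paths)) {
    paths <- list(paths)
  }
  lut <- shape_tables()$lut
  rows <- lapply(paths, function(p) {
    cc <- trace_chain_code(p)
    n <- length(cc)
    counts <- integer(12L)
    if (n >= 3) {
      cls <- lut[cc[1:(n - 2)] * 64L + cc[2:(n - 1)] * 8L + cc[3:n] + 1L]
      if (anyNA(cls)) {
        abort("path contains a non-single-width segment",
              class = "shapelength_invalid_segment")
      }
      counts <- tabulate(cls, nbins = 12L)
    }
    step_len <- function(code) if (code %% 2L == 0L) 1 else sqrt(2)
    c(
      n_codes = n,
      n_even = sum(cc %% 2L == 0L),
      n_odd = sum(cc %% 2L == 1L),
      n_corner = if (n < 2) 0L else sum(diff(cc) != 0L),
      stats::setNames(counts, shape_labels),
      head_code = cc[1],
      tail_code = cc[n],
      boundary_length = step_len(cc[1]) + step_len(cc[n])
    )
  })
  out <- as_tibble(do.call(rbind, rows))
  if (!is.null(carry) && ncol(carry)) out <- dplyr::bind_cols(carry, out)
  out
}
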