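# Fixture generators and independent oracles used across the suite.

# Random valid single-width chain, independent of the WLC simulator: codes
# drift by -1/0/+1 (mod 8) and candidates are rejected until the resulting
# path is strictly single-width.
random_valid_chain <- function(n_codes, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    codes <- integer(n_codes)
    codes[1] <- sample(0:7, 1)
    if (n_codes > 1) {
      turns <- sample(c(-1L, 0L, 1L), n_codes - 1, replace = TRUE,
                      prob = c(0.15, 0.7, 0.15))
      codes <- (codes[1] + cumsum(c(0L, turns))) %% 8L
    }
    path <- follow_chain_code(codes)
    if (is_single_width(path)) return(codes)
  }
  stop("could not generate a valid chain")
}

# flood-fill component counter (8-connectivity), an oracle independent of
# the package's labelling code
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (r0 in seq_len(nrow(mask))) {
    for (c0 in seq_len(ncol(mask))) {
      if (!mask[r0, c0] || lab[r0, c0] > 0L) next
      n <- n + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- n
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr
          cc <- p[2] + dc
          if (rr < 1 || rr > nrow(mask) || cc < 1 || cc > ncol(mask)) next
          if (mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- n
            queue <- c(queue, list(c(rr, cc)))
          }
        }
      }
    }
  }
  n
}

# geometric transforms of a directed code triple, for orbit oracles
rotate_codes <- function(codes) (codes + 2L) %% 8L
mirror_codes <- function(codes) (-codes) %% 8L
reverse_codes <- function(codes) rev((codes + 4L) %% 8L)

# translated undirected pixel-set key of a code triple
triple_key <- function(codes) {
  p <- follow_chain_code(codes)
  x <- p$x - min(p$x)
  y <- p$y - min(p$y)
  o <- order(x, y)
  paste(x[o], y[o], sep = ",", collapse = ";")
}
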