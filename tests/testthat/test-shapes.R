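test_that("shape numbers follow the cyclic difference rule", {
  expect_identical(shape_number(0, 0, 0), "000")
  expect_identical(shape_number(2, 3, 1), "116")
  expect_identical(shape_number(0, 1, 0), "017")
  # negative differences wrap by the eight's complement
  expect_identical(shape_number(0, 7, 1), "772")
})

test_that("canonicalization maps all codings of a segment to one identifier", {
  # worked examples for the k8 family and the squeezed k12/k10 entries
  expect_identical(canonical_id(c("116", "772", "727", "161")),
                   rep("116", 4))
  expect_identical(canonical_id("512"), "367")
  expect_identical(canonical_id("611"), "277")
  expect_identical(canonical_id("602"), "206")
  expect_identical(canonical_id("026"), "026")

  # invariance of the canonical id under rotation, mirror and reversal,
  # checked by brute force over every valid directed coding
  segs <- enumerate_valid_segments()
  all_codings <- unlist(segs$codings)
  for (coding in all_codings) {
    cd <- as_chain_code(coding)
    base <- canonical_id(shape_number(cd[1], cd[2], cd[3]))
    for (tf in list(rotate_codes, mirror_codes, reverse_codes)) {
      tc <- tf(cd)
      expect_identical(canonical_id(shape_number(tc[1], tc[2], tc[3])), base)
    }
    # first canonical digit never exceeds 4
    expect_lte(as.integer(substr(base, 1, 1)), 4L)
  }
  expect_setequal(unique(segs$canonical),
                  c("000", "017", "026", "107", "116", "206", "277", "367"))
})

test_that("the 64 valid segments partition into the twelve classes", {
  segs <- enumerate_valid_segments()
  expect_identical(nrow(segs), 64L)
  # two directed codings merge into each undirected segment
  expect_identical(sort(lengths(segs$codings)), rep(2L, 64L))

  classes <- partition_into_classes(segs)
  expect_identical(nrow(classes), 12L)
  expect_identical(sum(classes$n_members), 64L)
  # straight segments: two direct (k1) and two diagonal (k2) orientations
  expect_identical(classes$n_members[classes$label == "k1"], 2L)
  expect_identical(classes$n_members[classes$label == "k2"], 2L)
  # the k8 family comprises eight segments
  expect_identical(classes$n_members[classes$label == "k8"], 8L)

  # grouping by canonical id + parity equals grouping by geometric orbit:
  # applying all dihedral transforms and reversal to a member never leaves
  # its (canonical, parity) group
  for (i in sample(nrow(segs), 16)) {
    cd <- c(segs$c1[i], segs$c2[i], segs$c3[i])
    variants <- list(cd)
    for (rot in 1:3) variants <- c(variants, list(rotate_codes(variants[[length(variants)]])))
    variants <- c(variants, lapply(variants, mirror_codes))
    variants <- c(variants, lapply(variants, reverse_codes))
    for (v in variants) {
      if (!is_single_width(follow_chain_code(v))) next
      expect_identical(classify_segment(v[1], v[2], v[3]), segs$class[i])
    }
  }

  # middle-code parity is constant within each orbit
  by_key <- vapply(seq_len(nrow(segs)), function(i) segs$middle_parity[i], "")
  expect_identical(length(unique(paste(segs$canonical, by_key))), 12L)
})

test_that("classification resolves paired classes by middle-code parity", {
  expect_identical(classify_segment(0, 0, 0), 1L)   # straight direct
  expect_identical(classify_segment(1, 1, 1), 2L)   # straight diagonal
  expect_identical(classify_segment(2, 3, 1), 8L)
  expect_identical(classify_segment(1, 2, 1), 3L)   # 017, middle even
  expect_identical(classify_segment(0, 1, 0), 4L)   # 017, middle odd

  # code triples that cannot occur on a single-width path are rejected,
  # including ones whose shape number canonicalizes to a known id
  expect_error(classify_segment(0, 4, 0), class = "shapelength_invalid_segment")
  expect_error(classify_segment(0, 2, 0), class = "shapelength_invalid_segment")

  # s1 = 4 never occurs among valid segments, so the complement rule's
  # strict threshold (s1 > 4) is never ambiguous
  segs <- enumerate_valid_segments()
  s1 <- vapply(unlist(segs$codings), function(cod) {
    cd <- as_chain_code(cod)
    (cd[1] - cd[3]) %% 8L
  }, integer(1))
  expect_false(any(s1 == 4L))
})

test_that("rolling segments slide over interior code positions", {
  segs <- rolling_segments(c(0, 0, 0, 0))
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$c_prev, c(0L, 0L))

  fig <- rolling_segments(as_chain_code("07107565"))
  expect_identical(nrow(fig), 6L)
  expect_identical(unlist(fig[1, c("c_prev", "c_mid", "c_next")], use.names = FALSE),
                   c(0L, 7L, 1L))
  expect_identical(unlist(fig[6, c("c_prev", "c_mid", "c_next")], use.names = FALSE),
                   c(5L, 6L, 5L))

  expect_identical(nrow(rolling_segments(c(0, 1, 2))), 1L)
  expect_error(rolling_segments(c(0, 1)), class = "shapelength_too_short")
})

test_that("shape tallies count interior segments and respect reversal", {
  t0 <- shape_tally(c(0, 0, 0, 0))
  expect_identical(t0$k1, 2L)
  expect_identical(sum(as.matrix(t0[paste0("k", 1:12)])), 2L)
  expect_identical(t0$head_code, 0L)
  expect_identical(t0$tail_code, 0L)

  # chains shorter than one full segment tally nothing
  t2 <- shape_tally(c(1, 2))
  expect_identical(sum(as.matrix(t2[paste0("k", 1:12)])), 0L)
  expect_identical(t2$head_code, 1L)

  set.seed(103)
  for (i in 1:20) {
    cc <- random_valid_chain(sample(5:80, 1))
    tt <- shape_tally(cc)
    # counts sum to n - 2
    expect_identical(sum(as.matrix(tt[paste0("k", 1:12)])), length(cc) - 2L)
    # reversal invariance of the counts vector
    tr <- shape_tally(reverse_chain_code(cc))
    expect_identical(as.matrix(tt[paste0("k", 1:12)]),
                     as.matrix(tr[paste0("k", 1:12)]))
  }
})
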