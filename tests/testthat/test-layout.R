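test_that("layout validation enforces the pericentric ordering", {
  mk <- c("a", "b", "c", "d")
  expect_error(
    chromosome_layout(mk, left_bp = list(interval = 2, fraction = 0.5),
                      centromere = list(interval = 1, fraction = 0.5),
                      right_bp = list(interval = 3, fraction = 0.5)),
    "strictly ordered")
  expect_error(
    chromosome_layout(mk, left_bp = list(interval = 1, fraction = 1.5),
                      centromere = list(interval = 2, fraction = 0.5),
                      right_bp = list(interval = 3, fraction = 0.5)),
    "fraction")
  expect_error(
    chromosome_layout(mk, left_bp = list(interval = 9, fraction = 0),
                      centromere = list(interval = 2, fraction = 0.5),
                      right_bp = list(interval = 3, fraction = 0.5)),
    "out of range")
  # homokaryotype needs no placements
  expect_s3_class(chromosome_layout(mk, karyotype = "homo"), "xoinv_layout")
})

test_that("decomposition splits intervals and conserves lengths", {
  # placements at interval boundaries: no splits
  d <- decompose_layout(boundary_layout())
  sizes <- vapply(d$chains, nrow, integer(1))
  expect_equal(unname(sizes), c(1L, 1L, 1L, 1L))
  expect_true(all(unlist(lapply(d$chains, `[[`, "share")) == 1))

  # centromere and right breakpoint inside one interval: triple split with
  # pieces going to inner-left, inner-right, outer-right
  lay <- chromosome_layout(c("a", "b", "c"), lengths = c(0.1, 0.3),
                           left_bp = list(interval = 1, fraction = 0),
                           centromere = list(interval = 2, fraction = 0.25),
                           right_bp = list(interval = 2, fraction = 0.75))
  d <- decompose_layout(lay)
  expect_equal(nrow(d$chains$outer_left), 0L)
  expect_equal(d$chains$inner_left$parent, c(1L, 2L))
  expect_equal(d$chains$inner_left$share, c(1, 0.25))
  expect_equal(d$chains$inner_right$share, 0.5)
  expect_equal(d$chains$outer_right$share, 0.25)

  # conservation: shares per parent interval sum to 1 for random layouts
  set.seed(5)
  for (r in 1:20) {
    f <- sort(runif(3))
    iv <- sort(sample(1:4, 3, replace = TRUE))
    lay <- try(chromosome_layout(letters[1:5],
                                 left_bp = list(interval = iv[1], fraction = f[1]),
                                 centromere = list(interval = iv[2], fraction = f[2]),
                                 right_bp = list(interval = iv[3], fraction = f[3])),
               silent = TRUE)
    if (inherits(lay, "try-error")) next   # degenerate equal positions
    d <- decompose_layout(lay)
    all_sub <- do.call(rbind, d$chains)
    tot <- as.numeric(tapply(all_sub$share, all_sub$parent, sum))
    expect_equal(tot, rep(1, length(tot)), tolerance = 1e-9)
  }
})

test_that("region chains start at their adjoining breakpoint", {
  # outer-left and inner-right run right-to-left in marker order
  lay <- chromosome_layout(letters[1:6],
                           left_bp = list(interval = 3, fraction = 0),
                           centromere = list(interval = 3, fraction = 0.5),
                           right_bp = list(interval = 4, fraction = 0))
  d <- decompose_layout(lay)
  expect_equal(d$chains$outer_left$parent, c(2L, 1L))
  expect_equal(d$chains$outer_right$parent, c(4L, 5L))
})

test_that("starting phase laws follow the three hypotheses", {
  expect_equal(start_phase(hypothesis_spec("H1", qc = 4), m = 4),
               c(0, 0, 0, 0, 1))
  expect_equal(start_phase(hypothesis_spec("H0", qc = 4), m = 4), rep(0.2, 5))
  om <- start_phase(hypothesis_spec("H2", qc = 4, qb = 2.5), m = 4)
  expect_equal(om, c(0, 0, 0.5, 0.5, 0))
  expect_equal(hypothesis_spec("H1", qc = 3.1)$qb, 3.1)
  expect_error(hypothesis_spec("H2", qc = 1), "requires")
})

test_that("gamete balance is the inner-region parity rule", {
  d <- decompose_layout(toy_layout())
  # subinterval order: OL(1), IL(2), IR(2), OR(1)
  expect_true(is_balanced(d, c(0, 0, 0, 0, 0, 0)))
  expect_false(is_balanced(d, c(0, 1, 0, 0, 0, 0)))  # single inner-left CO
  expect_true(is_balanced(d, c(0, 1, 0, 1, 0, 0)))   # one CO in each inner
  expect_true(is_balanced(d, c(1, 0, 0, 0, 0, 1)))   # outer COs are harmless
  expect_false(is_balanced(d, c(1, 1, 1, 0, 1, 1)))
  expect_error(is_balanced(d, c(1, 0)), "length")
})

test_that("map ratio flags negative-interference intervals", {
  expect_equal(map_ratio(0.1, 0.1), 1)
  expect_equal(map_ratio(0.245, 0.045), 5.4, tolerance = 0.01)
  expect_equal(map_ratio(0.373, 0.045), 8.3, tolerance = 0.01)
  expect_error(map_ratio(0.1, 0), "> 0")
})

test_that("subpattern probability factorises over regions", {
  lay <- toy_layout()
  d <- decompose_layout(lay)
  g0spec <- hypothesis_spec("H1", qc = 0)
  lens <- lay$lengths
  # gamma_0 = 1: product of Haldane terms over all subintervals
  sub_len <- unlist(lapply(d$chains, function(ch) ch$share * lens[ch$parent]))
  pat <- c(1, 0, 1, 0, 0, 1)
  expect_equal(subpattern_probability(d, g0spec, pat, lens),
               prod(ifelse(pat == 1, haldane(sub_len), 1 - haldane(sub_len))),
               tolerance = 1e-9)
  # all-zero pattern with zero lengths has probability one
  expect_equal(subpattern_probability(d, hypothesis_spec("H1", qc = 4),
                                      rep(0, 6), rep(0, 3)), 1)
})

test_that("marker-pattern distribution matches direct enumeration in the
           no-interference case", {
  lay <- toy_layout(c(0.25, 0.4, 0.15))
  spec0 <- hypothesis_spec("H1", qc = 0)
  pr <- marker_pattern_distribution(lay, spec0)
  d <- decompose_layout(lay)
  sub_len <- unlist(lapply(d$chains, function(ch) ch$share * lay$lengths[ch$parent]))
  parent <- unlist(lapply(d$chains, `[[`, "parent"))
  inner <- rep(c(0, 1, 2, 0), vapply(d$chains, nrow, integer(1)))
  ora <- oracle_haldane_conditioned(sub_len, parent, inner, 3)
  expect_equal(unname(pr), ora, tolerance = 1e-9)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("marker-pattern distributions normalise across hypotheses", {
  lay <- toy_layout()
  for (spec in list(hypothesis_spec("H0", qc = 4),
                    hypothesis_spec("H1", qc = 4),
                    hypothesis_spec("H2", qc = 4, qb = 1.3))) {
    pr <- marker_pattern_distribution(lay, spec)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
  hl <- chromosome_layout(c("a", "b", "c"), lengths = c(0.3, 0.2),
                          karyotype = "homo")
  expect_equal(sum(marker_pattern_distribution(hl, hypothesis_spec("H1", 4))),
               1, tolerance = 1e-12)
})

test_that("with zero-length inner regions the conditioning is vacuous", {
  lay <- chromosome_layout(c("a", "b", "c"), lengths = c(0.3, 0.25),
                           left_bp = list(interval = 2, fraction = 0.2),
                           centromere = list(interval = 2, fraction = 0.5),
                           right_bp = list(interval = 2, fraction = 0.8))
  # the middle interval (holding all three placements) gets length zero, so
  # both inner regions have zero genetic length and no gamete is unbalanced
  pr <- marker_pattern_distribution(lay, hypothesis_spec("H1", qc = 4),
                                    lengths = c(0.3, 0))
  d <- decompose_layout(lay)
  str <- xoinv:::combination_structure(d)
  joint <- xoinv:::joint_subpattern_distribution(d, hypothesis_spec("H1", 4),
                                                 c(0.3, 0))
  # fold WITHOUT the balance filter: must coincide with the package result
  uncond <- numeric(4)
  for (i in seq_along(joint)) {
    k <- str$marker_idx[i]
    uncond[k + 1] <- uncond[k + 1] + joint[i]
  }
  expect_equal(unname(pr), uncond / sum(uncond), tolerance = 1e-12)
})

test_that("breakpoint interference lowers the double-recombinant rate in the
           three-locus scenario", {
  # loci at the two breakpoints and the centromere, moderate inversion length
  lay <- chromosome_layout(c("A", "B", "C"), lengths = c(0.5, 0.5),
                           left_bp = list(interval = 1, fraction = 0),
                           centromere = list(interval = 2, fraction = 0),
                           right_bp = list(interval = 2, fraction = 1))
  pr_h1 <- marker_pattern_distribution(lay, hypothesis_spec("H1", qc = 4))
  pr_h0 <- marker_pattern_distribution(lay, hypothesis_spec("H0", qc = 4))
  expect_lt(pr_h1[["11"]], pr_h0[["11"]])
})
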