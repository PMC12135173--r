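#' Chromosome layout for an inversion karyotype
#'
#' Describes the marker map of a chromosome together with the placements of
#' the two inversion breakpoints and the centromere.  A placement is given as
#' the 1-based index of the marker interval containing it plus a fraction in
#' [0, 1] measured from the interval's left end; fractions apportion the
#' interval's genetic length among the resulting subintervals and are fixed
#' (not fitted).  For a pericentric inversion the order along the map must be
#' left breakpoint < centromere < right breakpoint.
#'
#' @param markers Character vector of n + 1 marker names (n intervals).
#' @param lengths Optional per-interval heterokaryotype genetic lengths
#'   (Morgans).  May be left \code{NULL} and supplied at evaluation time.
#' @param lengths_homo Optional per-interval homokaryotype lengths (Morgans).
#' @param left_bp,centromere,right_bp Placements, each
#'   \code{list(interval =, fraction =)}.  Required for karyotype
#'   \code{"hetero"}; ignored for \code{"homo"}.
#' @param karyotype \code{"hetero"} or \code{"homo"}.
#' @return Object of class \code{"xoinv_layout"}.
#' @export
chromosome_layout <- function(markers, lengths = NULL, lengths_homo = NULL,
                              left_bp = NULL, centromere = NULL,
                              right_bp = NULL,
                              karyotype = c("hetero", "homo")) {
  karyotype <- match.arg(karyotype)
  markers <- as.character(markers)
  n <- length(markers) - 1L
  if (n < 1L) stop("need at least two markers")
  chk_len <- function(l, what) {
    if (!is.null(l)) {
      if (length(l) != n) stop("'", what, "' must have one entry per interval")
      if (any(l < 0)) stop("'", what, "' has negative lengths")
    }
    l
  }
  lengths <- chk_len(lengths, "lengths")
  lengths_homo <- chk_len(lengths_homo, "lengths_homo")
  obj <- structure(list(markers = markers, n_intervals = n,
                        lengths = lengths, lengths_homo = lengths_homo,
                        karyotype = karyotype),
                   class = "xoinv_layout")
  if (karyotype == "hetero") {
    chk_place <- function(p, what) {
      if (is.null(p)) stop("heterokaryotype layout requires '", what, "'")
      iv <- as.integer(p$interval); fr <- as.numeric(p$fraction)
      if (is.na(iv) || iv < 1L || iv > n)
        stop("'", what, "': interval index out of range")
      if (is.na(fr) || fr < 0 || fr > 1)
        stop("'", what, "': fraction must be in [0, 1]")
      list(interval = iv, fraction = fr, pos = iv - 1L + fr)
    }
    obj$left_bp <- chk_place(left_bp, "left_bp")
    obj$centromere <- chk_place(centromere, "centromere")
    obj$right_bp <- chk_place(right_bp, "right_bp")
    ps <- c(obj$left_bp$pos, obj$centromere$pos, obj$right_bp$pos)
    if (!(ps[1] < ps[2] && ps[2] < ps[3]))
      stop("placements must be strictly ordered: left breakpoint < ",
           "centromere < right breakpoint (pericentric inversion)")
  }
  obj
}

#' @export
print.xoinv_layout <- function(x, ...) {
  cat("Chromosome layout (", x$karyotype, "karyotype ):",
      x$n_intervals, "intervals\n")
  cat("  markers:", paste(x$markers, collapse = " - "), "\n")
  if (!is.null(x$lengths))
    cat("  lengths (cM):", paste(round(100 * x$lengths, 2), collapse = ", "),
        "\n")
  if (x$karyotype == "hetero") {
    fmt <- function(p) sprintf("interval %d + %.3g", p$interval, p$fraction)
    cat("  left breakpoint at", fmt(x$left_bp),
        "| centromere at", fmt(x$centromere),
        "| right breakpoint at", fmt(x$right_bp), "\n")
  }
  invisible(x)
}

#' Decompose a heterokaryotype layout into the four independent regions
#'
#' The centromere blocks the interference signal and recombination is
#' evaluated independently in the four regions delimited by the two
#' breakpoints and the centromere: outer-left (left of the left breakpoint),
#' inner-left (left breakpoint to centromere), inner-right (right breakpoint
#' back to the centromere) and outer-right (right of the right breakpoint).
#' Each region is an ordered chain of subintervals starting from the
#' adjoining breakpoint, so the outer-left and inner-right chains run
#' right-to-left relative to the marker order.  A homokaryotype layout yields
#' a single chain covering all intervals in marker order.
#'
#' @param layout A [chromosome_layout()].
#' @return Object of class \code{"xoinv_decomp"}: a list of region chains
#'   (\code{outer_left}, \code{inner_left}, \code{inner_right},
#'   \code{outer_right}, or just \code{chain} for a homokaryotype), each a
#'   data frame with columns \code{parent} (marker-interval index) and
#'   \code{share} (fraction of that interval's genetic length).
#' @export
decompose_layout <- function(layout) {
  stopifnot(inherits(layout, "xoinv_layout"))
  n <- layout$n_intervals
  if (layout$karyotype == "homo") {
    chains <- list(chain = data.frame(parent = seq_len(n), share = 1))
    return(structure(list(chains = chains, n_intervals = n, karyotype = "homo"),
                     class = "xoinv_decomp"))
  }
  cuts <- c(layout$left_bp$pos, layout$centromere$pos, layout$right_bp$pos)
  bounds <- sort(unique(c(0:n, cuts)))
  segs <- data.frame(from = bounds[-length(bounds)], to = bounds[-1L])
  segs <- segs[segs$to - segs$from > 1e-12, , drop = FALSE]  # drop null cuts
  mid <- (segs$from + segs$to) / 2
  segs$parent <- pmin(floor(segs$from + 1e-9) + 1L, n)
  segs$share <- segs$to - segs$from
  region <- ifelse(mid < cuts[1], "outer_left",
            ifelse(mid < cuts[2], "inner_left",
            ifelse(mid < cuts[3], "inner_right", "outer_right")))
  take <- function(name, reverse) {
    d <- segs[region == name, c("parent", "share"), drop = FALSE]
    if (reverse) d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  chains <- list(outer_left  = take("outer_left",  TRUE),
                 inner_left  = take("inner_left",  FALSE),
                 inner_right = take("inner_right", TRUE),
                 outer_right = take("outer_right", FALSE))
  structure(list(chains = chains, n_intervals = n, karyotype = "hetero"),
            class = "xoinv_decomp")
}

#' Hypothesis on breakpoint-chiasma interference
#'
#' The three competing hypotheses about the phase distribution \eqn{\Omega}
#' imposed at an inversion breakpoint: under H0 breakpoints block but do not
#' cause interference (\eqn{\Omega = \pi}, the stationary phase law); under
#' H1 breakpoints interfere exactly like chiasmata (\eqn{\Omega = \gamma});
#' under H2 the breakpoint interference has its own strength \code{qb}
#' (\eqn{\Omega} is the gamma-model law built from \code{qb}).
#'
#' @param name \code{"H0"}, \code{"H1"} or \code{"H2"}.
#' @param qc Chiasma-chiasma interference strength (>= 0).
#' @param qb Breakpoint-chiasma strength; required for H2, forced equal to
#'   \code{qc} for H1, unused for H0.
#' @return Object of class \code{"xoinv_hypothesis"}.
#' @export
hypothesis_spec <- function(name = c("H0", "H1", "H2"), qc, qb = NULL) {
  name <- match.arg(name)
  if (qc < 0) stop("'qc' must be >= 0")
  if (name == "H2") {
    if (is.null(qb)) stop("H2 requires 'qb'")
    if (qb < 0) stop("'qb' must be >= 0")
  } else if (name == "H1") {
    qb <- qc
  } else {
    qb <- NULL
  }
  structure(list(name = name, qc = qc, qb = qb), class = "xoinv_hypothesis")
}

## internal: phase-vector length needed to hold both gamma and omega supports
required_m <- function(spec) {
  qs <- c(spec$qc, spec$qb)
  max(floor(max(qs)) + 1L, 1L)
}

#' Starting phase distribution at a breakpoint under a hypothesis
#'
#' @param spec A [hypothesis_spec()].
#' @param m Maximum phase (vector indexed 0..m).  Defaults to the smallest
#'   value holding the supports implied by the hypothesis.
#' @return Numeric probability vector \eqn{\Omega} of length \code{m + 1}.
#' @export
start_phase <- function(spec, m = NULL) {
  stopifnot(inherits(spec, "xoinv_hypothesis"))
  if (is.null(m)) m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  switch(spec$name,
         H0 = stationary_phase(gam),
         H1 = as.numeric(gam),
         H2 = as.numeric(gamma_from_strength(spec$qb, m)))
}

#' Gamete balance from a full subinterval recombination pattern
#'
#' A gamete of a pericentric inversion heterokaryotype is unbalanced (and the
#' resulting zygote inviable) if and only if it is recombinant in exactly one
#' of the two inner regions; equivalently, balanced iff the crossover
#' parities of the inner-left and inner-right chains agree.
#'
#' @param decomp A heterokaryotype [decompose_layout()] result.
#' @param subpattern Binary vector over all subintervals, ordered as the
#'   concatenation outer-left, inner-left, inner-right, outer-right of the
#'   region chains.
#' @return \code{TRUE} if the gamete is balanced.
#' @export
is_balanced <- function(decomp, subpattern) {
  stopifnot(inherits(decomp, "xoinv_decomp"), decomp$karyotype == "hetero")
  sizes <- vapply(decomp$chains, nrow, integer(1))
  if (length(subpattern) != sum(sizes))
    stop("subpattern length does not match the subinterval count")
  off <- cumsum(c(0L, sizes))
  par_il <- sum(subpattern[seq_len(sizes[2L]) + off[2L]]) %% 2L
  par_ir <- sum(subpattern[seq_len(sizes[3L]) + off[3L]]) %% 2L
  par_il == par_ir
}

## internal: per-subinterval lengths (Morgans) for each chain, given the
## per-marker-interval lengths
chain_lengths <- function(decomp, lengths) {
  lapply(decomp$chains, function(d) d$share * lengths[d$parent])
}

#' Probability of a full subinterval recombination pattern
#'
#' Product over the four independent regions of the chain pattern
#' probability, each chain starting at its adjoining breakpoint with phase
#' law \eqn{\Omega} set by the hypothesis.
#'
#' @param decomp A heterokaryotype [decompose_layout()] result.
#' @param spec A [hypothesis_spec()].
#' @param subpattern Binary vector over all subintervals (region order as in
#'   [is_balanced()]).
#' @param lengths Per-marker-interval heterokaryotype lengths (Morgans).
#' @param tol Truncation tolerance.
#' @return Unconditioned probability of the subpattern.
#' @export
subpattern_probability <- function(decomp, spec, subpattern, lengths,
                                   tol = 1e-12) {
  stopifnot(inherits(decomp, "xoinv_decomp"), decomp$karyotype == "hetero")
  sizes <- vapply(decomp$chains, nrow, integer(1))
  if (length(subpattern) != sum(sizes))
    stop("subpattern length does not match the subinterval count")
  m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  omega <- start_phase(spec, m)
  lens <- chain_lengths(decomp, lengths)
  off <- cumsum(c(0L, sizes))
  pr <- 1
  for (r in seq_along(decomp$chains)) {
    pat <- subpattern[seq_len(sizes[r]) + off[r]]
    lam <- interval_rate(lens[[r]], gam)
    pr <- pr * pattern_probability(omega, lam, pat, gam, tol)
  }
  pr
}

## internal: static combination structure for a decomposition -- for every
## joint subinterval pattern, the marker pattern it induces (XOR of the bits
## of subintervals sharing a parent interval) and whether it is balanced.
## Joint pattern index: region chains concatenated outer-left, inner-left,
## inner-right, outer-right; subinterval p (1-based within the concatenation)
## carries bit value 2^(p-1).
combination_structure <- function(decomp) {
  sizes <- vapply(decomp$chains, nrow, integer(1))
  S <- sum(sizes)
  if (S > 24L) stop("subinterval count > 24: refusing to enumerate")
  parents <- unlist(lapply(decomp$chains, `[[`, "parent"), use.names = FALSE)
  idx <- 0:(2^S - 1L)
  bits <- matrix(0L, length(idx), S)
  for (p in seq_len(S)) bits[, p] <- bitwAnd(bitwShiftR(idx, p - 1L), 1L)
  n <- decomp$n_intervals
  marker_idx <- integer(length(idx))
  for (k in seq_len(n)) {
    cols <- which(parents == k)
    if (length(cols))
      marker_idx <- marker_idx +
        (as.integer(rowSums(bits[, cols, drop = FALSE])) %% 2L) *
        2L^(k - 1L)
  }
  off <- cumsum(c(0L, sizes))
  par_of <- function(r) {
    if (sizes[r] == 0L) return(integer(length(idx)))
    as.integer(rowSums(bits[, off[r] + seq_len(sizes[r]), drop = FALSE])) %% 2L
  }
  balanced <- par_of(2L) == par_of(3L)
  list(sizes = sizes, marker_idx = marker_idx, balanced = balanced)
}

## internal: joint probability vector over all 2^S subinterval patterns,
## ordered as in combination_structure (region 1 = lowest bits)
joint_subpattern_distribution <- function(decomp, spec, lengths,
                                          tol = 1e-12) {
  m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  omega <- start_phase(spec, m)
  lens <- chain_lengths(decomp, lengths)
  vs <- lapply(lens, function(l)
    chain_pattern_distribution(omega, interval_rate(l, gam), gam, tol))
  ## kronecker(B, A) indexes A fastest; fold so the first chain varies fastest
  Reduce(function(acc, v) kronecker(v, acc), vs[-1L], vs[[1L]])
}

## internal: static evaluation context for repeated likelihood evaluations on
## one layout -- region chains as plain vectors plus the precomputed
## combination structure (hetero) and cached pattern names
eval_context <- function(layout) {
  decomp <- decompose_layout(layout)
  chains <- lapply(decomp$chains, function(d)
    list(parent = d$parent, share = d$share))
  str <- NULL
  agg <- NULL
  if (layout$karyotype == "hetero") {
    str <- combination_structure(decomp)
    ## 0/1 matrix folding the balanced joint subpatterns onto marker patterns
    midx <- str$marker_idx[str$balanced]
    agg <- matrix(0, length(midx), 2^layout$n_intervals)
    agg[cbind(seq_along(midx), midx + 1L)] <- 1
  }
  list(karyotype = layout$karyotype, n = layout$n_intervals,
       chains = chains, str = str, agg = agg,
       pat_names = pattern_strings(layout$n_intervals))
}

## internal: viable-conditioned marker-pattern distribution (unnamed), the
## hot path behind marker_pattern_distribution / log_likelihood / fitting.
## The per-region chain distributions come from the compiled kernel (the R
## reference path, chain_pattern_distribution, is cross-checked against it in
## the test suite).
pattern_dist_ctx <- function(ctx, spec, lengths, tol = 1e-12) {
  m <- required_m(spec)
  gam <- gamma_from_strength(spec$qc, m)
  if (ctx$karyotype == "homo") {
    omega <- stationary_phase(gam)
    lam <- list(interval_rate(ctx$chains$chain$share *
                                lengths[ctx$chains$chain$parent], gam))
    return(.chain_distributions_cpp(lam, gam, omega, tol)[[1L]])
  }
  omega <- start_phase(spec, m)
  lam <- lapply(ctx$chains, function(ch)
    interval_rate(ch$share * lengths[ch$parent], gam))
  vs <- .chain_distributions_cpp(lam, gam, omega, tol)
  joint <- Reduce(function(acc, v) kronecker(v, acc), vs[-1L], vs[[1L]])
  pr <- drop(crossprod(ctx$agg, joint[ctx$str$balanced]))
  pr / sum(pr)
}

#' Distribution of observable marker recombination patterns
#'
#' For a heterokaryotype, enumerates all subinterval patterns across the four
#' independent regions, keeps only those producing balanced (viable) gametes,
#' folds subinterval bits into marker-interval bits by XOR, and renormalises:
#' the result is the distribution of marker patterns among surviving
#' offspring.  For a homokaryotype, returns the unconditioned chain
#' distribution with the stationary starting phase \eqn{\pi}.
#'
#' @param layout A [chromosome_layout()].
#' @param spec A [hypothesis_spec()].
#' @param lengths Per-interval lengths (Morgans); defaults to
#'   \code{layout$lengths}.
#' @param tol Truncation tolerance.
#' @return Named numeric vector over all \eqn{2^n} marker patterns; names are
#'   binary strings with character k (left to right) the recombination bit of
#'   interval k.  Sums to 1.
#' @export
marker_pattern_distribution <- function(layout, spec, lengths = NULL,
                                        tol = 1e-12) {
  stopifnot(inherits(layout, "xoinv_layout"))
  if (is.null(lengths)) lengths <- layout$lengths
  if (is.null(lengths)) stop("no interval lengths available")
  ctx <- eval_context(layout)
  pr <- pattern_dist_ctx(ctx, spec, lengths, tol)
  names(pr) <- ctx$pat_names
  pr
}

## internal: canonical pattern names; index idx (0-based) -> binary string
## whose k-th character is bit 2^(k-1)
pattern_strings <- function(n) {
  idx <- 0:(2^n - 1L)
  vapply(idx, function(i)
    paste(bitwAnd(bitwShiftR(i, 0:(n - 1L)), 1L), collapse = ""),
    character(1))
}

#' Heterokaryotype-to-homokaryotype map ratio
#'
#' \eqn{d_k = l'_k / l_k}: values below 1 indicate chiasma suppression not
#' attributable to breakpoint interference (e.g. imperfect synapsis); values
#' above 1 indicate negative interference, seen in intervals holding both a
#' breakpoint and the centromere.
#'
#' @param l_prime Heterokaryotype length (Morgans).
#' @param l_homo Homokaryotype length (Morgans), > 0.
#' @return The ratio \eqn{d_k}.
#' @export
map_ratio <- function(l_prime, l_homo) {
  if (any(l_homo <= 0)) stop("homokaryotype length must be > 0")
  l_prime / l_homo
}
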