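# Length-corrected Gestalt similarity between pathway strings.
#
# The raw score for pathways A and B is
#
#     similarity_AB = 2 * LCS / (L_A + L_B)
#
# where LCS is the length of the longest common subsequence.  When pathway
# lengths differ greatly, the raw score is dominated by the lengths, so the
# corrected form subtracts half the length difference from the denominator:
#
#     similarity_AB = 2 * LCS / (L_A + L_B - |L_A - L_B| / 2)

#' Longest common subsequence length
#'
#' Length of the longest (not necessarily contiguous) common subsequence of
#' two pathway strings.  Total function: either argument may be empty, giving
#' zero.
#'
#' @param a,b Pathway strings: `path_string`/`pathway` objects, integer
#'   state-id vectors, or display-alphabet strings.
#' @return Integer, between 0 and `min(length(a), length(b))`.
#' @examples
#' lcs_length("ABCDEFGHIJ", "ABCDEFGHIXY")  # 9
#' @export
lcs_length <- function(a, b) lcs_length_cpp(as_symbols(a), as_symbols(b))

#' Gestalt similarity of two pathway strings
#'
#' Computes `2*LCS/(L_A + L_B)` or, with `corrected = TRUE` (default), the
#' length-corrected variant `2*LCS/(L_A + L_B - |L_A - L_B|/2)`, which
#' penalises large length mismatches less than the raw score does and keeps
#' the ranking driven by the common subsequence.  The maximum value of one is
#' attained exactly for identical strings.
#'
#' @inheritParams lcs_length
#' @param corrected Apply the length correction (default `TRUE`).
#' @param method `"lcs"` (default) scores with the true longest common
#'   subsequence; `"matching-blocks"` uses the classical Ratcliff-Obershelp
#'   recursive matching-blocks count instead.
#' @return A `similarity_score` object: a list with `value`, `lcs_length`
#'   (the matched-symbol count under the chosen method) and `corrected`.
#' @examples
#' gestalt_similarity("ABCDEFGHIJ", "ABCDEFGHIXY")$value  # 18/20.5 ~ 0.88
#' @export
gestalt_similarity <- function(a, b, corrected = TRUE,
                               method = c("lcs", "matching-blocks")) {
  method <- match.arg(method)
  sa <- as_symbols(a); sb <- as_symbols(b)
  if (length(sa) == 0 && length(sb) == 0)
    stop("invalid pathways: both strings are empty")
  m <- if (method == "lcs") lcs_length_cpp(sa, sb) else
    matching_blocks_cpp(sa, sb)
  la <- length(sa); lb <- length(sb)
  denom <- la + lb - if (corrected) abs(la - lb) / 2 else 0
  structure(list(value = 2 * m / denom, lcs_length = m,
                 corrected = corrected, method = method),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> %.2f (matched %d symbols, %s, %s)\n",
              x$value, x$lcs_length, x$method,
              if (x$corrected) "corrected" else "uncorrected"))
  invisible(x)
}

# Bare-number similarity used in the pairwise loop.
.similarity_value <- function(sa, sb, corrected, method) {
  m <- if (method == "lcs") lcs_length_cpp(sa, sb) else
    matching_blocks_cpp(sa, sb)
  2 * m / (length(sa) + length(sb) -
             if (corrected) abs(length(sa) - length(sb)) / 2 else 0)
}

#' Condense repeated patterns in a pathway string
#'
#' Sequentially eliminates immediate repetitions of blocks of length
#' `1..max_block` (smallest block size first, each to a fixed point; the
#' sweep over block sizes is repeated until the whole string is a fixed
#' point).  For example `"11221112221122"` condenses at level 1 to
#' `"121212"` and at level 2 further to `"12"`, leaving the fundamental
#' sequence of states with dwell times disregarded.
#'
#' @param s Pathway string (`path_string`, `pathway`, integer vector, or
#'   display string).
#' @param max_block Largest repeating-block length to collapse (>= 1).
#' @return Same representation as the input (`pathway` objects keep their
#'   metadata; display strings come back as strings).
#' @examples
#' condense("11221112221122", 1)  # "121212"
#' condense("11221112221122", 2)  # "12"
#' @export
condense <- function(s, max_block) {
  if (!is.numeric(max_block) || length(max_block) != 1 || max_block < 1)
    stop("max_block must be an integer >= 1")
  max_block <- as.integer(max_block)
  x <- as_symbols(s)
  repeat {
    before <- x
    for (k in seq_len(max_block)) x <- .condense_block(x, k)
    if (identical(x, before)) break
  }
  if (inherits(s, "pathway")) { s$symbols <- x; return(s) }
  if (inherits(s, "path_string")) return(path_string(x))
  if (is.character(s)) return(encode_symbols(x))
  x
}

# Collapse immediate repeats of k-length blocks, left-to-right, restarting
# the scan at the collapse position, until none remain.
.condense_block <- function(x, k) {
  i <- 1L
  while (i + 2L * k - 1L <= length(x)) {
    if (all(x[i:(i + k - 1L)] == x[(i + k):(i + 2L * k - 1L)])) {
      x <- x[-(i:(i + k - 1L))]
      i <- max(1L, i)  # rescan from the collapse position
    } else {
      i <- i + 1L
    }
  }
  x
}

#' Pairwise pathway distance matrix
#'
#' Scores every pathway pair and compiles the distances
#' `d = 1 - similarity` into a symmetric matrix ready for
#' [ward_linkage()].  Condensation, when requested, affects matching only:
#' the input pathways themselves are not modified.
#'
#' @param pathways List of at least two pathways (any representation
#'   accepted by [lcs_length()]).
#' @param corrected Use the length-corrected score (default `TRUE`).
#' @param condense_level If non-`NULL`/non-zero, apply [condense()] with this
#'   `max_block` to every string before scoring.
#' @param metric_hook Optional user similarity function taking two integer
#'   symbol vectors and returning a number in `[0, 1]`; replaces the Gestalt
#'   score.  A return value outside `[0, 1]` is a contract violation and an
#'   error.
#' @param method Matching method passed to the built-in score; see
#'   [gestalt_similarity()].
#' @return An `n x n` numeric matrix with zero diagonal, symmetric, entries
#'   in `[0, 1]`.
#' @export
pairwise_distances <- function(pathways, corrected = TRUE,
                               condense_level = NULL, metric_hook = NULL,
                               method = c("lcs", "matching-blocks")) {
  method <- match.arg(method)
  n <- length(pathways)
  if (n < 2) stop("need at least two pathways")
  syms <- lapply(pathways, as_symbols)
  if (any(vapply(syms, length, 0L) == 0))
    stop("invalid pathway: empty string")
  if (!is.null(condense_level) && condense_level >= 1)
    syms <- lapply(syms, condense, max_block = condense_level)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- if (is.null(metric_hook)) {
        .similarity_value(syms[[i]], syms[[j]], corrected, method)
      } else {
        v <- metric_hook(syms[[i]], syms[[j]])
        if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
          stop("metric-contract violation: hook must return a number in [0,1]")
        v
      }
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    p <- pathways[[i]]
    if (inherits(p, "pathway") && !is.na(p$id)) as.character(p$id)
    else as.character(i)
  }, "")
  dimnames(d) <- list(ids, ids)
  d
}
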