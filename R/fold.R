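# Hairpin folding by base-pair maximization (Watson-Crick + G:U) over nested
# structures with a minimum loop, computed by an exact dynamic program in
# compiled code. Deliberately not thermodynamic: the maximization is
# deterministic under the documented tie-breaking rule and can be verified
# against an exhaustive recursion, which is what duplex verification needs.
# A thermodynamic folder can be substituted upstream if desired.

#' Fold a sequence into its maximum-pairing nested structure
#'
#' Returns a maximum-cardinality set of nested base pairs (Watson-Crick or
#' G:U; no pseudoknots) with hairpin loops of at least `min_loop` unpaired
#' bases. Tie-breaking is deterministic: whenever the optimum can be reached
#' by pairing the leftmost undecided position, it is paired, with the
#' smallest admissible partner.
#'
#' @param sequence a single DNA/RNA string (U is normalised to T).
#' @param min_loop minimum hairpin loop length (default 3).
#' @param min_length sequences shorter than this yield a rejection result
#'   (`ok = FALSE`) rather than a structure (default 40; set lower to fold
#'   short fixtures).
#' @return object of class `hairpin`: list with `ok`, `sequence`, `pairs`
#'   (two-column matrix of 1-based positions, i < j), `n_pairs`,
#'   `dot_bracket`, and `loop`/`arms` (the innermost loop of the largest
#'   stem and the paired ranges flanking it), or `ok = FALSE` with a
#'   `reason`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L, min_length = 40L) {
  sequence <- normalize_seq(sequence)
  stopifnot(length(sequence) == 1)
  n <- nchar(sequence)
  if (n < min_length) {
    return(structure(list(ok = FALSE, reason = "too_short",
                          sequence = sequence, n_pairs = 0L),
                     class = "hairpin"))
  }
  res <- .nussinov_fold(sequence, as.integer(min_loop))
  pairs <- cbind(i = res$i, j = res$j)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  db <- rep(".", n)
  db[pairs[, 1]] <- "("
  db[pairs[, 2]] <- ")"
  stem <- dominant_stem(pairs)
  structure(list(ok = TRUE, sequence = sequence, pairs = pairs,
                 n_pairs = nrow(pairs),
                 dot_bracket = paste(db, collapse = ""),
                 loop = stem$loop, arms = stem$arms),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  if (!x$ok) {
    cat("<hairpin> rejected:", x$reason, "\n")
    return(invisible(x))
  }
  cat("<hairpin>", nchar(x$sequence), "nt,", x$n_pairs, "pairs\n")
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

# The stem owning the innermost pair of the largest chain of nested pairs;
# returns its loop interval and the two arm ranges.
dominant_stem <- function(pairs) {
  if (nrow(pairs) == 0) return(list(loop = NULL, arms = NULL))
  # innermost pairs: no other pair strictly inside
  np <- nrow(pairs)
  depth <- integer(np)
  for (k in seq_len(np)) {
    depth[k] <- sum(pairs[, 1] < pairs[k, 1] & pairs[, 2] > pairs[k, 2])
  }
  inner <- which(vapply(seq_len(np), function(k)
    !any(pairs[, 1] > pairs[k, 1] & pairs[, 2] < pairs[k, 2]),
    logical(1)))
  k <- inner[which.max(depth[inner])]
  chain <- which(pairs[, 1] <= pairs[k, 1] & pairs[, 2] >= pairs[k, 2])
  list(loop = c(pairs[k, 1] + 1L, pairs[k, 2] - 1L),
       arms = list(`5p` = range(pairs[chain, 1]),
                   `3p` = range(pairs[chain, 2])))
}
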