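#' Signed feed-forward-loop motif analysis
#'
#' A feed-forward loop (FFL) is an ordered node triple (input a,
#' intermediate b, output c) with the three edges a->b, b->c and a->c all
#' present.  The loop is incoherent — and thereby capable of adaptation to
#' a sustained input, returning the output towards baseline after a
#' transient — when the sign of the direct edge differs from the product of
#' the two indirect edge signs.
#'
#' @name motif_analysis
NULL

#' Enumerate signed feed-forward loops
#'
#' @param edges signed sparse matrix with `edges[i, j]` the influence of
#'   source j on target i (e.g. a thresholded K); nonzero entries are
#'   edges.
#' @param restrict_to optional node-label subset (e.g. one organ's nodes);
#'   all three motif nodes must belong to it.
#' @return data.frame (input, intermediate, output, s_in, s_out, s_direct,
#'   class, adaptation_capable) with signs in {-1, 1} and class in
#'   {"coherent", "incoherent"}.
#' @export
enumerate_ffl <- function(edges, restrict_to = NULL) {
  nodes <- rownames(edges)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(edges)))
  keep <- if (is.null(restrict_to)) seq_along(nodes) else
    which(nodes %in% restrict_to)
  A <- edges[keep, keep, drop = FALSE]  # A[target, source]
  labs <- nodes[keep]
  n <- length(labs)
  rows <- list(); r <- 0L
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b == a || A[b, a] == 0) next
    for (cc in seq_len(n)) {
      if (cc == a || cc == b) next
      if (A[cc, b] != 0 && A[cc, a] != 0) {
        s_in <- sign(A[b, a]); s_out <- sign(A[cc, b])
        s_direct <- sign(A[cc, a])
        incoherent <- s_direct != s_in * s_out
        r <- r + 1L
        rows[[r]] <- data.frame(
          input = labs[a], intermediate = labs[b], output = labs[cc],
          s_in = s_in, s_out = s_out, s_direct = s_direct,
          class = if (incoherent) "incoherent" else "coherent",
          adaptation_capable = incoherent
        )
      }
    }
  }
  out <- if (r == 0) {
    data.frame(input = character(), intermediate = character(),
               output = character(), s_in = numeric(), s_out = numeric(),
               s_direct = numeric(), class = character(),
               adaptation_capable = logical())
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Adaptation capability of one feed-forward loop
#'
#' @param s_in,s_out,s_direct nonzero edge signs of the indirect input ->
#'   intermediate, intermediate -> output and direct input -> output edges.
#' @return TRUE when the loop is incoherent (adaptation capable).
#' @export
classify_adaptation <- function(s_in, s_out, s_direct) {
  stopifnot(all(c(s_in, s_out, s_direct) != 0))
  sign(s_direct) != sign(s_in) * sign(s_out)
}
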