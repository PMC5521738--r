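#' Differential (disease vs control) network analysis
#'
#' The strongest connections of each strain-specific network are kept
#' (|E| > med(E) + 2 sd(E)), scaled to (-1, 1) by the maximum absolute
#' edge, and every edge is tested for one of three mutually exclusive
#' rewiring classes — added (present only in disease), removed (present
#' only in control) or switched in sign — subject to the unscaled
#' edge-difference threshold E_th = max(2 sd(K_control), 2 sd(K_disease))
#' and class-specific |dE| cutoffs.
#'
#' @name differential_network
NULL

#' Threshold a network to its strong edges and scale to (-1, 1)
#'
#' @param K coefficient matrix.
#' @return list with `scaled` (entries below the strength threshold set to
#'   zero, survivors divided by max |K|), `threshold` and `max_abs`.
#' @export
threshold_and_scale <- function(K) {
  stopifnot(length(K) > 0)
  thr <- stats::median(K) + 2 * stats::sd(K)
  keep <- abs(K) > thr
  max_abs <- max(abs(K))
  scaled <- K / if (max_abs > 0) max_abs else 1
  scaled[!keep] <- 0
  list(scaled = scaled, threshold = thr, max_abs = max_abs)
}

#' Call added, removed and switched edges between strains
#'
#' @param K_disease,K_control coefficient matrices over matched nodes.
#' @param cutoffs named vector of class-specific |dE| cutoffs applied to the
#'   unscaled edge difference dE = E_disease - E_control.
#' @return data.frame (source, target, class, e_disease, e_control,
#'   delta_e) of class `"edge_changes"`; zero rows when the networks agree.
#' @export
differential_edges <- function(K_disease, K_control,
                               cutoffs = c(added = 0.15, removed = 0.15,
                                           switched = 0.2)) {
  stopifnot(identical(dim(K_disease), dim(K_control)))
  sc_d <- threshold_and_scale(K_disease)$scaled
  sc_c <- threshold_and_scale(K_control)$scaled
  e_th <- max(2 * stats::sd(K_control), 2 * stats::sd(K_disease))
  delta <- K_disease - K_control

  added <- abs(sc_d) > 0 & abs(sc_c) == 0 & abs(delta) > e_th &
    abs(delta) > cutoffs[["added"]]
  removed <- abs(sc_d) == 0 & abs(sc_c) > 0 & abs(delta) > e_th &
    abs(delta) > cutoffs[["removed"]]
  switched <- abs(sc_d) > 0 & abs(sc_c) > 0 &
    sign(sc_d) != sign(sc_c) & abs(delta) > e_th &
    abs(delta) > cutoffs[["switched"]]

  nodes <- rownames(K_disease)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(K_disease)))
  collect <- function(mask, cl) {
    ii <- which(mask)
    if (length(ii) == 0) return(NULL)
    data.frame(source = nodes[col(K_disease)[ii]],
               target = nodes[row(K_disease)[ii]], class = cl,
               e_disease = K_disease[ii], e_control = K_control[ii],
               delta_e = delta[ii])
  }
  out <- rbind(collect(added, "added"), collect(removed, "removed"),
               collect(switched, "switched"))
  if (is.null(out)) {
    out <- data.frame(source = character(), target = character(),
                      class = character(), e_disease = numeric(),
                      e_control = numeric(), delta_e = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("edge_changes", "data.frame")
  out
}

#' Export edges in SIF format
#'
#' One line per edge: `source <relation> target`, the plain-text network
#' interchange format read by Cytoscape.
#'
#' @param edges data.frame with `source`, `target` and a relation column.
#' @param path output file.
#' @param relation name of the relation column (default `class`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, relation = "class") {
  lines <- paste(edges$source, edges[[relation]], edges$target)
  writeLines(lines, path)
  invisible(path)
}
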