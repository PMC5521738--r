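#' Synthetic multi-organ qPCR study generator
#'
#' Emulates the structure of a two-strain (disease vs control) rat qPCR
#' time-course: a sparse stable linear network K drives expression dynamics
#' dE/dt = K E across (organ, gene) nodes; trajectories sampled at a handful
#' of ages are converted to replicate Ct measurements with Gaussian noise,
#' per-gene offsets, designated dropped organ/age cells and sporadic missing
#' values.  Every downstream stage of the pipeline can therefore be
#' exercised, with known ground truth, without any external data.
#'
#' @name synthetic_data
NULL

#' Default organ and gene labels
#'
#' @param n number of labels.
#' @return character vector of labels.
#' @keywords internal
organ_labels <- function(n) sprintf("organ%02d", seq_len(n))

#' @rdname organ_labels
#' @keywords internal
gene_labels <- function(n) sprintf("gene%02d", seq_len(n))

# node labels in the frozen organ-major, gene-minor order
node_labels <- function(organs, genes) {
  as.vector(t(outer(organs, genes, paste, sep = ".")))
}

spectral_abscissa <- function(K) max(Re(eigen(K, only.values = TRUE)$values))

#' Generate a ground-truth sparse interaction network
#'
#' Off-diagonal coefficients are placed uniformly at random at the requested
#' density and drawn symmetrically around zero; diagonal entries are strictly
#' negative (self-decay folded into k_ii).  If the spectral abscissa (largest
#' real part of any eigenvalue) is positive, the off-diagonal block is
#' rescaled geometrically until all trajectories are bounded — the study's
#' measured profiles are bounded, so unstable truths would make the (0, 1)
#' profile scaling meaningless.
#'
#' @param n_organs,n_genes grid dimensions; the network has
#'   `n_organs * n_genes` nodes.
#' @param density fraction of off-diagonal entries that are nonzero.
#' @param coeff_scale typical coefficient magnitude (1/week).
#' @param seed integer seed; the same seed reproduces the model bit for bit.
#' @param times sample ages (weeks) recorded in the model.
#' @return an object of class `"ground_truth_model"`: list with `K_true`,
#'   `E0`, `nodes`, `organs`, `genes`, `times`, `seed`.
#' @export
generate_network <- function(n_organs, n_genes, density, coeff_scale = 0.35,
                             seed = 1L, times = c(4, 6, 8, 12, 16)) {
  stopifnot(n_organs >= 1, n_genes >= 1, density >= 0, density <= 1,
            coeff_scale > 0)
  set.seed(seed)
  organs <- organ_labels(n_organs)
  genes <- gene_labels(n_genes)
  nodes <- node_labels(organs, genes)
  n <- length(nodes)

  K <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(K) <- -stats::runif(n, 0.5, 1.5) * coeff_scale
  off <- which(row(K) != col(K))
  n_edges <- round(density * length(off))
  if (n_edges > 0) {
    sel <- sample(off, n_edges)
    K[sel] <- sample(c(-1, 1), n_edges, replace = TRUE) *
      stats::runif(n_edges, 0.5, 1.5) * coeff_scale
  }
  # enforce boundedness by shrinking interactions, never the self-decay
  while (spectral_abscissa(K) > 0) {
    K[off] <- K[off] * 0.8
  }
  E0 <- stats::runif(n, 0.5, 1.5)
  names(E0) <- nodes
  structure(
    list(K_true = K, E0 = E0, nodes = nodes, organs = organs, genes = genes,
         times = times, seed = as.integer(seed)),
    class = "ground_truth_model"
  )
}

#' Simulate ground-truth expression trajectories
#'
#' Integrates dE/dt = K_true E from E0 with `deSolve::lsoda` and returns the
#' trajectories at the requested sample times.  (Correctness against the
#' matrix-exponential closed form is asserted in the test suite.)
#'
#' @param model a [generate_network()] result.
#' @param times sample times (weeks); defaults to the model's own.
#' @return a data.frame (organ, gene, age_weeks, value) of class
#'   `"truth_profiles"`.
#' @export
simulate_truth <- function(model, times = model$times) {
  stopifnot(inherits(model, "ground_truth_model"), !is.unsorted(times))
  if (spectral_abscissa(model$K_true) > 1e-8) {
    stop("ground-truth network is unstable (spectral abscissa > 0); ",
         "trajectories would diverge")
  }
  traj <- integrate_linear_system(model$K_true, model$E0, times)
  organs_genes <- do.call(rbind, strsplit(model$nodes, ".", fixed = TRUE))
  out <- data.frame(
    organ = rep(organs_genes[, 1], each = length(times)),
    gene = rep(organs_genes[, 2], each = length(times)),
    age_weeks = rep(times, length(model$nodes)),
    value = as.vector(traj)
  )
  class(out) <- c("truth_profiles", class(out))
  out
}

# lsoda integration of dE/dt = K E; returns times x nodes matrix
integrate_linear_system <- function(K, E0, times) {
  t0 <- times[1]
  deriv <- function(t, y, parms) list(as.vector(parms %*% y))
  grid <- unique(sort(c(t0, times)))
  sol <- deSolve::lsoda(y = E0, times = grid, func = deriv, parms = K,
                        rtol = 1e-10, atol = 1e-12)
  traj <- sol[match(times, sol[, 1]), -1, drop = FALSE]
  if (any(!is.finite(traj))) stop("trajectory integration diverged")
  rownames(traj) <- NULL
  traj
}

#' Emit a replicate-level Ct table from expression trajectories
#'
#' Inverts the -ddCt convention so that normalization is testable:
#' Ct = baseline - expression + per-gene offset + Gaussian noise.  Each
#' (strain, organ, age) cell receives `replicates` animals; cells listed in
#' `drop_cells` are omitted entirely (emulating an organ with a missing
#' sampling age) and a `missing_rate` fraction of the remaining measurements
#' is set to NA at random.
#'
#' @param profiles a [simulate_truth()] result.
#' @param strain strain label for the emitted rows.
#' @param replicates animals per (organ, age) cell.
#' @param noise_sd replicate noise standard deviation (Ct units).
#' @param missing_rate fraction of measurements set missing at random.
#' @param drop_cells data.frame (organ, age_weeks) of cells to omit.
#' @param baseline raw-Ct baseline (cycle units); arbitrary, since only the
#'   normalized values matter.
#' @param offset_sd standard deviation of the fixed per-gene Ct offsets.
#' @param seed integer seed.
#' @return a data.frame (animal, strain, organ, age_weeks, gene, ct) of
#'   class `"ct_table"`.
#' @export
generate_ct_dataset <- function(profiles, strain = "disease", replicates = 3L,
                                noise_sd = 0.05, missing_rate = 0,
                                drop_cells = NULL, baseline = 20,
                                offset_sd = 1, seed = 1L) {
  stopifnot(inherits(profiles, "truth_profiles"), replicates >= 1,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  genes <- sort(unique(profiles$gene))
  gene_offset <- stats::rnorm(length(genes), 0, offset_sd)
  names(gene_offset) <- genes

  rows <- profiles[rep(seq_len(nrow(profiles)), each = replicates), ]
  rows$replicate <- rep(seq_len(replicates), nrow(profiles))
  rows$animal <- sprintf("%s_w%02d_r%d", strain, rows$age_weeks,
                         rows$replicate)
  rows$strain <- strain
  rows$ct <- baseline - rows$value + gene_offset[rows$gene] +
    stats::rnorm(nrow(rows), 0, noise_sd)

  if (!is.null(drop_cells) && nrow(drop_cells) > 0) {
    drop_key <- paste(drop_cells$organ, drop_cells$age_weeks)
    rows <- rows[!(paste(rows$organ, rows$age_weeks) %in% drop_key), ]
  }
  if (missing_rate > 0) {
    miss <- stats::runif(nrow(rows)) < missing_rate
    rows$ct[miss] <- NA_real_
  }
  out <- rows[, c("animal", "strain", "organ", "age_weeks", "gene", "ct")]
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Perturb a ground-truth model into a disease variant
#'
#' Rewires part of the interaction structure while keeping the node set,
#' initial conditions and self-decay terms: a set of existing interactions
#' is removed, an equal number of new interactions is added at random empty
#' positions, and a few surviving interactions flip sign.  Off-diagonal
#' entries are rescaled afterwards if the spectral abscissa turns positive,
#' so the perturbed model stays simulable.
#'
#' @param model a [generate_network()] result (e.g. the control strain).
#' @param n_rewire interactions removed and (separately) added.
#' @param n_flip surviving interactions whose sign flips.
#' @param seed integer seed.
#' @return a new `ground_truth_model`.
#' @export
rewire_model <- function(model, n_rewire = 3L, n_flip = 2L, seed = 1L) {
  stopifnot(inherits(model, "ground_truth_model"))
  set.seed(seed)
  K <- model$K_true
  off <- which(row(K) != col(K))
  present <- off[K[off] != 0]
  absent <- off[K[off] == 0]
  n_rm <- min(n_rewire, length(present))
  rm_idx <- if (n_rm > 0) sample(present, n_rm) else integer(0)
  n_add <- min(n_rewire, length(absent))
  add_idx <- if (n_add > 0) sample(absent, n_add) else integer(0)
  mag <- abs(K[present])
  K[rm_idx] <- 0
  K[add_idx] <- sample(c(-1, 1), n_add, replace = TRUE) *
    stats::runif(n_add, min(mag), max(mag))
  survivors <- setdiff(present, rm_idx)
  n_fl <- min(n_flip, length(survivors))
  fl_idx <- if (n_fl > 0) sample(survivors, n_fl) else integer(0)
  K[fl_idx] <- -K[fl_idx]
  while (spectral_abscissa(K) > 0) {
    K[off] <- K[off] * 0.8
  }
  out <- model
  out$K_true <- K
  out$seed <- as.integer(seed)
  out
}

#' Plant differential rewiring between two networks
#'
#' Builds a (control, disease) pair of interaction matrices sharing a set of
#' strong persistent edges and weak background coefficients, with known
#' planted changes: `n_added` strong edges present only in disease,
#' `n_removed` present only in control, and `n_switched` with opposite signs
#' in the two strains.  The returned truth table is the benchmark for
#' differential-network calls.
#'
#' @param n_nodes number of nodes.
#' @param n_shared persistent strong edges present (identically) in both.
#' @param n_added,n_removed,n_switched planted change counts.
#' @param edge_magnitude typical strong-edge magnitude.
#' @param background_sd standard deviation of the dense weak background.
#' @param seed integer seed.
#' @return list with `K_control`, `K_disease` (dimnamed square matrices) and
#'   `truth`, a data.frame (source, target, class).
#' @export
make_rewired_pair <- function(n_nodes = 20L, n_shared = 20L, n_added = 10L,
                              n_removed = 10L, n_switched = 5L,
                              edge_magnitude = 1, background_sd = 0.02,
                              seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("node%02d", seq_len(n_nodes))
  n_planted <- n_shared + n_added + n_removed + n_switched
  off <- which(row(diag(n_nodes)) != col(diag(n_nodes)))
  stopifnot(n_planted <= length(off))
  sel <- sample(off, n_planted)
  mag <- function(k) sample(c(-1, 1), k, replace = TRUE) *
    stats::runif(k, 0.8, 1.2) * edge_magnitude

  base <- matrix(stats::rnorm(n_nodes^2, 0, background_sd), n_nodes, n_nodes,
                 dimnames = list(nodes, nodes))
  K_control <- base
  K_disease <- base
  idx <- split(sel, rep(c("shared", "added", "removed", "switched"),
                        c(n_shared, n_added, n_removed, n_switched)))

  shared_vals <- mag(n_shared)
  K_control[idx$shared] <- shared_vals
  K_disease[idx$shared] <- shared_vals
  K_disease[idx$added] <- mag(n_added)
  K_control[idx$removed] <- mag(n_removed)
  sw <- mag(n_switched)
  K_control[idx$switched] <- sw
  K_disease[idx$switched] <- -sw

  truth <- do.call(rbind, lapply(c("added", "removed", "switched"),
    function(cl) {
      ii <- idx[[cl]]
      data.frame(source = nodes[col(base)[ii]], target = nodes[row(base)[ii]],
                 class = cl)
    }))
  list(K_control = K_control, K_disease = K_disease, truth = truth)
}

#' Write a Ct table and its ground-truth sidecar
#'
#' @param ct a `ct_table`.
#' @param model the generating [generate_network()] model.
#' @param path CSV output path; a `.json` sidecar with the ground-truth K,
#'   seed and generation parameters is written next to it.
#' @return `path`, invisibly.
#' @export
write_ct_dataset <- function(ct, model, path) {
  utils::write.csv(ct, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(nodes = model$nodes, K_true = model$K_true, E0 = model$E0,
         times = model$times, seed = model$seed),
    sidecar, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
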