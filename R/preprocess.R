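#' qPCR preprocessing: median pseudo-reference normalization, imputation,
#' profile averaging and scaling
#'
#' Raw Ct values are normalized in two centering steps: per sample, the
#' median Ct across all genes in that organ acts as a pseudo reference gene
#' (dCt = Ct - med over genes); per (organ, gene), the median across all
#' samples centers the values for cross-gene comparison
#' (ddCt = dCt - med over samples).  Analyses use -ddCt so larger values
#' mean higher expression.  Missing values are imputed by a k-nearest-sample
#' mean within organ, replicates are averaged into per-strain profiles, and
#' each profile is min-max scaled to [0, 1] for system identification.
#'
#' @name preprocess
NULL

#' Normalize raw Ct values to -ddCt expression
#'
#' @param ct a `ct_table` data.frame (animal, strain, organ, age_weeks,
#'   gene, ct).  Missing Ct values propagate as missing expression; samples
#'   with no measured gene at all are excluded with a warning.
#' @return data.frame (animal, strain, organ, age_weeks, gene, value) of
#'   class `"expression_table"`, where `value` is -ddCt.
#' @export
normalize_ct <- function(ct) {
  stopifnot(all(c("animal", "strain", "organ", "age_weeks", "gene", "ct")
                %in% names(ct)))
  sample_id <- interaction(ct$animal, ct$organ, ct$age_weeks, drop = TRUE)

  all_missing <- tapply(ct$ct, sample_id, function(x) all(is.na(x)))
  if (any(all_missing)) {
    warning("excluding ", sum(all_missing),
            " sample(s) with all genes missing")
    ct <- ct[!(sample_id %in% names(all_missing)[all_missing]), ]
    sample_id <- interaction(ct$animal, ct$organ, ct$age_weeks, drop = TRUE)
  }

  med_sample <- stats::ave(ct$ct, sample_id,
                           FUN = function(x) stats::median(x, na.rm = TRUE))
  dct <- ct$ct - med_sample
  med_gene <- stats::ave(dct, interaction(ct$organ, ct$gene, drop = TRUE),
                         FUN = function(x) stats::median(x, na.rm = TRUE))
  out <- data.frame(animal = ct$animal, strain = ct$strain, organ = ct$organ,
                    age_weeks = ct$age_weeks, gene = ct$gene,
                    value = -(dct - med_gene))
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Rank the median pseudo reference against single-gene references
#'
#' For each (organ, age) cell, every single gene and the per-sample median
#' Ct are treated as candidate normalization references.  The stability
#' score of a candidate is the standard deviation of its value across the
#' samples in the cell; candidates are ranked by score (rank 1 = most
#' stable, ties share the minimum rank) and the rank of the median pseudo
#' reference is reported.
#'
#' @param ct a `ct_table`.
#' @return data.frame (organ, age_weeks, n_samples, n_candidates,
#'   median_rank, median_score).  Cells with fewer than two samples are
#'   skipped.
#' @export
rank_pseudo_reference <- function(ct) {
  cells <- unique(ct[, c("organ", "age_weeks")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- ct[ct$organ == cells$organ[i] & ct$age_weeks == cells$age_weeks[i], ]
    animals <- unique(cc$animal)
    genes <- sort(unique(cc$gene))
    wide <- matrix(NA_real_, length(animals), length(genes),
                   dimnames = list(animals, genes))
    wide[cbind(match(cc$animal, animals), match(cc$gene, genes))] <- cc$ct
    if (nrow(wide) < 2) return(NULL)
    med_ref <- apply(wide, 1, stats::median, na.rm = TRUE)
    scores <- c(apply(wide, 2, stats::sd, na.rm = TRUE),
                median_reference = stats::sd(med_ref, na.rm = TRUE))
    ranks <- rank(scores, ties.method = "min")
    data.frame(organ = cells$organ[i], age_weeks = cells$age_weeks[i],
               n_samples = nrow(wide), n_candidates = length(scores),
               median_rank = unname(ranks["median_reference"]),
               median_score = unname(scores["median_reference"]))
  })
  do.call(rbind, out)
}

#' Impute missing expression values by k-nearest samples
#'
#' Within each organ, a missing (sample, gene) value is replaced by the mean
#' of that gene over the `k` samples nearest to the incomplete sample by
#' Euclidean distance on their shared non-missing genes (distances are
#' scaled by the number of shared genes so samples with different overlap
#' are comparable).  Non-missing entries are never altered.
#'
#' @param expr an `expression_table`.
#' @param k neighborhood size; when fewer than `k` candidate neighbors carry
#'   the gene, all available ones are used with a warning.
#' @return the imputed `expression_table`.
#' @export
impute_missing <- function(expr, k = 10L) {
  stopifnot(k >= 1)
  out <- expr
  for (org in unique(expr$organ)) {
    idx <- which(expr$organ == org)
    sub <- expr[idx, ]
    sid <- interaction(sub$animal, sub$age_weeks, drop = TRUE)
    genes <- sort(unique(sub$gene))
    samples <- levels(sid)
    mat <- matrix(NA_real_, length(samples), length(genes),
                  dimnames = list(samples, genes))
    mat[cbind(as.character(sid), sub$gene)] <- sub$value
    if (!anyNA(mat)) next

    filled <- mat
    for (s in which(apply(mat, 1, anyNA))) {
      for (g in which(is.na(mat[s, ]))) {
        donors <- which(!is.na(mat[, g]) & seq_len(nrow(mat)) != s)
        if (length(donors) == 0) next
        d <- vapply(donors, function(dn) {
          shared <- !is.na(mat[s, ]) & !is.na(mat[dn, ])
          if (!any(shared)) return(Inf)
          sqrt(mean((mat[s, shared] - mat[dn, shared])^2))
        }, numeric(1))
        if (length(donors) < k) {
          warning("organ ", org, ": only ", length(donors),
                  " neighbor(s) available for imputation (k = ", k, ")")
        }
        nn <- donors[order(d)][seq_len(min(k, length(donors)))]
        filled[s, g] <- mean(mat[nn, g])
      }
    }
    out$value[idx] <- filled[cbind(as.character(sid), sub$gene)]
  }
  out
}

#' Average replicates into per-strain mean profiles
#'
#' @param expr an `expression_table` (typically imputed).
#' @return data.frame (strain, organ, gene, age_weeks, mean, n_rep) of class
#'   `"profile_set"`, ordered strain, organ-major, gene-minor, time.  Cells
#'   absent from the data (e.g. a dropped organ/age) are simply absent from
#'   that profile's time grid.
#' @export
mean_profiles <- function(expr) {
  agg <- stats::aggregate(
    value ~ strain + organ + gene + age_weeks, data = expr,
    FUN = function(x) c(mean = mean(x), n = length(x)), na.action = stats::na.omit
  )
  out <- data.frame(strain = agg$strain, organ = agg$organ, gene = agg$gene,
                    age_weeks = agg$age_weeks,
                    mean = agg$value[, "mean"], n_rep = agg$value[, "n"])
  out <- out[order(out$strain, out$organ, out$gene, out$age_weeks), ]
  rownames(out) <- NULL
  class(out) <- c("profile_set", "data.frame")
  out
}

#' Min-max scale each profile to [0, 1]
#'
#' Adds `scaled`, `scale_min` and `scale_max` columns:
#' scaled = (mean - min) / (max - min) per (strain, organ, gene) profile.
#' Constant profiles, which carry no dynamic information, map to all zeros.
#'
#' @param profiles a `profile_set`.
#' @return the `profile_set` with scaling columns.
#' @export
scale_profiles <- function(profiles) {
  key <- interaction(profiles$strain, profiles$organ, profiles$gene,
                     drop = TRUE)
  profiles$scale_min <- stats::ave(profiles$mean, key, FUN = min)
  profiles$scale_max <- stats::ave(profiles$mean, key, FUN = max)
  rng <- profiles$scale_max - profiles$scale_min
  profiles$scaled <- ifelse(rng > 0,
                            (profiles$mean - profiles$scale_min) / rng, 0)
  profiles
}

#' Build a profile set directly from ground-truth trajectories
#'
#' Bypasses the Ct layer: the `mean` and `scaled` columns both carry the
#' exact simulated expression.  Used for noise-free self-consistency checks
#' of the identification machinery.
#'
#' @param truth a [simulate_truth()] result.
#' @param strain strain label.
#' @return a `profile_set` with `scaled = mean` and unit scaling metadata.
#' @export
truth_profile_set <- function(truth, strain = "disease") {
  out <- data.frame(strain = strain, organ = truth$organ, gene = truth$gene,
                    age_weeks = truth$age_weeks, mean = truth$value,
                    n_rep = 1L, scale_min = 0, scale_max = 1,
                    scaled = truth$value)
  out <- out[order(out$strain, out$organ, out$gene, out$age_weeks), ]
  rownames(out) <- NULL
  class(out) <- c("profile_set", "data.frame")
  out
}

# split a one-strain profile_set into per-node time series in the frozen
# organ-major, gene-minor node order
profile_series <- function(profiles, strain, value = "scaled") {
  sub <- profiles[profiles$strain == strain, ]
  if (nrow(sub) == 0) stop("no profiles for strain '", strain, "'")
  sub <- sub[order(sub$organ, sub$gene, sub$age_weeks), ]
  key <- paste(sub$organ, sub$gene, sep = ".")
  nodes <- unique(key)
  series <- lapply(nodes, function(nd) {
    rows <- sub[key == nd, ]
    list(times = rows$age_weeks, values = rows[[value]],
         scale_min = rows$scale_min[1], scale_max = rows$scale_max[1])
  })
  names(series) <- nodes
  series
}
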