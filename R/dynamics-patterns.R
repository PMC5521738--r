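#' Temporal pattern classification and cascade ordering
#'
#' Each scaled profile is classified as showing a veritable peak or valley
#' (first interior extremum whose deviation from the initial time point
#' exceeds E_th = 0.5), as monotone (all putative extremum deviations below
#' E_th0 = 0.1, direction from the least-squares slope), or as none.
#' Monotone decays carry t_p = t_0 and monotone increases t_v = t_0, so
#' every profile participates in peak- or valley-time cascade ordering.
#'
#' @name dynamics_patterns
NULL

#' Classify one scaled profile
#'
#' Interior local extrema of the sampled sequence (strictly above/below both
#' neighbors) are candidate peaks/valleys; the first whose deviation
#' |E(t_x) - E(t_0)| exceeds `e_th` decides the call.  Note a prominent
#' valley occurring before a prominent peak therefore yields a valley call —
#' peaks preceded by prominent valleys never enter peak cascades.
#'
#' @param times sample times (weeks).
#' @param values scaled values in [0, 1].
#' @param e_th deviation threshold for a veritable extremum.
#' @param e_th0 deviation ceiling below which a profile counts as monotone.
#' @return list: `call` (one of `"peak"`, `"valley"`,
#'   `"monotone_increase"`, `"monotone_decay"`, `"none"`), `time`,
#'   `deviation`.
#' @export
classify_extrema <- function(times, values, e_th = 0.5, e_th0 = 0.1) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  n <- length(values)
  if (n < 3 || stats::sd(values) == 0) {
    return(list(call = "none", time = NA_real_, deviation = NA_real_))
  }
  interior <- 2:(n - 1)
  is_peak <- values[interior] > values[interior - 1] &
    values[interior] > values[interior + 1]
  is_valley <- values[interior] < values[interior - 1] &
    values[interior] < values[interior + 1]
  idx <- interior[is_peak | is_valley]
  kind <- c("peak", "valley")[1 + is_valley[is_peak | is_valley]]
  dev <- abs(values[idx] - values[1])

  qualifying <- which(dev > e_th)
  if (length(qualifying) > 0) {
    first <- qualifying[1]  # idx is already time-ordered
    return(list(call = kind[first], time = times[idx[first]],
                deviation = dev[first]))
  }
  if (length(dev) == 0 || all(dev < e_th0)) {
    slope <- stats::cov(times, values) / stats::var(times)
    if (slope > 0) {
      return(list(call = "monotone_increase", time = times[1],
                  deviation = abs(values[n] - values[1])))
    }
    if (slope < 0) {
      return(list(call = "monotone_decay", time = times[1],
                  deviation = abs(values[n] - values[1])))
    }
  }
  list(call = "none", time = NA_real_, deviation = max(dev, 0))
}

#' Classify every profile of a profile set
#'
#' @param profiles a scaled `profile_set` (or any data.frame with strain,
#'   organ, gene, age_weeks and the chosen value column).
#' @param value column holding the scaled values.
#' @inheritParams classify_extrema
#' @return data.frame (strain, organ, gene, call, time, deviation).
#' @export
classify_profiles <- function(profiles, value = "scaled", e_th = 0.5,
                              e_th0 = 0.1) {
  cells <- unique(profiles[, c("strain", "organ", "gene")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    pp <- profiles[profiles$strain == cells$strain[i] &
                     profiles$organ == cells$organ[i] &
                     profiles$gene == cells$gene[i], ]
    pp <- pp[order(pp$age_weeks), ]
    cl <- classify_extrema(pp$age_weeks, pp[[value]], e_th, e_th0)
    data.frame(strain = cells$strain[i], organ = cells$organ[i],
               gene = cells$gene[i], call = cl$call, time = cl$time,
               deviation = cl$deviation)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Order profiles into a peak or valley cascade
#'
#' Profiles of the reference strain carrying the requested extremum time —
#' peaks together with monotone decays (t_p = t_0) for `by = "peak"`,
#' valleys together with monotone increases (t_v = t_0) for
#' `by = "valley"` — are sorted ascending by that time, ties broken by
#' organ then gene label.  A cross-strain table pairs the extremum times of
#' profiles qualifying in both strains.
#'
#' @param calls a [classify_profiles()] table covering both strains.
#' @param by `"peak"` or `"valley"`.
#' @param reference_strain strain whose times define the ordering.
#' @return list with `ordering` (data.frame organ, gene, call, time, rank)
#'   and `cross_strain` (data.frame organ, gene, time_reference,
#'   time_other).
#' @export
order_cascade <- function(calls, by = c("peak", "valley"),
                          reference_strain) {
  by <- match.arg(by)
  wanted <- if (by == "peak") c("peak", "monotone_decay")
            else c("valley", "monotone_increase")
  ref <- calls[calls$strain == reference_strain & calls$call %in% wanted, ]
  ref <- ref[order(ref$time, ref$organ, ref$gene), ]
  ordering <- data.frame(organ = ref$organ, gene = ref$gene, call = ref$call,
                         time = ref$time,
                         rank = seq_len(nrow(ref)))

  other <- calls[calls$strain != reference_strain & calls$call %in% wanted, ]
  merged <- merge(ref[, c("organ", "gene", "time")],
                  other[, c("organ", "gene", "time")],
                  by = c("organ", "gene"), suffixes = c("_reference",
                                                        "_other"))
  list(ordering = ordering, cross_strain = merged)
}
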