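# One-parameter families: instances identical in every swept parameter but
# one, used to quantify robustness and period sensitivity along single
# conductance axes.

#' Partition a group into one-parameter families
#'
#' A family is a subset of a group whose members share every swept
#' parameter value except the varied one. The partition is exact (every
#' instance lands in exactly one family) and members are sorted ascending
#' by the varied parameter.
#'
#' @param group data.frame of instance records (level columns `SynS, SynG,
#'   P, K2, h, CaS, Leak, E_Leak`)
#' @param varied name of the varied parameter
#' @return List of families: each a data.frame of member rows (class
#'   `hco_family`, attributes `varied` and `fixed`).
#' @export
partition_families <- function(group, varied) {
  cols <- c(.swept_conductances, "E_Leak")
  stopifnot(varied %in% cols)
  fixed_cols <- setdiff(cols, varied)
  key <- do.call(paste, c(group[fixed_cols], sep = "|"))
  lapply(split(seq_len(nrow(group)), key), function(ix) {
    fam <- group[ix[order(group[[varied]][ix])], , drop = FALSE]
    structure(fam, varied = varied,
              fixed = fam[1, fixed_cols, drop = FALSE],
              class = c("hco_family", class(fam)))
  })
}

#' Family-size census of a group
#'
#' @param group data.frame of instance records
#' @param varied varied parameter name
#' @return Named integer vector: count of families per family size; sizes
#'   times counts sum to the group size.
#' @export
family_size_census <- function(group, varied) {
  fams <- partition_families(group, varied)
  sizes <- vapply(fams, nrow, integer(1))
  tab <- table(sizes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Period change across a family
#'
#' The difference between the mean cycle periods of the last and first
#' members of the family after ascending sort on the varied parameter
#' (negative = the period falls as the parameter rises).
#'
#' @param f an `hco_family` (from [partition_families()]) with a `period`
#'   column
#' @return Period difference (s), or `NA` with a warning for singleton
#'   families.
#' @export
family_period_change <- function(f) {
  stopifnot(inherits(f, "hco_family"))
  if (nrow(f) < 2) {
    warning("singleton family: period change undefined")
    return(NA_real_)
  }
  per <- f$period
  if (any(!is.finite(per))) {
    warning("family member with undefined period")
    return(NA_real_)
  }
  per[nrow(f)] - per[1]
}

#' Family robustness and period-sensitivity report
#'
#' Partitions the group along `varied` and reports, per family-size
#' stratum: the census, the mean period change (last minus first member)
#' and its range, and the fraction of multi-member families whose period
#' decreases monotonically as the varied parameter increases.
#'
#' @param group data.frame of instance records with a `period` column
#' @param varied varied parameter name
#' @return List with `census`, `by_size` (data.frame: size, n_families,
#'   mean/min/max period change), `monotone_fraction`, and `deltas`
#'   (per-family period change, multi-member families only).
#' @export
family_report <- function(group, varied) {
  fams <- partition_families(group, varied)
  sizes <- vapply(fams, nrow, integer(1))
  multi <- fams[sizes >= 2]
  deltas <- vapply(multi, function(f) suppressWarnings(family_period_change(f)),
                   numeric(1))
  monotone <- vapply(multi, function(f)
    all(diff(f$period) < 0), logical(1))
  msz <- vapply(multi, nrow, integer(1))
  by_size <- do.call(rbind, lapply(sort(unique(msz)), function(s) {
    d <- deltas[msz == s]
    data.frame(size = s, n_families = length(d),
               mean_delta = mean(d), min_delta = min(d), max_delta = max(d))
  }))
  list(census = family_size_census(group, varied),
       by_size = by_size,
       monotone_fraction = if (length(monotone)) mean(monotone) else NA_real_,
       deltas = deltas)
}
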