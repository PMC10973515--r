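.states <- c("MES", "AC", "OPC", "NPC")

#' Cell-state composition of hypoxic versus non-hypoxic cells
#'
#' Tabulates, per stratum (each patient, or the pooled cohort), the
#' proportion of each of the four collapsed states (MES, AC, OPC, NPC)
#' within the hypoxic and within the non-hypoxic cells, and their
#' difference `delta = prop_hypoxic - prop_nonhypoxic`.  Proportions within
#' a stratum and class sum to 1.  Strata with zero cells in a class get
#' `NA` proportions with a warning rather than zeros.
#'
#' @param ann per-cell annotation data.frame with columns `state`,
#'   `hypoxic`, and (when `by_patient`) `patient` and `idh_status`.
#' @param by_patient stratify per patient (default) or pool all cells into
#'   a single `"pooled"` stratum.
#' @return a `shift_table`: data.frame with one row per stratum x state:
#'   `patient`, `idh_status`, `state`, `n_hypoxic`, `n_nonhypoxic`,
#'   `prop_hypoxic`, `prop_nonhypoxic`, `delta`.
#' @export
state_composition <- function(ann, by_patient = TRUE) {
  stopifnot(all(c("state", "hypoxic") %in% names(ann)))
  if (by_patient) stopifnot(all(c("patient", "idh_status") %in% names(ann)))
  strata <- if (by_patient) split(ann, ann$patient) else list(pooled = ann)
  rows <- lapply(names(strata), function(p) {
    s <- strata[[p]]
    idh <- if (by_patient) s$idh_status[[1]] else NA_character_
    n_h <- table(factor(s$state[s$hypoxic], levels = .states))
    n_n <- table(factor(s$state[!s$hypoxic], levels = .states))
    prop <- function(n) {
      tot <- sum(n)
      if (tot == 0) {
        warning(sprintf("state_composition: stratum '%s' has an empty class; proportions set NA", p))
        rep(NA_real_, length(n))
      } else as.numeric(n) / tot
    }
    data.frame(patient = p, idh_status = idh, state = .states,
               n_hypoxic = as.integer(n_h), n_nonhypoxic = as.integer(n_n),
               prop_hypoxic = prop(n_h), prop_nonhypoxic = prop(n_n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta <- out$prop_hypoxic - out$prop_nonhypoxic
  rownames(out) <- NULL
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wraps `stats::wilcox.test` with the policy used throughout the package:
#' the exact null distribution when `n_a + n_b <= 12` and the data are
#' tie-free, otherwise the normal approximation with tie and continuity
#' correction.  Always two-sided.
#'
#' @param a,b numeric vectors, each non-empty.
#' @param group_a,group_b labels carried into the result.
#' @return a `group_test`: list with `statistic` (rank-sum W), `pval`,
#'   `n_a`, `n_b`, `exact` (whether the exact distribution was used), and
#'   the group labels.
#' @export
rank_sum_test <- function(a, b, group_a = "a", group_b = "b") {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  exact <- (length(a) + length(b) <= 12) && !anyDuplicated(c(a, b))
  ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  structure(list(statistic = unname(ht$statistic), pval = ht$p.value,
                 n_a = length(a), n_b = length(b), exact = exact,
                 group_a = group_a, group_b = group_b),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("rank-sum %s (n=%d) vs %s (n=%d): W = %g, p = %.4g (%s)\n",
              x$group_a, x$n_a, x$group_b, x$n_b, x$statistic, x$pval,
              if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

.p_stars <- function(p) ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                        ifelse(p <= 0.05, "*", "ns")))

#' IDH-stratified hypoxic state-shift report
#'
#' For each of the four states, compares the per-patient state-shift
#' `delta` (hypoxic minus non-hypoxic proportion) between IDH-wildtype and
#' IDH-mutant patients with a two-sided rank-sum test.  Also summarizes
#' per-patient hypoxic fractions and per-state deltas.  No multiplicity
#' correction is applied across the four states.
#'
#' @param shift a per-patient `shift_table` from [state_composition()].
#' @param value which per-patient statistic to compare: `"delta"`
#'   (default) or `"prop_hypoxic"` (the state's proportion within the
#'   hypoxic class alone).
#' @return list with `tests` (data.frame: `state`, `statistic`, `pval`,
#'   `stars`, `n_wt`, `n_mut`, and group mean values) and `patients`
#'   (data.frame: `patient`, `idh_status`, `frac_hypoxic` and one delta
#'   column per state).
#' @export
idh_shift_report <- function(shift, value = c("delta", "prop_hypoxic")) {
  value <- match.arg(value)
  stopifnot(inherits(shift, "data.frame"),
            all(c("patient", "idh_status", "state", value) %in% names(shift)))
  pts <- unique(shift[, c("patient", "idh_status")])
  n_wt <- sum(pts$idh_status == "WT"); n_mut <- sum(pts$idh_status == "MUT")
  if (n_wt == 0 || n_mut == 0)
    stop("both IDH groups must contain at least one patient")
  tests <- do.call(rbind, lapply(.states, function(st) {
    d <- shift[shift$state == st, ]
    d <- d[order(d$patient), ]
    wt <- d[[value]][d$idh_status == "WT"]
    mut <- d[[value]][d$idh_status == "MUT"]
    gt <- rank_sum_test(wt, mut, "WT", "MUT")
    data.frame(state = st, statistic = gt$statistic, pval = gt$pval,
               stars = .p_stars(gt$pval), n_wt = gt$n_a, n_mut = gt$n_b,
               mean_wt = mean(wt, na.rm = TRUE), mean_mut = mean(mut, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_pat <- lapply(split(shift, shift$patient), function(d) {
    tot_h <- sum(d$n_hypoxic); tot_n <- sum(d$n_nonhypoxic)
    row <- data.frame(patient = d$patient[[1]], idh_status = d$idh_status[[1]],
                      frac_hypoxic = tot_h / (tot_h + tot_n),
                      stringsAsFactors = FALSE)
    for (st in .states) row[[paste0("delta_", st)]] <- d$delta[d$state == st]
    row
  })
  patients <- do.call(rbind, per_pat[order(names(per_pat))])
  rownames(patients) <- NULL
  list(tests = tests, patients = patients)
}
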