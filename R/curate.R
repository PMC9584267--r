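# Cohort curation: drop irrelevant participants, off-schedule samples,
# participants without a pre-vaccination expression sample, and under-age
# participants. Order matters and every removal is counted in provenance.

#' Curate a compendium bundle
#'
#' Applies, in order: (1) a caller-supplied predicate flagging participants as
#' irrelevant to the study objective (default: none removed); (2) removal of
#' samples whose `time_days` matches no scheduled time for their study within
#' `tolerance`; (3) removal of participants with no remaining pre-vaccination
#' (`time_days <= 0`) sample; (4) removal of participants younger than
#' `age_min`. Each step logs its removal count to provenance.
#'
#' @param bundle A `CompendiumBundle`.
#' @param schedule Named list: study accession -> numeric vector of permissible
#'   `time_days`. Studies absent from the list are left untouched by the
#'   schedule filter. `NULL` disables the filter.
#' @param tolerance Half-width (days) for matching a sample time to a
#'   scheduled time. Default 0.25 day.
#' @param age_min Minimum age in years (uses `age_reported`, falling back to
#'   `age_imputed`; participants with no age are retained). Default 18.
#' @param irrelevant Optional function `(samples) -> character vector` of
#'   participant ids to drop, or a character vector of participant ids.
#' @return The curated bundle. Errors if nothing survives.
#' @export
curate <- function(bundle, schedule = NULL, tolerance = 0.25, age_min = 18,
                   irrelevant = NULL) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  s <- bundle$samples

  drop_participants <- character()
  if (is.function(irrelevant)) drop_participants <- irrelevant(s)
  else if (is.character(irrelevant)) drop_participants <- irrelevant
  keep <- !(s$participant_id %in% drop_participants)
  bundle <- curate_step(bundle, s$sample_id[keep], "curate_irrelevant",
                        list(n_participants = length(unique(
                          s$participant_id[!keep]))))
  s <- bundle$samples

  if (!is.null(schedule)) {
    ok <- vapply(seq_len(nrow(s)), function(i) {
      sched <- schedule[[s$study_accession[i]]]
      if (is.null(sched)) return(TRUE)
      any(abs(s$time_days[i] - sched) <= tolerance)
    }, logical(1))
    bundle <- curate_step(bundle, s$sample_id[ok], "curate_time_design",
                          list(tolerance = tolerance))
    s <- bundle$samples
  }

  has_baseline <- tapply(s$time_days <= 0, s$participant_id, any)
  keep_pid <- names(has_baseline)[has_baseline]
  bundle <- curate_step(bundle, s$sample_id[s$participant_id %in% keep_pid],
                        "curate_no_baseline", list())
  s <- bundle$samples

  age <- s$age_reported
  if ("age_imputed" %in% names(s))
    age <- ifelse(is.na(age), s$age_imputed, age)
  keep <- is.na(age) | age >= age_min
  bundle <- curate_step(bundle, s$sample_id[keep], "curate_age_min",
                        list(age_min = age_min))
  bundle
}

curate_step <- function(bundle, keep_ids, stage, params) {
  n_in <- nrow(bundle$samples)
  if (length(keep_ids) == 0L)
    stop("all samples curated away at stage '", stage, "'")
  if (length(keep_ids) == n_in &&
      setequal(keep_ids, bundle$samples$sample_id)) {
    return(add_provenance(bundle, stage, params, n_in, n_in))
  }
  keep <- bundle$samples$sample_id %in% keep_ids
  samples <- bundle$samples[keep, , drop = FALSE]
  rownames(samples) <- NULL
  bundle$expression$values <-
    bundle$expression$values[, samples$sample_id, drop = FALSE]
  if (!is.null(bundle$titers)) {
    bundle$titers <- bundle$titers[
      bundle$titers$participant_id %in% samples$participant_id, , drop = FALSE]
    rownames(bundle$titers) <- NULL
  }
  bundle$samples <- samples
  add_provenance(bundle, stage, params, n_in, nrow(samples))
}
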