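# Antibody endpoints: per-strain log2 fold change between a post-vaccination
# window and the pre-vaccination baseline, maximum fold change (MFC) across
# strains, maximum residual after baseline adjustment (maxRBA), assay
# preference (HAI > NAb > ELISA for influenza; NAb > ELISA otherwise), and
# merging endpoints back onto an expression bundle.

#' Log2 fold change of one participant/analyte
#'
#' Uses the latest baseline (`time_days <= 0`) measurement and, among the
#' post-vaccination values inside `post_window`, the one whose day is closest
#' to `target_day`. Missing baseline or post value yields `NA` (endpoint
#' unavailable, not an error).
#'
#' @param titers Validated titer table.
#' @param participant,analyte Row selectors.
#' @param assay Optional assay selector.
#' @param post_window Numeric length-2 window in days (default c(21, 35)).
#' @param target_day Preferred post day (default 28).
#' @return Scalar log2 fold change or NA.
#' @export
fold_change <- function(titers, participant, analyte, assay = NULL,
                        post_window = c(21, 35), target_day = 28) {
  rows <- titers$participant_id == participant & titers$analyte == analyte
  if (!is.null(assay)) rows <- rows & titers$assay == assay
  tt <- titers[rows, , drop = FALSE]
  base <- tt[tt$time_days <= 0, , drop = FALSE]
  post <- tt[tt$time_days >= post_window[1] &
               tt$time_days <= post_window[2], , drop = FALSE]
  if (!nrow(base) || !nrow(post)) return(NA_real_)
  b <- base$value[which.max(base$time_days)]
  p <- post$value[which.min(abs(post$time_days - target_day))]
  log2(p / b)
}

#' Maximum fold change across strains
#' @param fcs Numeric vector of per-strain log2 fold changes (NAs ignored).
#' @return The maximum.
#' @export
mfc <- function(fcs) {
  fcs <- fcs[!is.na(fcs)]
  if (!length(fcs)) stop("no per-strain fold changes available")
  max(fcs)
}

#' Per-participant maximum residual after baseline adjustment (maxRBA)
#'
#' For one study/assay: per strain, ordinary-least-squares regression of the
#' log2 fold change on the log2 baseline titer across participants; each
#' participant's maxRBA is the maximum over strains of their residual. Strains
#' with fewer than 3 complete participants are skipped with a warning. A
#' zero-variance baseline makes the slope inestimable; the residuals then
#' reduce to the centered fold changes (degenerate-slope convention).
#'
#' @param titers Validated titer table restricted to one study and assay.
#' @param post_window,target_day As in [fold_change()].
#' @return Named numeric vector participant -> maxRBA (participants with no
#'   usable strain get NA), with attribute `"per_strain"` (list of residual
#'   vectors).
#' @export
max_rba <- function(titers, post_window = c(21, 35), target_day = 28) {
  participants <- unique(titers$participant_id)
  strains <- unique(titers$analyte)
  per_strain <- list()
  for (strain in strains) {
    lb <- lfc <- stats::setNames(rep(NA_real_, length(participants)),
                                 participants)
    for (p in participants) {
      rows <- titers$participant_id == p & titers$analyte == strain
      tt <- titers[rows, , drop = FALSE]
      base <- tt[tt$time_days <= 0, , drop = FALSE]
      if (!nrow(base)) next
      lb[p] <- log2(base$value[which.max(base$time_days)])
      lfc[p] <- fold_change(titers, p, strain, post_window = post_window,
                            target_day = target_day)
    }
    ok <- !is.na(lb) & !is.na(lfc)
    if (sum(ok) < 3L) {
      warning("strain '", strain, "' skipped: fewer than 3 complete ",
              "participants")
      next
    }
    x <- lb[ok]; y <- lfc[ok]
    if (stats::var(x) == 0) {
      res <- y - mean(y)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      res <- fit$residuals
    }
    per_strain[[strain]] <- stats::setNames(res, names(y))
  }
  if (!length(per_strain)) {
    out <- stats::setNames(rep(NA_real_, length(participants)), participants)
    attr(out, "per_strain") <- per_strain
    return(out)
  }
  out <- vapply(participants, function(p) {
    vals <- unlist(lapply(per_strain, function(r) r[p]))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) NA_real_ else max(vals)
  }, numeric(1))
  names(out) <- participants
  attr(out, "per_strain") <- per_strain
  out
}

#' Choose the preferred assay for a pathogen
#'
#' Influenza: HAI, then NAb, then ELISA. Everything else: NAb, then ELISA
#' (HAI is not expected outside influenza but is accepted as a last resort).
#'
#' @param available Character vector of assays with computable endpoints.
#' @param pathogen Pathogen string (influenza detected case-insensitively).
#' @return The assay to use, or NA if none available.
#' @export
select_endpoint <- function(available, pathogen) {
  if (!length(available)) return(NA_character_)
  pref <- if (grepl("influenza", pathogen, ignore.case = TRUE))
    c("HAI", "NAb", "ELISA") else c("NAb", "ELISA", "HAI")
  hit <- pref[pref %in% available]
  if (!length(hit)) NA_character_ else hit[1]
}

#' Compute endpoint records for every participant
#'
#' Per study and assay: per-strain log2 fold changes, their MFC, and maxRBA.
#' The assay used per participant follows [select_endpoint()] preferences.
#'
#' @param titers Validated titer table.
#' @param pathogen_by_study Named character vector study -> pathogen (needed
#'   for assay preference; defaults to treating HAI-bearing studies as
#'   influenza).
#' @param post_window,target_day As in [fold_change()].
#' @return An `EndpointRecord` data.frame: `participant_id`,
#'   `study_accession`, `assay_used`, `MFC`, `maxRBA`, `n_strains`.
#' @export
compute_endpoints <- function(titers, pathogen_by_study = NULL,
                              post_window = c(21, 35), target_day = 28) {
  titers <- validate_titers(titers)
  recs <- list()
  for (study in unique(titers$study_accession)) {
    st <- titers[titers$study_accession == study, , drop = FALSE]
    pathogen <- if (!is.null(pathogen_by_study) &&
                    !is.na(pathogen_by_study[study]))
      pathogen_by_study[study]
    else if ("HAI" %in% st$assay) "influenza" else "other"
    by_assay <- list()
    for (assay in unique(st$assay)) {
      sa <- st[st$assay == assay, , drop = FALSE]
      rba <- suppressWarnings(max_rba(sa, post_window, target_day))
      rows <- lapply(unique(sa$participant_id), function(p) {
        fcs <- vapply(unique(sa$analyte), function(strain)
          fold_change(sa, p, strain, post_window = post_window,
                      target_day = target_day), numeric(1))
        fcs_ok <- fcs[!is.na(fcs)]
        data.frame(participant_id = p, study_accession = study,
                   assay = assay,
                   MFC = if (length(fcs_ok)) max(fcs_ok) else NA_real_,
                   maxRBA = unname(rba[p]),
                   n_strains = length(fcs_ok), stringsAsFactors = FALSE)
      })
      by_assay[[assay]] <- do.call(rbind, rows)
    }
    all_assays <- do.call(rbind, by_assay)
    for (p in unique(all_assays$participant_id)) {
      av <- all_assays[all_assays$participant_id == p &
                         !is.na(all_assays$MFC), , drop = FALSE]
      use <- select_endpoint(av$assay, pathogen)
      if (is.na(use)) next
      row <- av[av$assay == use, , drop = FALSE]
      names(row)[names(row) == "assay"] <- "assay_used"
      recs[[length(recs) + 1L]] <- row
    }
  }
  if (!length(recs))
    return(data.frame(participant_id = character(),
                      study_accession = character(),
                      assay_used = character(), MFC = numeric(),
                      maxRBA = numeric(), n_strains = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("EndpointRecord", "data.frame")
  out
}

#' Spearman correlation between two endpoint vectors
#'
#' @param x,y Named numeric vectors (names = participant ids); only shared,
#'   complete pairs are used (at least 3 required). Midranks handle ties.
#' @return List with `rho` (NA with a message when a vector is constant),
#'   `n`.
#' @export
correlate_endpoints <- function(x, y) {
  shared <- intersect(names(x), names(y))
  xv <- x[shared]; yv <- y[shared]
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3L) stop("need at least 3 paired participants")
  xv <- xv[ok]; yv <- yv[ok]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    return(list(rho = NA_real_, n = sum(ok),
                note = "constant endpoint vector; correlation undefined"))
  list(rho = unname(stats::cor(xv, yv, method = "spearman")), n = sum(ok))
}

#' Attach endpoints to a bundle (response-matched variant)
#'
#' Participants lacking a computable endpoint are excluded; counts are logged
#' to provenance. The endpoint record is stored as `bundle$endpoints` and the
#' per-sample columns `MFC`, `maxRBA`, `assay_used` are merged into the sample
#' table.
#'
#' @param bundle A `CompendiumBundle`.
#' @param endpoints An `EndpointRecord` from [compute_endpoints()].
#' @return The response-matched bundle.
#' @export
attach_endpoints <- function(bundle, endpoints) {
  stopifnot(inherits(bundle, "CompendiumBundle"))
  matched <- intersect(bundle$samples$participant_id,
                       endpoints$participant_id)
  if (!length(matched)) {
    warning("no participant has both expression and endpoints")
    bundle$samples <- bundle$samples[0, , drop = FALSE]
    bundle$expression$values <-
      bundle$expression$values[, 0, drop = FALSE]
    bundle$endpoints <- endpoints[0, , drop = FALSE]
    return(add_provenance(bundle, "attach_endpoints", list(),
                          length(unique(endpoints$participant_id)), 0))
  }
  keep <- bundle$samples$participant_id %in% matched
  out <- subset_bundle(bundle, bundle$samples$sample_id[keep],
                       stage = "attach_endpoints")
  ep <- endpoints[match(out$samples$participant_id,
                        endpoints$participant_id), , drop = FALSE]
  out$samples$MFC <- ep$MFC
  out$samples$maxRBA <- ep$maxRBA
  out$samples$assay_used <- ep$assay_used
  out$endpoints <- endpoints[endpoints$participant_id %in% matched, ,
                             drop = FALSE]
  out
}
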