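#' Classify urine samples against biomarker thresholds
#'
#' A sample is "above" when either biomarker reaches its threshold
#' (gVLM >= t_gvlm OR SREM >= t_srem); a value exactly on the threshold counts
#' as above, matching the "at least" definition of the target intake. When one
#' biomarker is missing the other decides; a sample missing both is an error
#' (such samples must be dropped explicitly upstream, never classified
#' silently).
#'
#' @param samples data.frame of urine samples with columns `participant_id`,
#'   `visit`, `gvlm`, `srem` (micromolar).
#' @param thresholds a [threshold_pair()].
#' @return data.frame with `participant_id`, `visit`, `above`.
#' @export
classify_samples <- function(samples, thresholds = cosmos_thresholds()) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (!all(c("participant_id", "visit", "gvlm", "srem") %in% names(samples)))
    stop("`samples` must have columns participant_id, visit, gvlm, srem")
  g <- samples$gvlm
  s <- samples$srem
  both_missing <- is.na(g) & is.na(s)
  if (any(both_missing))
    stop(sprintf("%d sample(s) missing both biomarker values (rows: %s)",
                 sum(both_missing),
                 paste(utils::head(which(both_missing), 10), collapse = ", ")))
  if (any(c(g, s) < 0, na.rm = TRUE) || any(is.infinite(c(g, s))))
    stop("concentrations must be finite and non-negative")
  above <- (!is.na(g) & g >= thresholds$t_gvlm) | (!is.na(s) & s >= thresholds$t_srem)
  data.frame(participant_id = samples$participant_id, visit = samples$visit,
             above = above, stringsAsFactors = FALSE)
}

#' Assign biomarker-defined analysis groups to trial participants
#'
#' Applies the trial's exposure-group rule: a participant is *biomarker active*
#' if above threshold at baseline or at any follow-up visit, *biomarker
#' control* if below at baseline and at every available follow-up visit, and
#' *excluded* if randomized to the intervention arm, below threshold at
#' baseline, and without any follow-up sample (adherence cannot be determined
#' for them). The exclusion rule applies to the intervention arm only: placebo
#' participants without follow-up are classified on their baseline sample
#' alone. Participants with no baseline sample are flagged `unclassifiable`
#' (group `NA`) and excluded from all biomarker analyses.
#'
#' @param samples urine-sample data.frame (see [classify_samples()]).
#' @param participants participant table with columns `id` and `arm`.
#' @param thresholds a [threshold_pair()].
#' @return data.frame with one row per participant: `participant_id`, `arm`,
#'   `baseline_above`, `has_followup`, `followup_above` (`NA` when no
#'   follow-up sample exists), `group` (factor: biomarker_active,
#'   biomarker_control, excluded; `NA` for unclassifiable), `unclassifiable`.
#' @export
classify_participants <- function(samples, participants,
                                  thresholds = cosmos_thresholds()) {
  st <- classify_samples(samples, thresholds)
  is_base <- st$visit == "baseline"
  if (anyDuplicated(st$participant_id[is_base]))
    stop("more than one baseline sample for some participant")
  if (anyDuplicated(paste(st$participant_id, st$visit)))
    stop("more than one sample per participant-visit")

  ids <- participants$id
  base_idx <- match(ids, st$participant_id[is_base])
  baseline_above <- st$above[is_base][base_idx]

  fu <- st[!is_base, , drop = FALSE]
  fu_any <- tapply(fu$above, fu$participant_id, any)
  fu_idx <- match(as.character(ids), names(fu_any))
  followup_above <- as.logical(fu_any[fu_idx])
  has_followup <- !is.na(fu_idx)

  unclassifiable <- is.na(base_idx)
  excluded <- !unclassifiable & participants$arm == "intervention" &
    !has_followup & !baseline_above
  active <- !unclassifiable & !excluded &
    (baseline_above | (has_followup & followup_above))
  group <- rep(NA_character_, length(ids))
  group[excluded] <- "excluded"
  group[active] <- "biomarker_active"
  group[!unclassifiable & !excluded & !active] <- "biomarker_control"

  data.frame(
    participant_id = ids, arm = participants$arm,
    baseline_above = baseline_above, has_followup = has_followup,
    followup_above = followup_above,
    group = factor(group, levels = c("biomarker_active", "biomarker_control", "excluded")),
    unclassifiable = unclassifiable,
    stringsAsFactors = FALSE
  )
}

#' Tabulate the classification into the trial's benchmark table layout
#'
#' Produces the counts and integer percentages of the published classification
#' table: participants above threshold at baseline (overall and by arm), the
#' follow-up subset with baseline and follow-up above-counts by arm, the
#' excluded count, the biomarker-analysis n, the arm composition of the
#' active and control groups, and (when `samples` is supplied) the share of
#' participants with both baseline biomarkers below the limit of
#' quantification. Percentages are rounded half-up to whole percent; an empty
#' denominator yields `NA`, never 0%.
#'
#' @param classifications result of [classify_participants()].
#' @param participants participant table.
#' @param samples optional urine samples (for the below-LOQ share, computed
#'   from the `below_loq_*` flags of the baseline samples).
#' @return object of class `classification_table`.
#' @export
tabulate_classification <- function(classifications, participants, samples = NULL) {
  cl <- classifications[!classifications$unclassifiable, , drop = FALSE]
  pl <- cl$arm == "placebo"
  iv <- cl$arm == "intervention"
  fu <- cl$has_followup

  cell <- function(num, den) list(n = num, pct = pct_of(num, den), denom = den)
  tab <- list(
    baseline = cell(sum(cl$baseline_above), nrow(cl)),
    baseline_placebo = cell(sum(cl$baseline_above & pl), sum(pl)),
    baseline_intervention = cell(sum(cl$baseline_above & iv), sum(iv)),
    fu_subset_baseline = cell(sum(cl$baseline_above & fu), sum(fu)),
    fu_subset_followup = cell(sum(fu & cl$followup_above, na.rm = TRUE), sum(fu)),
    fu_subset_baseline_placebo = cell(sum(cl$baseline_above & fu & pl), sum(fu & pl)),
    fu_subset_baseline_intervention = cell(sum(cl$baseline_above & fu & iv), sum(fu & iv)),
    fu_subset_followup_placebo = cell(sum(fu & pl & cl$followup_above, na.rm = TRUE), sum(fu & pl)),
    fu_subset_followup_intervention = cell(sum(fu & iv & cl$followup_above, na.rm = TRUE), sum(fu & iv))
  )

  grp <- table(cl$group)
  n_total <- nrow(classifications)
  act_iv <- sum(cl$group == "biomarker_active" & iv, na.rm = TRUE)
  ctl_iv <- sum(cl$group == "biomarker_control" & iv, na.rm = TRUE)

  below_loq <- NULL
  if (!is.null(samples)) {
    base <- samples[samples$visit == "baseline", , drop = FALSE]
    n_loq <- sum(base$below_loq_gvlm & base$below_loq_srem)
    below_loq <- cell(n_loq, nrow(base))
  }

  structure(list(
    cells = tab,
    n_cohort = n_total,
    n_classified = nrow(cl),
    n_unclassifiable = sum(classifications$unclassifiable),
    excluded = cell(unname(grp[["excluded"]]), n_total),
    n_analysis = unname(grp[["biomarker_active"]] + grp[["biomarker_control"]]),
    n_active = unname(grp[["biomarker_active"]]),
    n_control = unname(grp[["biomarker_control"]]),
    active_intervention = cell(act_iv, unname(grp[["biomarker_active"]])),
    control_intervention = cell(ctl_iv, unname(grp[["biomarker_control"]])),
    below_loq = below_loq
  ), class = "classification_table")
}

#' @export
print.classification_table <- function(x, ...) {
  c2 <- function(cl) {
    if (is.null(cl)) return("-")
    if (is.na(cl$pct)) sprintf("%d (undefined %%)", cl$n)
    else sprintf("%d (%d%%)", cl$n, as.integer(cl$pct))
  }
  t <- x$cells
  cat("Participants with biomarker levels consistent with the reference intake\n")
  cat(sprintf("  Baseline, all (n=%d): %s\n", t$baseline$denom, c2(t$baseline)))
  cat(sprintf("    placebo (n=%d): %s | intervention (n=%d): %s\n",
              t$baseline_placebo$denom, c2(t$baseline_placebo),
              t$baseline_intervention$denom, c2(t$baseline_intervention)))
  cat(sprintf("  Follow-up subset (n=%d): baseline %s | follow-up %s\n",
              t$fu_subset_baseline$denom, c2(t$fu_subset_baseline), c2(t$fu_subset_followup)))
  cat(sprintf("    placebo (n=%d): baseline %s, follow-up %s\n",
              t$fu_subset_baseline_placebo$denom, c2(t$fu_subset_baseline_placebo),
              c2(t$fu_subset_followup_placebo)))
  cat(sprintf("    intervention (n=%d): baseline %s, follow-up %s\n",
              t$fu_subset_baseline_intervention$denom, c2(t$fu_subset_baseline_intervention),
              c2(t$fu_subset_followup_intervention)))
  cat(sprintf("  Excluded (intervention, no follow-up, baseline below): %s\n", c2(x$excluded)))
  cat(sprintf("  Analysis n = %d: active %s intervention, control %s intervention\n",
              x$n_analysis, c2(x$active_intervention), c2(x$control_intervention)))
  if (!is.null(x$below_loq))
    cat(sprintf("  Below LOQ at baseline (both biomarkers): %s\n", c2(x$below_loq)))
  if (x$n_unclassifiable > 0)
    cat(sprintf("  Unclassifiable (no baseline sample): %d\n", x$n_unclassifiable))
  invisible(x)
}

#' @export
as.data.frame.classification_table <- function(x, ...) {
  cells <- c(x$cells, list(excluded = x$excluded,
                           active_intervention = x$active_intervention,
                           control_intervention = x$control_intervention))
  if (!is.null(x$below_loq)) cells$below_loq <- x$below_loq
  data.frame(
    cell = names(cells),
    n = vapply(cells, function(cl) cl$n, numeric(1)),
    denom = vapply(cells, function(cl) cl$denom, numeric(1)),
    pct = vapply(cells, function(cl) as.numeric(cl$pct), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare biomarker-measured and self-reported adherence
#'
#' Biomarker adherence is the share of intervention-arm participants with at
#' least one follow-up sample whose follow-up biomarkers reach the threshold;
#' self-reported adherence is the share of intervention-arm participants who
#' never report missing more than 8 pills per month, being unsure, or taking
#' an outside supplement.
#'
#' @param classifications result of [classify_participants()].
#' @param self_reports self-report table (`participant_id`, `report_date`,
#'   `status`).
#' @return list with `biomarker_adherence_pct` and `selfreport_adherence_pct`
#'   (unrounded percentages) and the corresponding denominators.
#' @export
adherence_summary <- function(classifications, self_reports) {
  iv_fu <- classifications$arm == "intervention" & classifications$has_followup &
    !classifications$unclassifiable
  n_bio <- sum(iv_fu)
  bio <- if (n_bio > 0)
    100 * sum(classifications$followup_above[iv_fu], na.rm = TRUE) / n_bio
  else NA_real_

  iv_ids <- classifications$participant_id[classifications$arm == "intervention"]
  flagged <- self_reports$status %in% selfreport_levels()[2:4]
  flag_ids <- unique(self_reports$participant_id[flagged])
  n_sr <- length(iv_ids)
  sr <- if (n_sr > 0) 100 * sum(!(iv_ids %in% flag_ids)) / n_sr else NA_real_

  list(biomarker_adherence_pct = bio, selfreport_adherence_pct = sr,
       n_biomarker = n_bio, n_selfreport = n_sr)
}
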