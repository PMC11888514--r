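#' Sweep classification thresholds over a two-dimensional grid
#'
#' Re-runs the complete biomarker pipeline — reclassification (with the
#' exclusion rule re-applied, since the excluded set depends on baseline
#' status) and a fresh Cox fit — at every point of a (gVLM, SREM) threshold
#' grid, for each endpoint. The published sensitivity analysis spans 1-50 uM
#' for gVLM and 1-30 uM for SREM in 1 uM steps; any strictly increasing grids
#' may be supplied. Cells with fewer than `min_events` events in either
#' exposure group (or an empty group) are flagged not-estimable.
#'
#' @param cohort a `flavanol_cohort`.
#' @param grid_gvlm,grid_srem strictly increasing threshold grids (micromolar).
#' @param endpoints endpoints to fit.
#' @param model adjustment model id (default 2, as in the published sweep).
#' @param min_events minimum events per exposure group for a cell to be fitted.
#' @return long-format data.frame of class `threshold_sweep`: `t_gvlm`,
#'   `t_srem`, `endpoint`, `hr`, `ci_low`, `ci_high`, `n_active`, `n_control`,
#'   `not_estimable`; attributes `grid_gvlm`, `grid_srem`, `model_id`.
#' @export
sweep_thresholds <- function(cohort, grid_gvlm = 1:50, grid_srem = 1:30,
                             endpoints = endpoint_levels(), model = 2,
                             min_events = 5) {
  if (any(diff(grid_gvlm) <= 0) || any(diff(grid_srem) <= 0))
    stop("threshold grids must be strictly increasing")
  rows <- list()
  for (tg in grid_gvlm) for (ts in grid_srem) {
    cls <- classify_participants(cohort$urine_samples, cohort$participants,
                                 threshold_pair(tg, ts))
    n_active <- sum(cls$group == "biomarker_active", na.rm = TRUE)
    n_control <- sum(cls$group == "biomarker_control", na.rm = TRUE)
    for (ep in endpoints) {
      res <- tryCatch({
        d <- build_survival_dataset(cohort, ep, "biomarker", cls)
        ev_by_group <- tapply(as.logical(d$event), d$exposure, sum)
        if (length(ev_by_group) < 2 || any(is.na(ev_by_group)) ||
            any(ev_by_group < min_events))
          stop_not_estimable(sprintf("fewer than %d events in an exposure group",
                                     min_events))
        fit_cox(d, model_spec(model))
      }, flavatrial_not_estimable = function(e) e)
      ne <- inherits(res, "flavatrial_not_estimable")
      rows[[length(rows) + 1L]] <- data.frame(
        t_gvlm = tg, t_srem = ts, endpoint = ep,
        hr = if (ne) NA_real_ else res$hr,
        ci_low = if (ne) NA_real_ else res$ci_low,
        ci_high = if (ne) NA_real_ else res$ci_high,
        n_active = n_active, n_control = n_control,
        not_estimable = ne, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, grid_gvlm = grid_gvlm, grid_srem = grid_srem, model_id = model,
            class = c("threshold_sweep", "data.frame"))
}

#' Stable threshold ranges around a reference cell
#'
#' For each endpoint, finds the maximal contiguous grid rectangle containing
#' the reference cell in which the upper 95% confidence limit of the hazard
#' ratio stays within a relative tolerance of the reference cell's value and
#' does not cross 1 in the opposite direction of the reference. "No material
#' change" is operationalized as: estimable, `|upper/upper_ref - 1| <= tol`,
#' and on the same side of 1 as the reference. The rectangle is grown
#' greedily, one grid line at a time, cycling over the four directions
#' (deterministic).
#'
#' @param surface a [sweep_thresholds()] result.
#' @param reference reference thresholds `c(t_gvlm, t_srem)`; the nearest grid
#'   cell is used.
#' @param tol relative tolerance on the HR upper confidence limit (default
#'   0.10).
#' @return data.frame: per endpoint, the stable `t_gvlm`/`t_srem` ranges.
#' @export
stability_report <- function(surface, reference = c(18.2, 7.8), tol = 0.10) {
  stopifnot(inherits(surface, "threshold_sweep"))
  gg <- attr(surface, "grid_gvlm")
  gs <- attr(surface, "grid_srem")
  ig0 <- which.min(abs(gg - reference[1]))
  is0 <- which.min(abs(gs - reference[2]))
  eps <- lapply(unique(surface$endpoint), function(ep) {
    sub <- surface[surface$endpoint == ep, , drop = FALSE]
    up <- matrix(NA_real_, length(gg), length(gs))
    est <- matrix(FALSE, length(gg), length(gs))
    up[cbind(match(sub$t_gvlm, gg), match(sub$t_srem, gs))] <- sub$ci_high
    est[cbind(match(sub$t_gvlm, gg), match(sub$t_srem, gs))] <- !sub$not_estimable
    ref <- up[ig0, is0]
    if (!est[ig0, is0] || is.na(ref))
      stop(sprintf("reference cell not estimable for endpoint %s", ep))
    ok <- est & !is.na(up) & abs(up / ref - 1) <= tol &
      (sign(log(up)) == sign(log(ref)) | up == 1 | ref == 1)
    lo_g <- ig0; hi_g <- ig0; lo_s <- is0; hi_s <- is0
    repeat {
      grew <- FALSE
      if (lo_g > 1 && all(ok[lo_g - 1, lo_s:hi_s])) { lo_g <- lo_g - 1; grew <- TRUE }
      if (hi_g < length(gg) && all(ok[hi_g + 1, lo_s:hi_s])) { hi_g <- hi_g + 1; grew <- TRUE }
      if (lo_s > 1 && all(ok[lo_g:hi_g, lo_s - 1])) { lo_s <- lo_s - 1; grew <- TRUE }
      if (hi_s < length(gs) && all(ok[lo_g:hi_g, hi_s + 1])) { hi_s <- hi_s + 1; grew <- TRUE }
      if (!grew) break
    }
    data.frame(endpoint = ep, t_gvlm_min = gg[lo_g], t_gvlm_max = gg[hi_g],
               t_srem_min = gs[lo_s], t_srem_max = gs[hi_s],
               reference_upper_ci = ref, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, eps)
  rownames(out) <- NULL
  out
}

#' Biomarker-contrast sensitivity across the adjustment-model ladder
#'
#' Refits the biomarker-active vs biomarker-control contrast for each endpoint
#' under each of the five adjustment models, yielding the sensitivity table of
#' hazard ratios by model.
#'
#' @param cohort a `flavanol_cohort`.
#' @param classifications [classify_participants()] output.
#' @param endpoints endpoints to fit.
#' @param models model ids (default 1:5).
#' @return data.frame as in [run_contrasts()], restricted to the biomarker
#'   contrast.
#' @export
model_ladder <- function(cohort, classifications, endpoints = endpoint_levels(),
                         models = 1:5) {
  run_contrasts(cohort, classifications, contrasts = "biomarker",
                models = models, endpoints = endpoints)
}
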