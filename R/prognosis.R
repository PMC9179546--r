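#' Metagene-resolved hazard-ratio map
#'
#' For every map unit, samples whose decomposed metagene score exceeds the
#' unit's own mean plus one standard deviation form the "high" group; a
#' univariate Cox proportional-hazards model of high vs rest yields the
#' unit's hazard ratio `HR = exp(beta)`. Units whose high group is smaller
#' than `min_group`, or where either arm lacks events, are `NA`. Because the
#' mean + 1 SD cut is taken on the unit's own profile the map is invariant
#' to positive rescaling of the omics matrix.
#'
#' @param decomposed output of [decompose_model()].
#' @param modality modality to map.
#' @param annotations data frame with `sample_id`, `time` (months) and
#'   `event` (0/1); rows with missing survival are ignored.
#' @param side grid side length.
#' @param min_group minimum size of the high group (default 5).
#' @return list of [portrait()]s: `hr` (kind `"HR"`), `n_high` and `events`
#'   companion grids.
#' @export
hr_map <- function(decomposed, modality, annotations, side, min_group = 5) {
  surv <- survival_records(annotations)
  M <- decomposed[[modality]]
  surv <- surv[surv$sample_id %in% colnames(M), , drop = FALSE]
  if (nrow(surv) < 2 * min_group)
    stop("need at least 2 * min_group samples with survival data")
  if (sum(surv$event) < 1) stop("no events in the survival data")
  M <- M[, surv$sample_id, drop = FALSE]
  n_units <- nrow(M)
  hr <- rep(NA_real_, n_units)
  n_high <- integer(n_units)
  events <- integer(n_units)
  ss <- survival::Surv(surv$time, surv$event)
  mu <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  for (u in seq_len(n_units)) {
    high <- M[u, ] > mu[u] + sdv[u]
    n_high[u] <- sum(high)
    events[u] <- sum(surv$event)
    if (n_high[u] < min_group || n_high[u] > nrow(surv) - min_group) next
    if (sum(surv$event[high]) == 0 || sum(surv$event[!high]) == 0) next
    fit <- tryCatch(survival::coxph(ss ~ high), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit)) next
    hr[u] <- exp(stats::coef(fit)[[1]])
  }
  list(hr = portrait(grid_from_units(hr, side), "HR", modality),
       n_high = grid_from_units(n_high, side),
       events = grid_from_units(events, side))
}

#' Hazard ratio of a spot module
#'
#' Applies the same mean + 1 SD dichotomization to the spot's mean metagene
#' profile and reports the Cox hazard ratio with its 95% confidence
#' interval, per modality.
#'
#' @param spot a `spot_module`.
#' @param decomposed output of [decompose_model()].
#' @param annotations survival annotations as in [hr_map()].
#' @param min_group minimum high-group size.
#' @return data frame: `modality`, `hr`, `ci_low`, `ci_high`, `n_high`,
#'   `p`; `NA` rows where the fit is not defined.
#' @export
spot_hr <- function(spot, decomposed, annotations, min_group = 5) {
  if (length(spot$member_units) == 0) stop("empty spot")
  surv <- survival_records(annotations)
  out <- do.call(rbind, lapply(MODALITIES, function(m) {
    prof <- spot_profiles_units(decomposed, spot$member_units)[[m]]
    na_row <- data.frame(modality = m, hr = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, n_high = NA_integer_,
                         p = NA_real_)
    if (all(is.na(prof))) return(na_row)
    keep <- surv$sample_id %in% names(prof)
    sv <- surv[keep, , drop = FALSE]
    x <- prof[sv$sample_id]
    high <- x > mean(x) + stats::sd(x)
    if (sum(high) < min_group || sum(high) > length(x) - min_group)
      return(na_row)
    fit <- tryCatch(
      survival::coxph(survival::Surv(sv$time, sv$event) ~ high),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(na_row)
    sm <- summary(fit)
    data.frame(modality = m, hr = sm$conf.int[1, "exp(coef)"],
               ci_low = sm$conf.int[1, "lower .95"],
               ci_high = sm$conf.int[1, "upper .95"],
               n_high = sum(high), p = sm$coefficients[1, "Pr(>|z|)"])
  }))
  rownames(out) <- NULL
  out
}

survival_records <- function(annotations) {
  ann <- validate_annotations(annotations)
  if (!all(c("time", "event") %in% names(ann)))
    stop("annotations carry no survival data (columns 'time' and 'event')")
  keep <- !is.na(ann$time) & !is.na(ann$event)
  if (!any(keep)) stop("annotations carry no survival data")
  data.frame(sample_id = ann$sample_id[keep], time = ann$time[keep],
             event = as.integer(ann$event[keep]))
}
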