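#' Group summary of a record-level feature
#'
#' @param cohort Cohort table (one row per kept record) with a `group` column.
#' @param group Group label to summarize.
#' @param feature Feature column name.
#' @return One-row data frame with `group`, `feature`, `n`, `mean`, `min`,
#'   `max`, or `NULL` (with a message) when the group is empty.
#' @export
summarize_group <- function(cohort, group, feature) {
  stopifnot(is.data.frame(cohort), feature %in% names(cohort))
  x <- cohort[[feature]][cohort$group == group]
  x <- x[is.finite(x)]
  if (!length(x)) {
    message("no kept records in group '", group, "'")
    return(NULL)
  }
  data.frame(
    group = group, feature = feature, n = length(x),
    mean = mean(x), min = min(x), max = max(x),
    stringsAsFactors = FALSE
  )
}

#' Two-group Welch comparison of a record-level feature
#'
#' Welch's unequal-variance t-test (two-sided, Satterthwaite degrees of
#' freedom) on record-level values. When both groups have zero variance and
#' equal means, `t = 0` and `p = 1` by convention.
#'
#' @param cohort Cohort table with a `group` column.
#' @param feature Feature column name.
#' @param groups The two group labels to compare (order defines the sign of
#'   the mean difference).
#' @return An object of class `group_comparison`: data frame with `feature`,
#'   `t`, `df`, `p_value`, the group means, and `direction`
#'   (`"<group1> higher"` / `"<group2> higher"` / `"equal"`).
#' @export
compare_groups <- function(cohort, feature, groups = c("diabetes", "control")) {
  stopifnot(is.data.frame(cohort), feature %in% names(cohort), length(groups) == 2)
  x <- cohort[[feature]][cohort$group == groups[1]]
  y <- cohort[[feature]][cohort$group == groups[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least 2 records per group", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      tt <- list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                 parameter = c(df = length(x) + length(y) - 2), p.value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
  }
  m1 <- mean(x); m2 <- mean(y)
  out <- data.frame(
    feature = feature,
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_1 = m1, mean_2 = m2,
    direction = if (m1 > m2) paste(groups[1], "higher")
                else if (m1 < m2) paste(groups[2], "higher") else "equal",
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  class(out) <- c("group_comparison", class(out))
  out
}

#' Bramwell--Hill pulse wave velocity
#'
#' `PWV = sqrt(dP * V / (rho * dV))`: the pulse wave velocity implied by the
#' pulse pressure `dP`, blood density `rho`, and the fractional vessel volume
#' change `dV / V` over the pulse.
#'
#' @param pulse_pressure Pulse pressure in Pa (use [mmhg_to_pa()] for mmHg).
#' @param blood_density Blood density in kg/m^3 (default 1050).
#' @param volume Vessel volume (any unit shared with `volume_change`).
#' @param volume_change Pulse volume change (> 0, same unit as `volume`).
#' @return PWV in m/s.
#' @export
#' @examples
#' bramwell_hill_pwv(mmhg_to_pa(40), 1050, 1, 0.1) # ~ 7.13 m/s
bramwell_hill_pwv <- function(pulse_pressure, blood_density = 1050,
                              volume = 1, volume_change) {
  if (!is.finite(pulse_pressure) || pulse_pressure < 0) {
    stop("pulse_pressure must be non-negative", call. = FALSE)
  }
  stopifnot(blood_density > 0, volume > 0, volume_change > 0)
  sqrt(pulse_pressure * volume / (blood_density * volume_change))
}

#' Convert mmHg to Pa
#' @param x Pressure in mmHg.
#' @return Pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' Select subjects with strictly height-ordered wrist pressures
#'
#' Returns, per subject, the navel/chest/forehead record triplets for which
#' all three posture measurements exist and the wrist systolic pressures obey
#' the strict hydrostatic ordering navel > chest > forehead. (A further
#' "minimal overlap with other data" criterion used for plotting in the source
#' protocol is subjective and deliberately not implemented.)
#'
#' @param cohort Data frame with `subject_id`, `posture` and `wrist_sbp`
#'   columns (one row per record).
#' @return Data frame of the selected rows (three per selected subject),
#'   ordered navel, chest, forehead within subject. May be empty.
#' @export
select_height_ordered <- function(cohort) {
  stopifnot(all(c("subject_id", "posture", "wrist_sbp") %in% names(cohort)))
  out <- list()
  for (sid in unique(cohort$subject_id)) {
    sub <- cohort[cohort$subject_id == sid, , drop = FALSE]
    rows <- lapply(c("navel", "chest", "forehead"), function(p) {
      r <- sub[sub$posture == p & is.finite(sub$wrist_sbp), , drop = FALSE]
      if (nrow(r)) r[1, , drop = FALSE] else NULL
    })
    if (any(vapply(rows, is.null, logical(1)))) next
    sbp <- vapply(rows, function(r) r$wrist_sbp, numeric(1))
    if (sbp[1] > sbp[2] && sbp[2] > sbp[3]) {
      out[[length(out) + 1]] <- do.call(rbind, rows)
    }
  }
  if (length(out)) do.call(rbind, out) else cohort[0, , drop = FALSE]
}
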