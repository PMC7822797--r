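#' Collapse woman-level outcomes to facility percentages for one wave
#'
#' For each facility with at least one linked woman in the wave, computes
#' per outcome the eligible denominator (women with a non-missing
#' indicator) and the percentage of positive indicators among them.
#' Facilities with zero linked women in the wave simply do not appear;
#' when the facility roster is supplied their number is logged.
#'
#' @param links data.frame from [link_cohort()].
#' @param women woman-level data.frame (see [gen_women()] for the schema).
#' @param wave the survey wave to collapse.
#' @param facilities optional roster, used only to log how many
#'   facilities attracted no women.
#' @return data.frame keyed by `facility_id` with `wave`, and per outcome
#'   `n_<outcome>` (eligible count) and `pct_<outcome>` (0-100, `NA` when
#'   the denominator is zero).
#' @export
collapse_outcomes <- function(links, women, wave, facilities = NULL) {
  assert_cols(links, c("woman_id", "facility_id", "wave"), "links")
  w <- women[women$wave == wave, , drop = FALSE]
  l <- links[links$wave == wave, , drop = FALSE]
  miss <- setdiff(w$woman_id, l$woman_id)
  if (length(miss)) {
    stop_invalid("links do not cover woman '%s' (and %d more) in wave %s",
                 miss[1L], length(miss) - 1L, wave)
  }
  unknown <- setdiff(l$woman_id, w$woman_id)
  if (length(unknown)) {
    stop_invalid("link references unknown woman '%s' in wave %s",
                 unknown[1L], wave)
  }
  if (!is.null(facilities)) {
    bad_fac <- setdiff(l$facility_id, facilities$facility_id)
    if (length(bad_fac)) {
      stop_invalid("link references unknown facility '%s'", bad_fac[1L])
    }
  }
  fac_of <- setNames(l$facility_id, l$woman_id)
  w_fac <- unname(fac_of[w$woman_id])
  fac_ids <- sort(unique(w_fac))
  out <- data.frame(facility_id = fac_ids, wave = as.integer(wave),
                    stringsAsFactors = FALSE)
  grp <- factor(w_fac, levels = fac_ids)
  for (o in outcome_names()) {
    y <- w[[o]]
    elig <- !is.na(y)
    n_elig <- as.vector(rowsum(as.numeric(elig), grp))
    pos <- as.vector(rowsum(ifelse(elig, as.numeric(y), 0), grp))
    out[[paste0("n_", o)]] <- as.integer(n_elig)
    out[[paste0("pct_", o)]] <- ifelse(n_elig > 0, 100 * pos / n_elig, NA_real_)
  }
  if (!is.null(facilities)) {
    n_empty <- sum(!facilities$facility_id %in% fac_ids)
    if (n_empty > 0) {
      fd_log("collapse_outcomes: wave %s, %d facilities with zero linked women omitted",
             wave, n_empty)
    }
  }
  out
}

#' Assemble the facility-by-wave panel
#'
#' Binds per-wave collapsed rows into a long panel keyed by
#' `(facility_id, wave)` and attaches the treatment indicator and
#' covariates: `policy = 1` iff the wave is at or after the facility's
#' accreditation wave and its status is provisional or full (both count
#' as treated); facility covariates (staff counts, building condition,
#' catchment population) and, when the district table is supplied, the
#' eight district indicators and region. Unbalanced panels are allowed.
#'
#' @param rows rbind of [collapse_outcomes()] results (or draws from
#'   [gen_facility_panel()]).
#' @param facilities facility table with accreditation fields.
#' @param districts optional district table.
#' @return the panel data.frame, with attribute `balanced`.
#' @export
build_panel <- function(rows, facilities, districts = NULL) {
  assert_cols(rows, c("facility_id", "wave"), "panel rows")
  waves <- sort(unique(rows$wave))
  if (length(waves) < 2L) stop_invalid("panel needs at least two waves")
  key <- paste(rows$facility_id, rows$wave)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (facility, wave) key: %s", key[duplicated(key)][1L])
  }
  fi <- match(rows$facility_id, facilities$facility_id)
  if (anyNA(fi)) {
    stop_invalid("panel row references unknown facility '%s'",
                 rows$facility_id[which(is.na(fi))[1L]])
  }
  treated <- !is.na(facilities$accreditation_wave[fi]) &
    facilities$accreditation_status[fi] %in% c("provisional", "full")
  rows$policy <- as.integer(treated & rows$wave >=
                              facilities$accreditation_wave[fi])
  rows$ever_treated <- as.integer(treated)
  rows$district_id <- facilities$district_id[fi]
  for (col in c(paste0("staff_", staff_categories()),
                "building_condition", "catchment_population",
                "accreditation_status", "other_interventions")) {
    if (col %in% names(facilities)) rows[[col]] <- facilities[[col]][fi]
  }
  if (!is.null(districts)) {
    di <- match(rows$district_id, districts$district_id)
    for (col in c(district_indicators(), "region")) {
      rows[[col]] <- districts[[col]][di]
    }
  }
  per_fac <- table(rows$facility_id)
  balanced <- all(per_fac == length(waves))
  if (!balanced) {
    fd_log("build_panel: unbalanced panel (%d of %d facilities observed in all %d waves)",
           sum(per_fac == length(waves)), length(per_fac), length(waves))
  }
  rownames(rows) <- NULL
  attr(rows, "balanced") <- balanced
  rows
}

#' Apply the analysis-sample rules
#'
#' Two rules, each logged: (1) facilities that are accredited *and*
#' flagged as subject to additional reform interventions
#' (performance-based financing, user fees) are removed entirely, so the
#' treatment contrast reflects accreditation alone — never-accredited
#' facilities are retained even if flagged; (2) outcome cells whose
#' eligible denominator is below `min_denominator` have their percentage
#' set to missing, since facility percentages from tiny denominators are
#' noise.
#'
#' @param panel panel from [build_panel()].
#' @param facilities facility table (used for the intervention flag when
#'   the panel lacks the columns).
#' @param min_denominator minimum eligible women per cell (default 5).
#' @return the filtered panel; attribute `dropped` records counts.
#' @export
apply_sample_rules <- function(panel, facilities = NULL, min_denominator = 5) {
  if (!all(c("other_interventions", "accreditation_status") %in% names(panel))) {
    if (is.null(facilities)) {
      stop_invalid("panel lacks intervention flags and no facility table given")
    }
    fi <- match(panel$facility_id, facilities$facility_id)
    panel$other_interventions <- facilities$other_interventions[fi]
    panel$accreditation_status <- facilities$accreditation_status[fi]
  }
  drop_fac <- panel$other_interventions == 1L &
    panel$accreditation_status %in% c("provisional", "full")
  n_fac_dropped <- length(unique(panel$facility_id[drop_fac]))
  if (n_fac_dropped > 0) {
    fd_log("apply_sample_rules: removed %d accredited facilities subject to other interventions (%d rows)",
           n_fac_dropped, sum(drop_fac))
  }
  panel <- panel[!drop_fac, , drop = FALSE]
  n_masked <- 0L
  for (o in outcome_names()) {
    ncol_ <- paste0("n_", o); pcol <- paste0("pct_", o)
    if (!all(c(ncol_, pcol) %in% names(panel))) next
    small <- panel[[ncol_]] < min_denominator & !is.na(panel[[pcol]])
    n_masked <- n_masked + sum(small)
    panel[[pcol]][panel[[ncol_]] < min_denominator] <- NA_real_
  }
  if (n_masked > 0) {
    fd_log("apply_sample_rules: masked %d cells with fewer than %d eligible women",
           n_masked, min_denominator)
  }
  rownames(panel) <- NULL
  attr(panel, "dropped") <- list(facilities_other_interventions = n_fac_dropped,
                                 cells_below_min_denominator = n_masked,
                                 min_denominator = min_denominator)
  panel
}
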