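#' Recode an ordinal item so that higher values mean worse health
#'
#' Items coded with higher values meaning \emph{better} health are
#' reversed (k -> K-1-k over the item's 0..K-1 range); items already
#' coded higher-is-worse are returned unchanged. Applying the function
#' twice with the same direction returns the input (involution).
#'
#' @param values integer vector of 0-based ordinal responses (NA allowed).
#' @param current_direction \code{"higher_is_better"} or
#'   \code{"higher_is_worse"}.
#' @param n_cat number of categories K; defaults to
#'   \code{max(values, na.rm = TRUE) + 1}.
#' @return Recoded integer vector with higher = worse.
#' @export
recode_direction <- function(values, current_direction,
                             n_cat = max(values, na.rm = TRUE) + 1L) {
  if (!current_direction %in% c("higher_is_better", "higher_is_worse")) {
    stop("unknown direction flag: ", current_direction)
  }
  if (current_direction == "higher_is_worse") return(values)
  as.integer(n_cat - 1L - values)
}

#' Band a numeric test into three groups by the 25th/75th percentiles
#'
#' Used for timed tests where a \emph{lower} time means better
#' performance: values below the empirical 25th percentile form the
#' "high"-performance band (0), the interquartile range the medium band
#' (1), and values above the 75th percentile the low band (2). Quantiles
#' are linear-interpolation empirical quantiles (type 7) of the
#' non-missing values; values exactly on a boundary fall in the medium
#' band. Output is coded higher = worse.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @return Integer vector in \{0, 1, 2\}; missing stays missing.
#' @export
band_percentile <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("cannot band an all-missing vector")
  if (sum(ok) < 4) stop("need at least 4 non-missing values to band")
  q <- quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  out <- rep(NA_integer_, length(values))
  out[ok] <- 1L
  out[ok & values < q[1]] <- 0L
  out[ok & values > q[2]] <- 2L
  out
}

#' Band a numeric test by one standard deviation around the mean
#'
#' Scores above mean + 1 SD form the high-performance band (0), scores
#' within +/- 1 SD the medium band (1), and scores below mean - 1 SD the
#' low band (2), computed on the non-missing values; boundary values fall
#' in the medium (closed) band. Banding is invariant to affine rescaling
#' of the input. Output is coded higher = worse.
#'
#' @param values numeric vector with positive standard deviation.
#' @return Integer vector in \{0, 1, 2\}; missing stays missing.
#' @export
band_sd <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("cannot band an all-missing vector")
  m <- mean(values[ok]); s <- sd(values[ok])
  if (!is.finite(s) || s == 0) stop("cannot band a vector with zero SD")
  out <- rep(NA_integer_, length(values))
  out[ok] <- 1L
  out[ok & values > m + s] <- 0L
  out[ok & values < m - s] <- 2L
  out
}

#' Recode the orientation-in-time test to binary
#'
#' Participants answering all four orientation questions (day, date,
#' month, year) correctly are coded "no difficulty" (0); anyone failing
#' at least one question is coded "some difficulties" (1).
#'
#' @param correct_count integer vector in 0..4 (NA allowed).
#' @return Integer vector: 0 = no difficulty, 1 = some difficulties.
#' @export
recode_orientation <- function(correct_count) {
  if (any(!is.na(correct_count) &
          (correct_count < 0 | correct_count > 4))) {
    stop("orientation correct_count must lie in 0..4")
  }
  ifelse(is.na(correct_count), NA_integer_,
         ifelse(correct_count == 4L, 0L, 1L))
}

# per person-wave missing fraction among administered (non-structural)
# cells, restricted to a wave
personwave_missing <- function(panel, wave = NULL) {
  sub <- if (is.null(wave)) panel else panel[panel$wave %in% wave, ]
  sub <- sub[sub$status != "structural", ]
  if (!nrow(sub)) {
    return(data.frame(person_id = integer(), wave = integer(),
                      n_administered = integer(), n_missing = integer()))
  }
  agg <- aggregate(cbind(n_administered = rep(1L, nrow(sub)),
                         n_missing = as.integer(is.na(sub$response))) ~
                     person_id + wave, data = sub, FUN = sum)
  agg[order(agg$person_id, agg$wave), ]
}

#' Exclude persons with excessive baseline missingness before factor
#' analysis
#'
#' Drops persons whose fraction of missing responses over the baseline
#' item set is \emph{at least} \code{threshold} (the inclusive rule: a
#' person missing exactly 25\% of the items is excluded). Structurally
#' unavailable cells do not count toward the denominator.
#'
#' @param panel a \code{"response_panel"}.
#' @param threshold missing-fraction cutoff (default 0.25).
#' @param wave baseline wave (default 1).
#' @return List with \code{panel} (rows of retained persons, all waves)
#'   and \code{report} (n_total, n_excluded, n_retained, excluded ids).
#' @export
filter_participants_fa <- function(panel, threshold = 0.25, wave = 1L) {
  mw <- personwave_missing(panel, wave = wave)
  if (!nrow(mw)) stop("no administered items at the baseline wave")
  frac <- mw$n_missing / mw$n_administered
  excluded <- mw$person_id[frac >= threshold]
  keep <- !(panel$person_id %in% excluded)
  out <- panel[keep, ]
  rownames(out) <- NULL
  list(panel = out,
       report = list(n_total = nrow(mw), n_excluded = length(excluded),
                     n_retained = nrow(mw) - length(excluded),
                     threshold = threshold, excluded_ids = excluded))
}

#' Exclude person-waves with more than half of administered items missing
#'
#' Applied before the multilevel IRT fit: a person-wave is dropped when
#' \emph{strictly more than} \code{threshold} of the items administered
#' in that wave are missing ("more than a half" is strict: exactly half
#' missing is retained). Person-waves with no administered items at all
#' are dropped with a warning.
#'
#' @param panel a \code{"response_panel"}.
#' @param threshold missing-fraction cutoff (default 0.5).
#' @return The filtered panel.
#' @export
filter_personwave_irt <- function(panel, threshold = 0.5) {
  mw <- personwave_missing(panel)
  frac <- mw$n_missing / mw$n_administered
  drop <- mw[frac > threshold, c("person_id", "wave")]

  administered <- unique(panel[panel$status != "structural",
                               c("person_id", "wave")])
  all_pw <- unique(panel[, c("person_id", "wave")])
  key <- function(d) paste(d$person_id, d$wave)
  empty <- all_pw[!key(all_pw) %in% key(administered), , drop = FALSE]
  if (nrow(empty)) {
    warning(nrow(empty), " person-wave(s) had no administered items and",
            " were dropped")
    drop <- rbind(drop, empty)
  }
  keep <- !key(panel) %in% key(drop)
  out <- panel[keep, ]
  rownames(out) <- NULL
  out
}

#' Split persons into development and validation samples
#'
#' Random split stratified by a person-level factor (typically gender):
#' within each stratum, round(frac * n) persons go to the development
#' sample, so per-stratum proportions match \code{frac} within one
#' person.
#'
#' @param persons data frame with \code{person_id} and the stratification
#'   column, or a vector of ids (unstratified).
#' @param frac development fraction in (0, 1); default 0.7.
#' @param stratify name of the stratification column (default
#'   \code{"gender"}); ignored when \code{persons} is a bare vector.
#' @param seed integer seed.
#' @return List with integer vectors \code{development} and
#'   \code{validation} (disjoint, exhaustive).
#' @export
split_sample <- function(persons, frac = 0.7, stratify = "gender",
                         seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  if (is.data.frame(persons)) {
    ids <- persons$person_id
    strata <- if (!is.null(stratify) && stratify %in% names(persons)) {
      persons[[stratify]]
    } else {
      rep(0L, length(ids))
    }
  } else {
    ids <- persons
    strata <- rep(0L, length(ids))
  }
  set.seed(seed)
  dev <- unlist(lapply(split(ids, strata), function(g) {
    sample(g, round(frac * length(g)))
  }), use.names = FALSE)
  list(development = sort(dev), validation = sort(setdiff(ids, dev)))
}

#' Cast a long response panel to a person(-wave) by item matrix
#'
#' @param panel a \code{"response_panel"}.
#' @param wave optional wave filter.
#' @return Integer matrix (rows = person or person-wave, columns =
#'   items), NA for missing; rownames are \code{person_id} (single wave)
#'   or \code{person_id.wave}.
#' @export
panel_to_matrix <- function(panel, wave = NULL) {
  sub <- if (is.null(wave)) panel else panel[panel$wave %in% wave, ]
  item_ids <- sort(unique(sub$item_id))
  if (is.null(wave) || length(wave) > 1) {
    rid <- paste(sub$person_id, sub$wave, sep = ".")
  } else {
    rid <- as.character(sub$person_id)
  }
  rows <- unique(rid)
  m <- matrix(NA_integer_, length(rows), length(item_ids),
              dimnames = list(rows, item_ids))
  m[cbind(match(rid, rows), match(sub$item_id, item_ids))] <- sub$response
  m
}
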