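# Harmonization of heterogeneous literature/assay activity records and
# construction of the categorical and five-level potency reference sets.

#' Potency class levels, weakest to strongest
#' @export
POTENCY_LEVELS <- c("inactive", "very_weak", "weak", "moderate", "strong")

#' The three modeled activity classes
#' @export
ACTIVITY_TYPES <- c("binding", "agonist", "antagonist")

#' Inactive AC50 sentinel (1 M expressed in micromolar)
#' @export
INACTIVE_AC50_UM <- 1e6

.UNIT_TO_UM <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)

#' Convert a concentration to micromolar
#'
#' Exact power-of-ten conversion for molar units. Mass-per-volume or unknown
#' units are unsupported: the record is ambiguous and the caller drops it.
#'
#' @param value numeric vector of concentrations.
#' @param unit character vector of units; supported: `M`, `mM`, `uM` (also
#'   written with a micro sign), `nM`, `pM`.
#' @return numeric vector in micromolar; `NA` (with a warning) for
#'   unsupported units.
#' @export
convert_to_micromolar <- function(value, unit) {
  u <- gsub("µ|μ", "u", trimws(unit))
  fac <- .UNIT_TO_UM[u]
  if (anyNA(fac[!is.na(u)])) {
    warning("unsupported unit(s): ",
            paste(unique(u[is.na(fac) & !is.na(u)]), collapse = ", "))
  }
  unname(value * fac)
}

#' Harmonize raw activity records into clean activity entries
#'
#' Applies the cleaning rules for a literature-derived evaluation corpus:
#' in vivo and cytotoxicity records are removed; cell-proliferation records
#' are called active iff proliferation exceeds the 125% threshold;
#' concentrations are converted to micromolar and adopted as the AC50 for
#' actives; inactive records receive the 1 M sentinel (`1e6` micromolar);
#' records with unsupported units or with neither an endpoint value nor an
#' activity flag are dropped as ambiguous.
#'
#' @param raw data.frame with columns `inchi`, `activity_type` (binding /
#'   agonist / antagonist), `assay_class` (binding / transactivation /
#'   proliferation / in_vivo / cytotoxicity), `value`, `unit`, `active`
#'   (logical, may be `NA`), `source_ref`.
#' @param proliferation_threshold percent proliferation above which a
#'   proliferation record is an active call (default 125).
#' @return data.frame of activity entries (`inchi`, `activity_type`,
#'   `assay_class`, `ac50`, `active`, `source_ref`, `raw_value`, `raw_unit`)
#'   with the drop log attached as attribute `"dropped"`.
#' @export
harmonize_entries <- function(raw, proliferation_threshold = 125) {
  stopifnot(all(c("inchi", "activity_type", "assay_class", "value", "unit",
                  "active", "source_ref") %in% names(raw)))
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  active <- as.logical(raw$active)
  ac50 <- rep(NA_real_, n)

  in_scope <- raw$assay_class %in% c("binding", "transactivation", "proliferation")
  reason[!in_scope] <- ifelse(raw$assay_class[!in_scope] %in% c("in_vivo", "cytotoxicity"),
                              raw$assay_class[!in_scope], "unknown_assay_class")

  prolif <- in_scope & raw$assay_class == "proliferation"
  pv <- prolif & !is.na(raw$value) & !is.na(raw$unit) & trimws(raw$unit) == "%"
  active[pv] <- raw$value[pv] > proliferation_threshold
  reason[prolif & !pv & is.na(active)] <- "ambiguous"

  conc <- in_scope & !prolif & !is.na(raw$value)
  if (any(conc)) {
    um <- suppressWarnings(convert_to_micromolar(raw$value[conc], raw$unit[conc]))
    bad <- is.na(um) | um <= 0
    reason[which(conc)[bad]] <- "ambiguous_unit"
    ac50[which(conc)[!bad]] <- um[!bad]
  }
  # a concentration without an activity flag: adopt active iff below sentinel
  flagless <- is.na(active) & !is.na(ac50)
  active[flagless] <- ac50[flagless] < INACTIVE_AC50_UM
  reason[is.na(reason) & is.na(active)] <- "ambiguous"

  keep <- is.na(reason)
  out <- data.frame(inchi = raw$inchi[keep],
                    activity_type = raw$activity_type[keep],
                    assay_class = raw$assay_class[keep],
                    ac50 = ac50[keep],
                    active = active[keep],
                    source_ref = raw$source_ref[keep],
                    raw_value = raw$value[keep],
                    raw_unit = raw$unit[keep],
                    stringsAsFactors = FALSE)
  out$ac50[!out$active] <- INACTIVE_AC50_UM
  dropped <- data.frame(row = which(!keep), inchi = raw$inchi[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Categorical reference set from harmonized entries
#'
#' Rule 1: per (chemical, activity type) group, if the minority-call fraction
#' strictly exceeds `max_disagreement` the group is removed (logged with its
#' disagreement); otherwise the majority call is assigned. Rule 2: an active
#' agonist or antagonist becomes an active binder when no binding call
#' survived. Rule 3: a chemical inactive as both agonist and antagonist
#' becomes an inactive binder when no binding call survived. Propagation
#' never overwrites an observed binding reference.
#'
#' @param entries data.frame from [harmonize_entries()].
#' @param max_disagreement removal threshold on the minority fraction
#'   (default 0.20, strict inequality).
#' @return list with `reference` (inchi, activity_type, active, n_sources,
#'   provenance) and `removed` (inchi, activity_type, disagreement).
#' @export
build_categorical_reference <- function(entries, max_disagreement = 0.20) {
  if (nrow(entries) == 0) {
    return(list(reference = data.frame(inchi = character(0),
                                       activity_type = character(0),
                                       active = logical(0),
                                       n_sources = integer(0),
                                       provenance = character(0)),
                removed = data.frame(inchi = character(0),
                                     activity_type = character(0),
                                     disagreement = numeric(0))))
  }
  key <- interaction(entries$inchi, entries$activity_type, drop = TRUE)
  grp <- split(entries, key)
  rows <- lapply(grp, function(g) {
    frac_active <- mean(g$active)
    minority <- min(frac_active, 1 - frac_active)
    data.frame(inchi = g$inchi[1], activity_type = g$activity_type[1],
               active = frac_active > 0.5,
               n_sources = length(unique(g$source_ref)),
               disagreement = minority, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$inchi, tab$activity_type), , drop = FALSE]
  removed <- tab[tab$disagreement > max_disagreement,
                 c("inchi", "activity_type", "disagreement"), drop = FALSE]
  ref <- tab[tab$disagreement <= max_disagreement, , drop = FALSE]
  ref$provenance <- "observed"

  # rules 2 and 3: binding propagation from agonist/antagonist calls
  has_binding <- unique(ref$inchi[ref$activity_type == "binding"])
  aa <- ref[ref$activity_type %in% c("agonist", "antagonist") &
              !(ref$inchi %in% has_binding), , drop = FALSE]
  prop <- lapply(split(aa, aa$inchi), function(g) {
    if (any(g$active)) {
      data.frame(inchi = g$inchi[1], activity_type = "binding", active = TRUE,
                 n_sources = max(g$n_sources), disagreement = 0,
                 provenance = "propagated_rule2", stringsAsFactors = FALSE)
    } else if (all(c("agonist", "antagonist") %in% g$activity_type)) {
      data.frame(inchi = g$inchi[1], activity_type = "binding", active = FALSE,
                 n_sources = max(g$n_sources), disagreement = 0,
                 provenance = "propagated_rule3", stringsAsFactors = FALSE)
    } else NULL
  })
  prop <- do.call(rbind, prop[!vapply(prop, is.null, logical(1))])
  out <- rbind(ref, prop)
  out <- out[order(out$inchi, out$activity_type),
             c("inchi", "activity_type", "active", "n_sources", "provenance"),
             drop = FALSE]
  rownames(out) <- NULL
  rownames(removed) <- NULL
  list(reference = out, removed = removed)
}

#' Bin an AC50 (micromolar) into the five potency classes
#'
#' Strong < 0.09; moderate in [0.09, 0.18); weak in [0.18, 20);
#' very weak in [20, 800]; inactive > 800 (the 1 M sentinel falls here).
#'
#' @param ac50 numeric vector, micromolar, strictly positive.
#' @param thresholds numeric vector `c(strong, moderate, weak, very_weak)`
#'   upper bounds in micromolar.
#' @return factor with ordered levels inactive < very_weak < weak < moderate
#'   < strong.
#' @export
classify_potency <- function(ac50, thresholds = c(0.09, 0.18, 20, 800)) {
  if (any(!is.na(ac50) & ac50 <= 0)) stop("AC50 values must be positive")
  cls <- ifelse(is.na(ac50), NA_character_,
         ifelse(ac50 < thresholds[1], "strong",
         ifelse(ac50 < thresholds[2], "moderate",
         ifelse(ac50 < thresholds[3], "weak",
         ifelse(ac50 <= thresholds[4], "very_weak", "inactive")))))
  factor(cls, levels = POTENCY_LEVELS, ordered = TRUE)
}

#' Numeric score of a potency class
#'
#' inactive 0, very weak 0.25, weak 0.5, moderate 0.75, strong 1.
#' @param class character or factor of potency classes.
#' @return numeric vector in \[0, 1\].
#' @export
potency_score <- function(class) {
  (match(as.character(class), POTENCY_LEVELS) - 1) / 4
}

#' Potency class from an average score
#'
#' Strong > 0.75; moderate (0.5, 0.75]; weak (0.25, 0.5]; very weak
#' (0, 0.25]; inactive = 0.
#' @param avg_score numeric in \[0, 1\].
#' @return ordered factor of potency classes.
#' @export
class_from_score <- function(avg_score) {
  cls <- ifelse(is.na(avg_score), NA_character_,
         ifelse(avg_score > 0.75, "strong",
         ifelse(avg_score > 0.5, "moderate",
         ifelse(avg_score > 0.25, "weak",
         ifelse(avg_score > 0, "very_weak", "inactive")))))
  factor(cls, levels = POTENCY_LEVELS, ordered = TRUE)
}

#' Merge per-source potency classes by score averaging
#'
#' @param source_classes non-empty vector of potency classes.
#' @return list with `avg_score` (arithmetic mean of class scores) and
#'   `class` (merged class from [class_from_score()]).
#' @export
score_and_merge <- function(source_classes) {
  if (length(source_classes) == 0) stop("empty class list")
  avg <- mean(potency_score(source_classes))
  list(avg_score = avg, class = class_from_score(avg))
}

#' Median of log10-transformed concentrations
#' @param ac50_values positive numeric vector (micromolar).
#' @return the median of `log10(ac50_values)`.
#' @export
log10_median <- function(ac50_values) {
  if (length(ac50_values) == 0) stop("empty value list")
  if (any(ac50_values <= 0)) stop("AC50 values must be positive")
  stats::median(log10(ac50_values))
}

#' Potency reference set from harmonized entries
#'
#' Each entry's AC50 is binned into the five classes; per (chemical, activity
#' type) the class scores are averaged and mapped back to a merged class.
#' The log10-median of the entry AC50 values is carried as a descriptive
#' field. By default groups removed by the categorical 20% disagreement rule
#' are excluded.
#'
#' @param entries data.frame from [harmonize_entries()].
#' @param max_disagreement categorical removal threshold used to exclude
#'   discordant groups (set `NULL` to keep all groups).
#' @return data.frame (inchi, activity_type, potency_class, avg_score,
#'   log10_median_uM, n_sources).
#' @export
build_potency_reference <- function(entries, max_disagreement = 0.20) {
  ent <- entries[!is.na(entries$ac50), , drop = FALSE]
  if (!is.null(max_disagreement)) {
    rem <- build_categorical_reference(entries, max_disagreement)$removed
    if (nrow(rem) > 0) {
      bad <- paste(rem$inchi, rem$activity_type)
      ent <- ent[!(paste(ent$inchi, ent$activity_type) %in% bad), , drop = FALSE]
    }
  }
  if (nrow(ent) == 0) {
    return(data.frame(inchi = character(0), activity_type = character(0),
                      potency_class = character(0), avg_score = numeric(0),
                      log10_median_uM = numeric(0), n_sources = integer(0)))
  }
  key <- interaction(ent$inchi, ent$activity_type, drop = TRUE)
  rows <- lapply(split(ent, key), function(g) {
    sm <- score_and_merge(classify_potency(g$ac50))
    data.frame(inchi = g$inchi[1], activity_type = g$activity_type[1],
               potency_class = as.character(sm$class), avg_score = sm$avg_score,
               log10_median_uM = log10_median(g$ac50),
               n_sources = length(unique(g$source_ref)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inchi, out$activity_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct source counts per (chemical, activity type)
#' @param entries data.frame with `inchi`, `activity_type`, `source_ref`.
#' @return data.frame (inchi, activity_type, n_sources).
#' @export
count_sources <- function(entries) {
  if (nrow(entries) == 0) {
    return(data.frame(inchi = character(0), activity_type = character(0),
                      n_sources = integer(0)))
  }
  key <- interaction(entries$inchi, entries$activity_type, drop = TRUE)
  rows <- lapply(split(entries, key), function(g) {
    data.frame(inchi = g$inchi[1], activity_type = g$activity_type[1],
               n_sources = length(unique(g$source_ref)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$inchi, out$activity_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
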