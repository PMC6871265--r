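#' Bracket estimate container
#'
#' A minimum constraint plus a soft maximum at a stated confidence, with an
#' unbiased point estimate in between.
#'
#' @param min_age Hard minimum in Ma.
#' @param soft_max_age Soft maximum in Ma (holds at confidence
#'   \code{confidence}, not absolutely).
#' @param confidence Confidence level in (0, 1).
#' @param point_estimate Unbiased point estimate in Ma.
#' @param method Label of the method that produced the soft maximum.
#' @param notes Free text.
#' @return An object of class \code{bracket_estimate}.
#' @export
bracket_estimate <- function(min_age, soft_max_age, confidence,
                             point_estimate, method = "", notes = "") {
  check_prob(confidence, "confidence", allow_zero = FALSE)
  if (!(min_age <= point_estimate && point_estimate <= soft_max_age))
    fb_stop("need min_age <= point_estimate <= soft_max_age; got ",
            min_age, " / ", point_estimate, " / ", soft_max_age)
  structure(list(min_age = min_age, soft_max_age = soft_max_age,
                 confidence = confidence, point_estimate = point_estimate,
                 method = method, notes = notes),
            class = "bracket_estimate")
}

#' @export
print.bracket_estimate <- function(x, ...) {
  cat(sprintf("<bracket: min %.1f Ma, point %.1f Ma, soft max %.1f Ma at C = %g [%s]>\n",
              x$min_age, x$point_estimate, x$soft_max_age, x$confidence,
              x$method))
  invisible(x)
}

#' Taphonomic control occurrences
#'
#' Occurrences of control taxa -- groups with preservation potential similar
#' to the focal lineage -- whose presence in rocks older than the focal FAD
#' argues that the focal taxon's absence there is real.
#'
#' @param control_taxon Character labels.
#' @param age_older_ma,age_younger_ma Age interval bounds in Ma.
#' @param region Character region labels.
#' @param environment Optional environment labels.
#' @return A validated data frame of class \code{control_occurrences}.
#' @export
control_occurrences <- function(control_taxon, age_older_ma, age_younger_ma,
                                region = NA_character_,
                                environment = NA_character_) {
  df <- data.frame(control_taxon = as.character(control_taxon),
                   age_older_ma = as.numeric(age_older_ma),
                   age_younger_ma = as.numeric(age_younger_ma),
                   region = as.character(region),
                   environment = as.character(environment),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$age_older_ma) | is.na(df$age_younger_ma) |
               df$age_younger_ma < 0 | df$age_older_ma < df$age_younger_ma)
  if (length(bad))
    fb_stop("invalid control age interval at row(s) ",
            paste(bad, collapse = ", "))
  class(df) <- c("control_occurrences", "data.frame")
  df
}

#' Apomorphy-gated minimum age constraint
#'
#' The minimum constraint on a divergence time must rest on positive
#' morphological evidence: only occurrences documenting a diagnostic
#' apomorphy of the lineage qualify. The hard minimum is the YOUNGER dating
#' endpoint of the oldest such occurrence (a minimum cannot be overstated);
#' the full dating interval is reported as an envelope.
#'
#' @param record A [lineage_record()].
#' @return A list with \code{min_ma} (hard minimum; \code{NA} if no
#'   apomorphy-documented occurrence exists), \code{envelope}
#'   \code{c(younger =, older =)} and \code{valid} (logical). The no-valid
#'   case is explicit, never a silent fallback to undiagnostic material.
#' @export
min_constraint <- function(record) {
  stopifnot(inherits(record, "lineage_record"))
  occ <- record$occurrences[record$occurrences$apomorphy, , drop = FALSE]
  if (!nrow(occ)) {
    fb_log("no apomorphy-documented occurrence for '", record$lineage_id,
           "': no valid minimum", level = "WARN")
    return(list(min_ma = NA_real_, envelope = c(younger = NA_real_,
                                                older = NA_real_),
                valid = FALSE))
  }
  oldest <- occ[which.max(occ$age_older_ma), , drop = FALSE]
  list(min_ma = oldest$age_younger_ma,
       envelope = c(younger = oldest$age_younger_ma,
                    older = oldest$age_older_ma),
       valid = TRUE)
}

#' Taphonomic-control soft maximum
#'
#' Control occurrences older than the focal FAD indicate that suitable
#' fossil-bearing rocks exist in which the focal taxon is absent -- evidence
#' that it had not yet evolved. Two bounds are returned: the base (older
#' endpoint) of the youngest qualifying control interval (the "reasonable"
#' soft maximum) and the base of the oldest qualifying control (a stricter,
#' more certain bracket).
#'
#' @param record Focal [lineage_record()].
#' @param controls A [control_occurrences()] data frame.
#' @param same_region Require controls from the focal record's region(s)
#'   (default \code{TRUE}; rows with missing region never match).
#' @param environment Optional environment label the controls must carry.
#' @param k Minimum number of qualifying control horizons (default 1).
#' @return A list with \code{soft_max_ma}, \code{strict_max_ma},
#'   \code{n_controls} and \code{valid}. When no (or fewer than \code{k})
#'   controls qualify, both bounds are \code{NA} and \code{valid} is
#'   \code{FALSE} -- an explicit "no taphonomic maximum".
#' @export
taphonomic_max <- function(record, controls, same_region = TRUE,
                           environment = NULL, k = 1L) {
  stopifnot(inherits(record, "lineage_record"))
  controls <- as.data.frame(controls)
  k <- check_count(k, "k", 1L)
  fad <- record$fad_ma
  keep <- controls$age_older_ma > fad
  if (same_region) {
    regions <- unique(stats::na.omit(record$occurrences$region))
    keep <- keep & !is.na(controls$region) & controls$region %in% regions
  }
  if (!is.null(environment))
    keep <- keep & !is.na(controls$environment) &
      controls$environment == environment
  qualifying <- controls[keep, , drop = FALSE]
  if (nrow(qualifying) < k) {
    fb_log("taphonomic_max: ", nrow(qualifying), " qualifying control(s), ",
           "policy requires >= ", k, "; no taphonomic maximum", level = "WARN")
    return(list(soft_max_ma = NA_real_, strict_max_ma = NA_real_,
                n_controls = nrow(qualifying), valid = FALSE))
  }
  list(soft_max_ma = min(qualifying$age_older_ma),
       strict_max_ma = max(qualifying$age_older_ma),
       n_controls = nrow(qualifying), valid = TRUE)
}

#' Successive-outgroup FAD soft maximum
#'
#' The informal rule of using the FAD of a more inclusive clade as a soft
#' maximum on a nested focal taxon's time of origin: older rocks yield only
#' successively more plesiomorphic relatives, suggesting the focal group had
#' not yet evolved.
#'
#' @param focal Focal [lineage_record()].
#' @param inclusive_clade_fad FAD of the more inclusive clade in Ma.
#' @return The soft maximum in Ma (the inclusive clade's FAD, validated).
#' @export
outgroup_fad_max <- function(focal, inclusive_clade_fad) {
  stopifnot(inherits(focal, "lineage_record"))
  check_pos(inclusive_clade_fad, "inclusive_clade_fad")
  if (inclusive_clade_fad < focal$fad_ma)
    fb_stop("inclusive clade FAD (", inclusive_clade_fad,
            " Ma) is younger than the focal FAD (", focal$fad_ma,
            " Ma): inconsistent data")
  if (inclusive_clade_fad == focal$fad_ma)
    fb_warn("inclusive clade FAD equals the focal FAD: degenerate bracket")
  inclusive_clade_fad
}

#' Coalescence adjustment of DNA-based divergence times
#'
#' A calibrated DNA estimate measures the coalescence of the sampled loci,
#' which predates the population divergence: \code{T_DNA = T_Divergence +
#' T_Coalescence}. This removes the coalescent component.
#'
#' @param T_DNA DNA-based estimate in Ma.
#' @param T_Coalescence Coalescence time in Ma, \code{0 <= T_Coalescence <=
#'   T_DNA}.
#' @return \code{T_Divergence = T_DNA - T_Coalescence} in Ma.
#' @export
coalescence_adjust <- function(T_DNA, T_Coalescence) {
  check_pos(T_DNA, "T_DNA", strict = FALSE)
  check_pos(T_Coalescence, "T_Coalescence", strict = FALSE)
  if (T_Coalescence > T_DNA)
    fb_stop("T_Coalescence (", T_Coalescence, ") exceeds T_DNA (", T_DNA, ")")
  T_DNA - T_Coalescence
}

#' Apomorphy-lag widening of a soft maximum
#'
#' Fossil-based soft maxima bound the origin of the first fossilizable
#' apomorphy, not the divergence itself. The lag between divergence and
#' first apomorphy is at most about one average paleontological species
#' duration (about 2.3 Myr for Cenozoic mammals, ~15 Myr for cycads), since
#' that is roughly how long the first diagnosable morphology takes to
#' evolve; rapid early morphological change only shortens it. Adding the
#' duration therefore widens the apomorphy bound into an upper bound on the
#' divergence time.
#'
#' @param soft_max_on_first_apomorphy Soft maximum on the first apomorphy's
#'   origin, in Ma.
#' @param mean_species_duration Average species duration in Myr (>= 0).
#' @return Widened soft maximum on the divergence time, in Ma.
#' @export
apomorphy_lag_bound <- function(soft_max_on_first_apomorphy,
                                mean_species_duration) {
  check_pos(soft_max_on_first_apomorphy, "soft_max_on_first_apomorphy")
  check_pos(mean_species_duration, "mean_species_duration", strict = FALSE)
  soft_max_on_first_apomorphy + mean_species_duration
}

#' Fossil-record quality metric Q
#'
#' The proportion of extant taxa also found in the fossil record, a simple
#' index of record quality.
#'
#' @param extant_total Number of extant taxa (>= 1).
#' @param extant_with_fossils Number of those with a fossil record.
#' @return \code{extant_with_fossils / extant_total}, in \code{[0, 1]}.
#' @export
q_metric <- function(extant_total, extant_with_fossils) {
  extant_total <- check_count(extant_total, "extant_total", 1L)
  extant_with_fossils <- check_count(extant_with_fossils,
                                     "extant_with_fossils", 0L)
  if (extant_with_fossils > extant_total)
    fb_stop("extant_with_fossils exceeds extant_total")
  extant_with_fossils / extant_total
}

#' Expected number of preserved fossil species
#'
#' Even a tiny Q still implies many potential calibration fossils once
#' species turnover is accounted for: the expected count is
#' \code{extant * Q * turnover_ratio}, where the turnover ratio is the
#' number of extinct species per extant one over the clade's history.
#'
#' @param extant Number of extant species.
#' @param Q Fossil-record quality ([q_metric()]).
#' @param turnover_ratio Extinct-to-extant species ratio.
#' @param rounding \code{"raw"} (default) or \code{"hundred"} (report policy:
#'   round to the nearest hundred).
#' @return Expected fossil species count.
#' @examples
#' expected_fossil_species(5500, 0.01, 26)                      # 1430
#' expected_fossil_species(5500, 0.01, 26, rounding = "hundred") # 1400
#' @export
expected_fossil_species <- function(extant, Q, turnover_ratio,
                                    rounding = c("raw", "hundred")) {
  rounding <- match.arg(rounding)
  check_pos(extant, "extant", strict = FALSE)
  check_pos(Q, "Q", strict = FALSE)
  check_pos(turnover_ratio, "turnover_ratio", strict = FALSE)
  out <- extant * Q * turnover_ratio
  if (rounding == "hundred") out <- round(out / 100) * 100
  out
}

#' Assemble a per-node divergence-time bracket
#'
#' Collects the apomorphy-gated minimum and all available soft-maximum
#' candidates for one node, applies optional coalescence and apomorphy-lag
#' adjustments, and reports a final envelope. Candidates are never averaged:
#' each is reported with its method label, and the final maximum is either
#' the least restrictive candidate (default) or a user-selected method.
#'
#' @param node Node label.
#' @param min A [min_constraint()] result (must be valid).
#' @param soft_max_candidates Named numeric vector of soft maxima in Ma, one
#'   per method (e.g. \code{c(ci = 12.8, taphonomic = 10)}).
#' @param point_estimate Optional unbiased point estimate in Ma.
#' @param select Method name whose maximum becomes the final envelope, or
#'   \code{"least_restrictive"} (default: the largest candidate).
#' @param mean_species_duration If supplied, every candidate is widened by
#'   [apomorphy_lag_bound()] before selection (adjustment is logged).
#' @param T_Coalescence Reserved for DNA-side comparisons; recorded in the
#'   adjustment log.
#' @return An object of class \code{node_bracket}: list with \code{node},
#'   \code{min_ma}, \code{min_envelope}, \code{soft_max} (per-method table),
#'   \code{adjustments}, \code{final} \code{c(min =, max =)} and
#'   \code{point_estimate}. A bracket with no applicable maximum is returned
#'   open-ended and flagged.
#' @export
assemble_bracket <- function(node, min, soft_max_candidates = numeric(),
                             point_estimate = NA_real_,
                             select = "least_restrictive",
                             mean_species_duration = NULL,
                             T_Coalescence = NULL) {
  if (!isTRUE(min$valid)) fb_stop("a valid minimum constraint is required")
  adjustments <- character()
  cand <- soft_max_candidates
  if (!is.null(mean_species_duration) && length(cand)) {
    cand <- vapply(cand, apomorphy_lag_bound,
                   numeric(1), mean_species_duration = mean_species_duration)
    adjustments <- c(adjustments,
                     sprintf("apomorphy lag: all maxima widened by %g Myr",
                             mean_species_duration))
  }
  if (!is.null(T_Coalescence))
    adjustments <- c(adjustments,
                     sprintf("coalescence: DNA estimates comparable after subtracting %g Myr",
                             T_Coalescence))

  if (!length(cand)) {
    fb_log("no soft maximum applicable for node '", node,
           "': open-ended bracket", level = "WARN")
    final_max <- NA_real_
    selected <- NA_character_
  } else {
    if (identical(select, "least_restrictive")) {
      selected <- names(cand)[which.max(cand)]
    } else {
      if (!select %in% names(cand))
        fb_stop("selected method '", select, "' not among candidates: ",
                paste(names(cand), collapse = ", "))
      selected <- select
    }
    final_max <- unname(cand[[selected]])
    if (min$min_ma > final_max)
      fb_stop("minimum (", min$min_ma, " Ma) exceeds selected maximum (",
              final_max, " Ma): inconsistent data")
    adjustments <- c(adjustments,
                     sprintf("final maximum: '%s' (%s)", selected,
                             if (identical(select, "least_restrictive"))
                               "least restrictive" else "user-selected"))
  }

  structure(list(
    node = node,
    min_ma = min$min_ma,
    min_envelope = min$envelope,
    soft_max = data.frame(method = names(cand),
                          value_ma = unname(cand),
                          stringsAsFactors = FALSE),
    point_estimate = point_estimate,
    adjustments = adjustments,
    selected_method = selected,
    final = c(min = min$min_ma, max = final_max),
    open_ended = !length(cand)
  ), class = "node_bracket")
}

#' @export
print.node_bracket <- function(x, ...) {
  cat(sprintf("<node_bracket '%s': min %.1f Ma, max %s>\n", x$node, x$min_ma,
              if (is.na(x$final[["max"]])) "open-ended"
              else sprintf("%.1f Ma [%s]", x$final[["max"]],
                           x$selected_method)))
  if (nrow(x$soft_max))
    for (i in seq_len(nrow(x$soft_max)))
      cat(sprintf("  candidate %-14s %.1f Ma\n", x$soft_max$method[i],
                  x$soft_max$value_ma[i]))
  for (a in x$adjustments) cat("  ", a, "\n", sep = "")
  invisible(x)
}
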