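## Evidence combination: per-channel classes under the original
## class-combining rules and the additive point system, the two-channel
## merge, and the cross-channel rule summarization.

#' Select the applied evidence feeding one channel
#'
#' A channel's classification combines `general` evidence with the
#' channel's own evidence.  A code applied in both contributes once, at
#' the stronger strength.
#'
#' @param results List of [rule_result()] from [run_rules()].
#' @param channel `"protein"` or `"splicing"`.
#' @return Data frame of applied evidence with columns `code`,
#'   `strength`, `direction`.
#' @export
channel_select <- function(results, channel = c("protein", "splicing")) {
  channel <- match.arg(channel)
  sel <- Filter(function(r) r$status == "applied" &&
                  r$channel %in% c("general", channel), results)
  if (!length(sel))
    return(data.frame(code = character(), strength = character(),
                      direction = character(), stringsAsFactors = FALSE))
  df <- data.frame(
    code = vapply(sel, `[[`, "", "code"),
    strength = vapply(sel, `[[`, "", "strength"),
    stringsAsFactors = FALSE)
  rank <- match(df$strength, hc_strengths())
  df <- df[order(df$code, -rank), ]
  df <- df[!duplicated(df$code), ]
  df$direction <- vapply(df$code, rule_direction, "")
  rownames(df) <- NULL
  df
}

strength_counts <- function(applied) {
  cnt <- function(dir, s) sum(applied$direction == dir &
                                applied$strength == s)
  list(pa = cnt("pathogenic", "stand_alone"),  # unused; defensive
       pvs = cnt("pathogenic", "very_strong"),
       ps = cnt("pathogenic", "strong"),
       pm = cnt("pathogenic", "moderate"),
       pp = cnt("pathogenic", "supporting"),
       ba = cnt("benign", "stand_alone"),
       bvs = cnt("benign", "very_strong"),
       bs = cnt("benign", "strong"),
       bm = cnt("benign", "moderate"),
       bp = cnt("benign", "supporting"))
}

#' Original class-combining rules
#'
#' Implements the published combination table on strength counts, with
#' criteria counted at their (possibly modulated) applied strength.
#' Benign evidence applied above strong counts with the strong
#' criteria; benign moderate counts with the supporting criteria.
#' Stand-alone benign evidence (BA1) short-circuits to benign.
#' Simultaneous qualification on both sides yields VUS (conflict),
#' except under the BA1 short-circuit.
#'
#' @param applied Data frame from [channel_select()] (columns `code`,
#'   `strength`, `direction`).
#' @return A 5-tier class label.
#' @export
classify_acmg_combining <- function(applied) {
  k <- strength_counts(applied)
  if (k$ba >= 1) return("benign")

  pvs <- k$pvs; ps <- k$ps; pm <- k$pm; pp <- k$pp
  bs <- k$bs + k$bvs; bp <- k$bp + k$bm

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp == 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs == 1 && pm == 1) ||
    (ps == 1 && pm >= 1 && pm <= 2) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- bs >= 2
  likely_benign <- (bs == 1 && bp == 1) || bp >= 2

  patho_side <- pathogenic || likely_pathogenic
  benign_side <- benign || likely_benign
  if (patho_side && benign_side) return("vus")
  if (pathogenic) return("pathogenic")
  if (likely_pathogenic) return("likely_pathogenic")
  if (benign) return("benign")
  if (likely_benign) return("likely_benign")
  "vus"
}

#' Point-based classification
#'
#' Sums signed point values (supporting 1, moderate 2, strong 4, very
#' strong 8; benign negative) and maps the sum onto the configured
#' class bounds.  Stand-alone benign evidence (BA1) short-circuits the
#' class to benign; the reported score still sums the remaining
#' evidence.
#'
#' @inheritParams classify_acmg_combining
#' @param points Strength-to-points map.
#' @param bounds Class bounds (`pathogenic_min`, `likely_pathogenic_min`,
#'   `benign_max`).
#' @return List with `point_score` and `point_class`.
#' @export
classify_point_based <- function(applied, points = default_points(),
                                 bounds = default_point_bounds()) {
  standalone <- applied$strength == "stand_alone"
  score <- 0L
  for (i in which(!standalone))
    score <- score + point_value(applied$strength[i], applied$direction[i],
                                 points)
  cls <- if (any(standalone & applied$direction == "benign")) {
    "benign"
  } else {
    point_class(score, bounds)
  }
  list(point_score = as.integer(score), point_class = cls)
}

point_class <- function(score, bounds = default_point_bounds()) {
  if (score >= bounds$pathogenic_min) "pathogenic"
  else if (score >= bounds$likely_pathogenic_min) "likely_pathogenic"
  else if (score >= 0) "vus"
  else if (score > bounds$benign_max) "likely_benign"
  else "benign"
}

default_point_bounds <- function() hc_defaults()$point_class_bounds

#' Merge the protein and splicing classifications
#'
#' When one channel is VUS and the other is not, the non-VUS class is
#' final.  A benign-side class together with a pathogenic-side class
#' yields VUS.  Two classes on the same side merge to the more extreme
#' tier.  Symmetric in its arguments.
#'
#' @param protein_class,splicing_class 5-tier class labels.
#' @return The final 5-tier class.
#' @export
merge_channels <- function(protein_class, splicing_class) {
  cl <- hc_classes()
  a <- chk_enum(protein_class, cl, "protein_class")
  b <- chk_enum(splicing_class, cl, "splicing_class")
  if (a == "vus") return(b)
  if (b == "vus") return(a)
  side <- function(x) if (x %in% c("benign", "likely_benign")) -1 else 1
  if (side(a) != side(b)) return("vus")
  ia <- match(a, cl); ib <- match(b, cl)
  if (side(a) < 0) cl[min(ia, ib)] else cl[max(ia, ib)]
}

#' Summarize rule calls across channels
#'
#' For criteria with both a protein and a splicing implementation, a
#' pathogenic criterion counts as called when either implementation is
#' applied; a benign criterion counts as called only when both are.
#' Single-channel and general criteria count as called when applied.
#'
#' @param results List of [rule_result()] from [run_rules()].
#' @return Named logical vector keyed by criterion code.
#' @export
summarize_rule_calls <- function(results) {
  tab <- results_table(results)
  codes <- automated_codes()
  called <- logical(length(codes))
  names(called) <- codes
  for (code in codes) {
    hit <- tab$status[tab$code == code] == "applied"
    if (code %in% dual_channel_codes()) {
      called[code] <- if (rule_direction(code) == "pathogenic")
        any(hit) else all(hit) && length(hit) > 0
    } else {
      called[code] <- any(hit)
    }
  }
  called
}

#' Classify an annotated variant
#'
#' Runs every registered criterion, combines the evidence per channel
#' under both classification systems, merges the two channels into a
#' final class, and summarizes cross-channel rule calls.
#'
#' @param variant An [annotated_variant()].
#' @param scheme A `scheme_config` (defaults to the scheme selected for
#'   the variant's gene).
#' @param merge_system Which per-channel class feeds the merge:
#'   `"points"` (default) or `"acmg"`.
#' @return A `classification_report`: per-channel classifications
#'   (`protein`, `splicing`), `final_class`, `rule_calls`, and
#'   `all_results`.
#' @export
classify_variant <- function(variant,
                             scheme = select_scheme(variant$variant$gene),
                             merge_system = c("points", "acmg")) {
  merge_system <- match.arg(merge_system)
  results <- run_rules(variant, scheme)
  chans <- lapply(c(protein = "protein", splicing = "splicing"),
                  function(ch) {
    applied <- channel_select(results, ch)
    pts <- classify_point_based(applied, scheme$points,
                                scheme$point_class_bounds)
    acmg <- classify_acmg_combining(applied)
    structure(list(channel = ch, acmg_class = acmg,
                   point_score = pts$point_score,
                   point_class = pts$point_class,
                   applied = applied),
              class = "channel_classification")
  })
  pick <- function(cc) if (merge_system == "points") cc$point_class
                       else cc$acmg_class
  final <- merge_channels(pick(chans$protein), pick(chans$splicing))
  structure(list(protein = chans$protein, splicing = chans$splicing,
                 final_class = final,
                 merge_system = merge_system,
                 rule_calls = summarize_rule_calls(results),
                 all_results = results,
                 scheme_id = scheme$scheme_id),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("ACMG/AMP classification (scheme: %s)\n", x$scheme_id))
  cat(sprintf("  protein:  %s (points %+d, combining %s)\n",
              x$protein$point_class, x$protein$point_score,
              x$protein$acmg_class))
  cat(sprintf("  splicing: %s (points %+d, combining %s)\n",
              x$splicing$point_class, x$splicing$point_score,
              x$splicing$acmg_class))
  cat(sprintf("  final:    %s (merged %s classes)\n", x$final_class,
              x$merge_system))
  called <- names(x$rule_calls)[x$rule_calls]
  cat(sprintf("  called criteria: %s\n",
              if (length(called)) paste(called, collapse = ", ") else "none"))
  invisible(x)
}
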