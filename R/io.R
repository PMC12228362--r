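## JSON interchange for annotated variants and classification reports,
## and minimal VCF export.

av_from_list <- function(x, strict = FALSE, where = "") {
  need <- function(field) {
    if (is.null(x[[field]]))
      stop_hc("SCHEMA_VIOLATION",
              sprintf("%smissing required field '%s'", where, field))
    x[[field]]
  }
  v <- need("variant")
  variant <- variant_record(v$chrom, v$pos, v$ref, v$alt,
                            gene = v$gene %||% NA_character_,
                            transcript = v$transcript %||% NA_character_)
  txl <- need("tx")
  tx <- do.call(transcript_annotation, txl)
  pop <- if (is.null(x$pop)) {
    if (strict)
      stop_hc("SCHEMA_VIOLATION", sprintf("%smissing 'pop'", where))
    warning(sprintf("%srecord lacks 'pop'; assuming no frequency data and inadequate coverage",
                    where), call. = FALSE)
    population_data(coverage_ok = FALSE)
  } else do.call(population_data, x$pop)
  scores <- if (is.null(x$scores)) prediction_scores()
            else do.call(prediction_scores, x$scores)
  prior <- if (is.null(x$prior)) prior_classification()
           else do.call(prior_classification, x$prior)
  assay <- if (is.null(x$assay)) functional_assay()
           else do.call(functional_assay, x$assay)
  coseg <- if (is.null(x$coseg)) cosegregation_data()
           else do.call(cosegregation_data, x$coseg)
  rna <- if (is.null(x$rna)) rna_evidence() else do.call(rna_evidence, x$rna)
  known <- c("variant", "tx", "pop", "scores", "prior", "assay", "coseg",
             "rna")
  annotated_variant(variant, tx, pop, scores, prior, assay, coseg, rna,
                    extra = x[setdiff(names(x), known)])
}

av_to_list <- function(av) {
  drop_null <- function(l) l[!vapply(l, is.null, TRUE)]
  c(list(variant = drop_null(unclass(av$variant)),
         tx = drop_null(unclass(av$tx)),
         pop = drop_null(unclass(av$pop)),
         scores = drop_null(unclass(av$scores)),
         prior = unclass(av$prior),
         assay = unclass(av$assay),
         coseg = drop_null(unclass(av$coseg)),
         rna = unclass(av$rna)),
    av$extra)
}

#' Read annotated variants from JSON
#'
#' Accepts JSON Lines (one record per line, the primary interchange) or
#' a single JSON array.  Every record is validated against the
#' annotated-variant schema (shipped at
#' `inst/schema/annotated_variant.schema.json`); fields the engine does
#' not consume are preserved in a passthrough bag.  Under
#' `strict = FALSE` a record lacking the `pop` block gets conservative
#' defaults (no frequency data, inadequate coverage) with a warning;
#' malformed records raise per-record errors naming the line.
#'
#' @param path JSON or JSON Lines file.
#' @param strict Fail on any schema deviation instead of defaulting.
#' @return List of [annotated_variant()].
#' @export
read_annotated_json <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  first <- substr(trimws(lines[1]), 1, 1)
  handle <- function(i, expr) {
    tryCatch(expr, error = function(e) {
      if (strict)
        stop_hc("SCHEMA_VIOLATION",
                sprintf("record %d: %s", i, conditionMessage(e)))
      warning(sprintf("record %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }
  recs <- if (first == "[") {
    jsonlite::fromJSON(paste(lines, collapse = "\n"),
                       simplifyVector = FALSE)
  } else {
    lapply(seq_along(lines), function(i)
      handle(i, jsonlite::fromJSON(lines[i], simplifyVector = FALSE)))
  }
  out <- lapply(seq_along(recs), function(i) {
    if (is.null(recs[[i]])) return(NULL)
    handle(i, av_from_list(recs[[i]], strict = strict,
                           where = sprintf("record %d: ", i)))
  })
  Filter(Negate(is.null), out)
}

#' Write annotated variants as JSON Lines
#' @param variants List of [annotated_variant()].
#' @param path Output file.
#' @export
write_annotated_json <- function(variants, path) {
  lines <- vapply(variants, function(av)
    jsonlite::toJSON(av_to_list(av), auto_unbox = TRUE, digits = NA,
                     null = "null"), character(1))
  writeLines(lines, path)
  invisible(path)
}

report_to_list <- function(av, report) {
  chan <- function(cc) list(
    acmg_class = cc$acmg_class,
    point_score = cc$point_score,
    point_class = cc$point_class,
    applied = lapply(seq_len(nrow(cc$applied)), function(i)
      list(code = cc$applied$code[i], strength = cc$applied$strength[i])))
  list(variant = list(chrom = av$variant$chrom, pos = av$variant$pos,
                      ref = av$variant$ref, alt = av$variant$alt,
                      gene = av$variant$gene),
       scheme_id = report$scheme_id,
       protein = chan(report$protein),
       splicing = chan(report$splicing),
       final_class = report$final_class,
       merge_system = report$merge_system,
       rule_calls = as.list(report$rule_calls),
       rules = lapply(report$all_results, function(r)
         list(code = r$code, channel = r$channel, status = r$status,
              strength = r$strength, comment = r$comment)))
}

#' Write a classification report document as JSON
#'
#' The document carries a schema version, provenance (scheme ids and an
#' MD5 digest of the configuration files), and one entry per variant
#' with its identity, both channel classifications, the merged final
#' class, and every rule result.
#'
#' @param variants List of [annotated_variant()].
#' @param reports List of `classification_report`, parallel to `variants`.
#' @param path Output file.
#' @param config_dir Configuration directory recorded in provenance.
#' @export
write_report_json <- function(variants, reports, path,
                              config_dir = default_config_dir()) {
  stopifnot(length(variants) == length(reports))
  cfg_files <- sort(list.files(config_dir, pattern = "\\.yaml$",
                               full.names = TRUE, recursive = TRUE))
  doc <- list(
    schema_version = "1.0",
    provenance = list(
      schemes = unique(vapply(reports, `[[`, "", "scheme_id")),
      config_hash = unname(tools::md5sum(cfg_files)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    variants = lapply(seq_along(variants), function(i)
      report_to_list(variants[[i]], reports[[i]])))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read a report document written by [write_report_json()]
#' @param path Report JSON file.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

chrom_rank <- function(chrom) {
  match(chrom, c(as.character(1:22), "X", "Y", "MT"))
}

#' Export classifications as minimal VCF
#'
#' Writes a VCFv4.2 file with one record per variant and INFO keys
#' `HC_PROT_CLASS`, `HC_SPLI_CLASS`, `HC_FINAL`, `HC_PROT_PTS`,
#' `HC_SPLI_PTS` and `HC_RULES` (comma list `code|channel|strength` of
#' applied rules), records sorted by chromosome in natural order, then
#' position.
#'
#' @inheritParams write_report_json
#' @export
write_vcf <- function(variants, reports, path) {
  stopifnot(length(variants) == length(reports), length(variants) > 0)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=hbocclassify-%s",
            as.character(utils::packageVersion("hbocclassify"))),
    '##INFO=<ID=HC_PROT_CLASS,Number=1,Type=String,Description="Protein-channel 5-tier class">',
    '##INFO=<ID=HC_SPLI_CLASS,Number=1,Type=String,Description="Splicing-channel 5-tier class">',
    '##INFO=<ID=HC_FINAL,Number=1,Type=String,Description="Merged final 5-tier class">',
    '##INFO=<ID=HC_PROT_PTS,Number=1,Type=Integer,Description="Protein-channel point score">',
    '##INFO=<ID=HC_SPLI_PTS,Number=1,Type=Integer,Description="Splicing-channel point score">',
    '##INFO=<ID=HC_RULES,Number=.,Type=String,Description="Applied rules as code|channel|strength">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- lapply(seq_along(variants), function(i) {
    v <- variants[[i]]$variant
    rep <- reports[[i]]
    applied <- Filter(function(r) r$status == "applied", rep$all_results)
    rules <- if (length(applied))
      paste(vapply(applied, function(r)
        paste(r$code, r$channel, r$strength, sep = "|"), ""),
        collapse = ",")
    else "."
    info <- sprintf("HC_PROT_CLASS=%s;HC_SPLI_CLASS=%s;HC_FINAL=%s;HC_PROT_PTS=%d;HC_SPLI_PTS=%d;HC_RULES=%s",
                    toupper(rep$protein$point_class),
                    toupper(rep$splicing$point_class),
                    toupper(rep$final_class),
                    rep$protein$point_score, rep$splicing$point_score,
                    rules)
    list(chrom = v$chrom, pos = v$pos,
         line = sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                        v$chrom, v$pos, v$ref, v$alt, info))
  })
  ord <- order(vapply(recs, function(r) chrom_rank(r$chrom), 1L),
               vapply(recs, `[[`, 1L, "pos"))
  writeLines(c(header, vapply(recs[ord], `[[`, "", "line")), path)
  invisible(path)
}
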