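## Variant curation: reference validation, minimal-representation left
## normalization, and the engine's size gate. The reference sequence is
## supplied inline as a window around the variant, so no genome files
## are needed.

#' Local reference sequence window
#'
#' @param sequence Uppercase A/C/G/T string covering the variant and at
#'   least ~50 nt of upstream context for left shifting.
#' @param window_start 1-based genomic position of the first base of
#'   `sequence`.
#' @export
reference_context <- function(sequence, window_start) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L || grepl("[^ACGT]", sequence))
    stop_hc("BAD_FIELD", "sequence must be a non-empty uppercase A/C/G/T string")
  window_start <- chk_num(window_start, "window_start", lo = 1,
                          integer = TRUE)
  structure(list(sequence = sequence,
                 window_start = as.integer(window_start)),
            class = "reference_context")
}

ctx_base <- function(ctx, pos) {
  i <- pos - ctx$window_start + 1L
  if (i < 1L || i > nchar(ctx$sequence)) return(NA_character_)
  substr(ctx$sequence, i, i)
}

ctx_substr <- function(ctx, pos, len) {
  i <- pos - ctx$window_start + 1L
  if (i < 1L || i + len - 1L > nchar(ctx$sequence)) return(NA_character_)
  substr(ctx$sequence, i, i + len - 1L)
}

#' Validate a variant record against its reference context
#'
#' Checks that the chromosome label is recognized, the alleles are
#' legal nucleotide strings, and the stated reference allele matches
#' the supplied reference sequence at the stated position.
#'
#' @param v A [variant_record()] (its constructor already enforces
#'   allele and chromosome legality; this adds the reference check).
#' @param ctx A [reference_context()] covering `v$pos .. v$pos+nchar(ref)-1`.
#' @return `v`, invisibly unchanged, on success.  Errors carry the
#'   condition classes `REF_MISMATCH`, `BAD_ALLELE` or `BAD_CHROM`.
#' @export
validate_variant <- function(v, ctx) {
  stopifnot(inherits(v, "variant_record"), inherits(ctx, "reference_context"))
  ref_here <- ctx_substr(ctx, v$pos, nchar(v$ref))
  if (is.na(ref_here))
    stop_hc("CTX_TOO_SHORT",
            "reference context does not cover the variant position")
  if (ref_here != v$ref)
    stop_hc("REF_MISMATCH",
            sprintf("stated ref '%s' at %s:%d but reference has '%s'",
                    v$ref, v$chrom, v$pos, ref_here))
  v
}

#' Left-normalize a variant to its minimal representation
#'
#' Produces the left-most minimal representation so identical variants
#' compare equal: trims the longest shared allele suffix, then the
#' shared prefix (advancing the position), and shifts pure
#' insertions/deletions leftwards through repeat tracts by repeatedly
#' exchanging the trailing shared base for the preceding reference
#' base.  Output alleles are never empty and the operation is
#' idempotent.
#'
#' @param v A validated [variant_record()].
#' @param ctx A [reference_context()] supplying upstream sequence.
#' @return The normalized `variant_record`.
#' @export
left_normalize <- function(v, ctx) {
  stopifnot(inherits(v, "variant_record"), inherits(ctx, "reference_context"))
  pos <- v$pos
  ref <- strsplit(v$ref, "")[[1]]
  alt <- strsplit(v$alt, "")[[1]]

  repeat {
    # Trim a shared last base; re-anchor on the preceding reference
    # base when one allele would become empty (the leftward shift).
    while (length(ref) && length(alt) &&
           ref[length(ref)] == alt[length(alt)]) {
      if (length(ref) == 1L || length(alt) == 1L) {
        prev <- ctx_base(ctx, pos - 1L)
        if (is.na(prev))
          stop_hc("CTX_TOO_SHORT",
                  "insufficient upstream context to left-shift the variant")
        ref <- c(prev, ref[-length(ref)])
        alt <- c(prev, alt[-length(alt)])
        pos <- pos - 1L
      } else {
        ref <- ref[-length(ref)]
        alt <- alt[-length(alt)]
      }
    }
    # Trim shared leading bases while both alleles keep >= 1 base.
    while (length(ref) > 1L && length(alt) > 1L && ref[1] == alt[1]) {
      ref <- ref[-1]
      alt <- alt[-1]
      pos <- pos + 1L
    }
    if (!(length(ref) && length(alt) &&
          ref[length(ref)] == alt[length(alt)])) break
  }

  variant_record(v$chrom, pos, paste(ref, collapse = ""),
                 paste(alt, collapse = ""), gene = v$gene,
                 transcript = v$transcript)
}

#' Engine scope gate on variant size
#'
#' The engine classifies variants up to 15 bp; the length is measured
#' on the longer allele of the normalized representation, boundary
#' inclusive.
#'
#' @param v A normalized [variant_record()].
#' @param max_len Scope bound in bp.
#' @return `"pass"` or `"out_of_scope"`.
#' @export
size_gate <- function(v, max_len = 15L) {
  stopifnot(inherits(v, "variant_record"))
  if (max(nchar(v$ref), nchar(v$alt)) <= max_len) "pass" else "out_of_scope"
}

#' Run validation, normalization and the size gate in order
#'
#' @inheritParams validate_variant
#' @return A list with the normalized record (`variant`) and the gate
#'   status (`scope`).
#' @export
curate_variant <- function(v, ctx) {
  v <- validate_variant(v, ctx)
  v <- left_normalize(v, ctx)
  list(variant = v, scope = size_gate(v))
}
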