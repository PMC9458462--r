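# Readers and writers for the external formats the pipeline touches:
# FASTA references, pileup-statistics TSV (pysamstats-style dialect),
# minimal VCF, and two-column absorbance trace CSV. All coordinates are
# 1-based inclusive; DNA input (T) is silently normalized to RNA (U).

# ---- transcript references ------------------------------------------------

#' Construct a transcript reference
#'
#' Holds a single-molecule RNA reference sequence together with its base
#' composition. DNA input (`T`) is normalized to RNA (`U`); ambiguity codes
#' are rejected.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Sequence over `A,C,G,U` (or `T`, normalized to `U`).
#' @return An object of class `transcript_ref` with fields `id`, `seq`,
#'   `length` and `base_fractions` (named fractions over A/C/G/U summing
#'   to 1).
#' @export
transcript_ref <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    format_error("transcript id must be a non-empty string")
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    format_error("empty sequence in record '%s'", id)
  seq <- normalize_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), RNA_BASES)
  if (length(bad))
    format_error("record '%s' contains non-ACGU character(s): %s",
                 id, paste(bad, collapse = ", "))
  counts <- vapply(RNA_BASES, function(b) sum(chars == b), integer(1))
  structure(
    list(id = id, seq = seq, length = length(chars),
         base_fractions = counts / length(chars)),
    class = "transcript_ref")
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat(sprintf("<transcript_ref> %s: %d nt\n", x$id, x$length))
  cat("  base fractions:",
      paste(sprintf("%s=%.3f", names(x$base_fractions), x$base_fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' Read transcript references from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet and base compositions are
#' computed. Ambiguity codes are a format error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A list of [transcript_ref()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)))
  if (length(set) == 0L) format_error("no records in FASTA '%s'", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  lapply(seq_along(set), function(i) {
    s <- as.character(set[[i]])
    if (!nzchar(s)) format_error("empty sequence in record '%s'", ids[i])
    transcript_ref(ids[i], s)
  })
}

#' Write transcript references to a FASTA file
#'
#' @param refs A `transcript_ref` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  if (inherits(refs, "transcript_ref")) refs <- list(refs)
  seqs <- Biostrings::RNAStringSet(vapply(refs, `[[`, character(1), "seq"))
  names(seqs) <- vapply(refs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---- pileup tables --------------------------------------------------------

#' Construct a per-position pileup table
#'
#' A pileup table tallies aligned base calls at each reference position:
#' depth, matches (calls of the reference base), mismatches (calls of the
#' three other canonical bases) and per-base counts. Deletions and N calls
#' never count toward matches or mismatches.
#'
#' @param ref_id Reference identifier the rows belong to.
#' @param pos 1-based positions, strictly increasing.
#' @param ref_base Reference base per position (`T` normalized to `U`).
#' @param count_A,count_C,count_G,count_U Per-base call counts.
#' @param count_N,count_del N-call and deletion counts (default 0).
#' @param depth Total reads per position; defaults to the sum of all counts.
#' @param matches,mismatches Optional externally supplied columns. When they
#'   disagree with the per-base counts, strict mode raises an error and
#'   lenient mode recomputes them from the per-base counts with a warning.
#' @param strict Logical; reconciliation mode (default `TRUE`).
#' @return A `data.frame` of class `pileup_table` with attribute `ref_id`.
#' @export
pileup_table <- function(ref_id, pos, ref_base,
                         count_A, count_C, count_G, count_U,
                         count_N = 0L, count_del = 0L,
                         depth = NULL, matches = NULL, mismatches = NULL,
                         strict = TRUE) {
  n <- length(pos)
  ref_base <- check_base(ref_base, "ref_base")
  counts <- cbind(A = rep_len(count_A, n), C = rep_len(count_C, n),
                  G = rep_len(count_G, n), U = rep_len(count_U, n))
  count_N <- rep_len(count_N, n); count_del <- rep_len(count_del, n)
  if (any(counts < 0) || any(count_N < 0) || any(count_del < 0))
    format_error("negative counts in pileup table")
  if (n && (any(diff(pos) <= 0)))
    format_error("pileup positions must be strictly increasing")
  m_calc <- counts[cbind(seq_len(n), match(ref_base, RNA_BASES))]
  mm_calc <- rowSums(counts) - m_calc
  if (!is.null(matches) || !is.null(mismatches)) {
    bad <- (!is.null(matches) && any(matches != m_calc)) ||
      (!is.null(mismatches) && any(mismatches != mm_calc))
    if (bad) {
      if (strict)
        format_error("matches/mismatches columns disagree with per-base counts (strict mode)")
      warning("matches/mismatches disagree with per-base counts; recomputed from counts",
              call. = FALSE)
    }
  }
  if (is.null(depth)) depth <- rowSums(counts) + count_N + count_del
  if (any(m_calc + mm_calc > depth))
    format_error("matches + mismatches exceed depth")
  out <- data.frame(pos = as.integer(pos), ref_base = ref_base,
                    depth = as.integer(depth),
                    matches = as.integer(m_calc),
                    mismatches = as.integer(mm_calc),
                    count_A = as.integer(counts[, "A"]),
                    count_C = as.integer(counts[, "C"]),
                    count_G = as.integer(counts[, "G"]),
                    count_U = as.integer(counts[, "U"]),
                    count_N = as.integer(count_N),
                    count_del = as.integer(count_del),
                    stringsAsFactors = FALSE)
  attr(out, "ref_id") <- ref_id
  class(out) <- c("pileup_table", "data.frame")
  out
}

#' @export
print.pileup_table <- function(x, ...) {
  cat(sprintf("<pileup_table> %s: %d positions, mean depth %.1f\n",
              attr(x, "ref_id"), nrow(x), mean(x$depth)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

PILEUP_COLS <- c("chrom", "pos", "ref", "reads_all", "matches", "mismatches",
                 "A", "C", "G", "T", "N", "deletions")

#' Read a pileup-statistics TSV
#'
#' Consumes the tab-separated per-position statistics dialect produced by
#' standard pileup-statistics tools: a header naming at least
#' `chrom, pos, ref, reads_all, matches, mismatches, A, C, G, T, N,
#' deletions`; extra columns are ignored. Rows are validated against the
#' supplied reference (position within range, reference base agreement).
#'
#' @param path Path to the TSV.
#' @param ref A [transcript_ref()] the table must be consistent with.
#' @param strict Reconciliation mode for disagreeing matches/mismatches
#'   columns; see [pileup_table()].
#' @return A [pileup_table()].
#' @export
read_pileup_tsv <- function(path, ref, strict = TRUE) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- tryCatch(utils::read.delim(path, check.names = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) format_error("malformed pileup TSV '%s': %s",
                                                  path, conditionMessage(e)))
  missing_cols <- setdiff(PILEUP_COLS, names(df))
  if (length(missing_cols))
    format_error("pileup TSV '%s' lacks column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) format_error("empty pileup table: %s", path)
  if (anyDuplicated(df$pos)) format_error("duplicate positions in '%s'", path)
  df <- df[order(df$pos), , drop = FALSE]
  if (any(df$pos < 1L) || any(df$pos > ref$length))
    format_error("position outside 1..%d for reference '%s'", ref$length, ref$id)
  ref_at <- strsplit(ref$seq, "", fixed = TRUE)[[1L]][df$pos]
  got <- normalize_rna(df$ref)
  if (any(got != ref_at))
    format_error("reference base disagreement at position %d ('%s' in table, '%s' in reference)",
                 df$pos[which(got != ref_at)[1L]],
                 got[which(got != ref_at)[1L]],
                 ref_at[which(got != ref_at)[1L]])
  pileup_table(ref_id = df$chrom[1L], pos = df$pos, ref_base = got,
               count_A = df$A, count_C = df$C, count_G = df$G, count_U = df$T,
               count_N = df$N, count_del = df$deletions,
               depth = df$reads_all,
               matches = df$matches, mismatches = df$mismatches,
               strict = strict)
}

#' Write a pileup table as TSV
#'
#' Emits the same dialect [read_pileup_tsv()] consumes (RNA `U` written as
#' `T` in the `ref` column and per-base counts), so write-then-read is the
#' identity.
#'
#' @param table A [pileup_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(table, path) {
  out <- data.frame(chrom = attr(table, "ref_id"),
                    pos = table$pos,
                    ref = chartr("U", "T", table$ref_base),
                    reads_all = table$depth,
                    matches = table$matches,
                    mismatches = table$mismatches,
                    A = table$count_A, C = table$count_C,
                    G = table$count_G, T = table$count_U,
                    N = table$count_N, deletions = table$count_del)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- minimal VCF ----------------------------------------------------------

#' Read the minimal fixed fields of a VCF
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` and `QUAL` are consumed; INFO/FORMAT
#' are ignored. Multi-allelic `ALT` entries are split into one record per
#' allele. A missing QUAL (`.`) becomes 0 with a warning and is flagged, so
#' a downstream quality filter excludes it. Bases are normalized to the RNA
#' alphabet.
#'
#' @param path Path to a VCF 4.x text file.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `qual_missing`, in file order.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) format_error("malformed VCF '%s': %s",
                                                 path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(),
                      qual_missing = logical()))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  reps <- lengths(alts)
  qual_chr <- rep(fix[, "QUAL"], reps)
  qual_missing <- is.na(qual_chr) | qual_chr == "."
  qual <- suppressWarnings(as.numeric(qual_chr))
  if (any(is.na(qual) & !qual_missing))
    format_error("unparsable QUAL value '%s' in '%s'",
                 qual_chr[which(is.na(qual) & !qual_missing)[1L]], path)
  if (any(qual_missing))
    warning(sprintf("%d record(s) with missing QUAL ('.') treated as 0 and flagged",
                    sum(qual_missing)), call. = FALSE)
  qual[qual_missing] <- 0
  out <- data.frame(chrom = rep(fix[, "CHROM"], reps),
                    pos = as.integer(rep(fix[, "POS"], reps)),
                    ref = normalize_rna(rep(fix[, "REF"], reps)),
                    alt = normalize_rna(unlist(alts)),
                    qual = qual,
                    qual_missing = qual_missing,
                    stringsAsFactors = FALSE)
  if (any(out$qual < 0)) format_error("negative QUAL in '%s'", path)
  bad <- out$ref == out$alt
  if (any(bad))
    format_error("REF equals ALT at %s:%d", out$chrom[bad][1L], out$pos[bad][1L])
  rownames(out) <- NULL
  out
}

#' Write minimal variant records as VCF
#'
#' @param records A data.frame as returned by [read_vcf_minimal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(records, path) {
  qual_missing <- if ("qual_missing" %in% names(records)) records$qual_missing
                  else rep(FALSE, nrow(records))
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(records)) {
    qual <- ifelse(qual_missing, ".", format(records$qual, trim = TRUE,
                                             scientific = FALSE))
    lines <- c(lines,
               paste(records$chrom, records$pos, ".",
                     chartr("U", "T", records$ref),
                     chartr("U", "T", records$alt),
                     qual, ".", ".", sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- absorbance traces ----------------------------------------------------

#' Construct an absorbance trace
#'
#' A gradient trace: strictly increasing positions (arbitrary gradient
#' units) with A254 absorbance values.
#'
#' @param position Strictly increasing numeric gradient coordinates.
#' @param absorbance Absorbance values, same length.
#' @return A `data.frame` of class `profile_trace`.
#' @export
profile_trace <- function(position, absorbance) {
  if (length(position) != length(absorbance))
    format_error("position and absorbance must have equal length")
  if (length(position) < 3L) format_error("a trace needs at least 3 points")
  if (anyNA(position) || anyNA(absorbance) ||
      any(!is.finite(position)) || any(!is.finite(absorbance)))
    format_error("trace contains missing or non-finite values")
  ord <- order(position)
  position <- position[ord]; absorbance <- absorbance[ord]
  if (any(diff(position) <= 0))
    format_error("trace positions must be strictly increasing (duplicates found)")
  structure(data.frame(position = position, absorbance = absorbance),
            class = c("profile_trace", "data.frame"))
}

#' Read an absorbance trace CSV
#'
#' Two numeric columns with header `position,absorbance`; positions are
#' sorted ascending on read and duplicates rejected.
#'
#' @param path Path to the CSV.
#' @return A [profile_trace()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) format_error("malformed trace CSV '%s': %s",
                                                  path, conditionMessage(e)))
  if (!all(c("position", "absorbance") %in% names(df)))
    format_error("trace CSV '%s' must have columns position,absorbance", path)
  profile_trace(df$position, df$absorbance)
}

#' Write an absorbance trace CSV
#'
#' @param trace A [profile_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("position", "absorbance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
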